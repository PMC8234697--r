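test_that("inversion is the intensity complement and an involution", {
  expect_equal(pixels(invertImage(enFaceImage(matrix(0, 4, 4)))),
               matrix(1, 4, 4))
  expect_equal(pixels(invertImage(enFaceImage(matrix(0.25, 4, 4)))),
               matrix(0.75, 4, 4))
  set.seed(11)
  img <- enFaceImage(matrix(runif(64), 8, 8), pixelPitchUm = 5,
                     modality = "structure", eyeId = "e1")
  twice <- invertImage(invertImage(img))
  expect_equal(pixels(twice), pixels(img))
  expect_identical(modality(twice), "structure")
  expect_identical(eyeId(twice), "e1")
  expect_identical(pixelPitchUm(twice), 5)
})

test_that("Gaussian blur preserves constants and unit mass", {
  u <- matrix(0.37, 11, 11)
  for (s in c(0.5, 1, 3)) expect_equal(gaussianBlur(u, s), u)
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  expect_equal(sum(gaussianBlur(imp, 1)), 1, tolerance = 1e-12)
  x <- matrix(runif(25), 5, 5)
  expect_identical(gaussianBlur(x, 0), x)  # sigma 0 is the identity
  expect_error(gaussianBlur(x, -1), "sigmaPx")
})

test_that("separable blur matches brute-force direct convolution", {
  set.seed(3)
  x <- matrix(runif(81), 9, 9)
  expect_equal(gaussianBlur(x, 1.5), oracle_gaussian_blur(x, 1.5),
               tolerance = 1e-6)
  # also at a sigma whose kernel is larger than the image half-extent
  expect_equal(gaussianBlur(x, 2.5), oracle_gaussian_blur(x, 2.5),
               tolerance = 1e-6)
})

test_that("a uniform structure slab leaves only a rescaling of the flow", {
  set.seed(4)
  fl <- enFaceImage(matrix(runif(256, 0.1, 0.9), 16, 16), modality = "flow")
  for (lev in c(0.2, 0.65)) {
    st <- enFaceImage(matrix(lev, 16, 16), modality = "structure")
    comp <- compensate(fl, st)
    expect_equal(pixels(comp), (pixels(fl) - min(pixels(fl))) /
                   diff(range(pixels(fl))), tolerance = 1e-12)
    expect_identical(order(pixels(comp)), order(pixels(fl)))
  }
})

test_that("a zero flow pixel stays at the floor of the compensated image", {
  set.seed(5)
  px <- matrix(runif(256, 0.2, 0.9), 16, 16); px[3, 7] <- 0
  fl <- enFaceImage(px, modality = "flow")
  st <- enFaceImage(matrix(runif(256, 0.3, 0.7), 16, 16),
                    modality = "structure")
  comp <- compensate(fl, st)
  expect_identical(pixels(comp)[3, 7], 0)
})

test_that("compensated output spans [0, 1] and keeps geometry", {
  set.seed(6)
  fl <- enFaceImage(matrix(runif(144), 12, 12), pixelPitchUm = 4,
                    modality = "flow")
  st <- enFaceImage(matrix(runif(144), 12, 12), pixelPitchUm = 4,
                    modality = "structure")
  comp <- compensate(fl, st)
  expect_identical(range(pixels(comp)), c(0, 1))
  expect_identical(dim(comp), dim(fl))
  expect_identical(pixelPitchUm(comp), 4)
  # constant product degenerates to all zeros
  compConst <- compensate(enFaceImage(matrix(0.5, 8, 8), modality = "flow"),
                          enFaceImage(matrix(0.5, 8, 8),
                                      modality = "structure"))
  expect_true(all(pixels(compConst) == 0))
})

test_that("mismatched inputs are rejected with both shapes reported", {
  fl <- enFaceImage(matrix(0.5, 8, 8), modality = "flow")
  st <- enFaceImage(matrix(0.5, 8, 9), modality = "structure")
  expect_error(compensate(fl, st), "8 x 8.*8 x 9")
  expect_error(compensate(fl, fl), "modality")
  stp <- enFaceImage(matrix(0.5, 8, 8), pixelPitchUm = 7,
                     modality = "structure")
  expect_error(compensate(fl, stp), "pitch")
})

test_that("a jointly attenuated disc is equalized by compensation", {
  # flow and structure both attenuated by a = 0.6 inside a central disc;
  # after compensation the disc interior should match the surround to
  # within 5% relative, excluding a 2-sigma band around the boundary
  n <- 64; a <- 0.6; sigma <- 2; rad <- 14
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- (rows - 32.5)^2 + (cols - 32.5)^2
  att <- ifelse(d2 <= rad^2, a, 1)
  fl <- enFaceImage(0.5 * att, modality = "flow")
  st <- enFaceImage(0.65 * att, modality = "structure")
  # compare on the compensated product before the final min-max rescale
  # (an affine stretch of a near-two-level image does not preserve relative
  # contrast, so the shading claim is about the product itself)
  product <- pixels(fl) * gaussianBlur(pixels(invertImage(st)), sigma)
  inside <- d2 <= (rad - 2 * sigma)^2
  outside <- d2 >= (rad + 2 * sigma)^2
  mIn <- mean(product[inside]); mOut <- mean(product[outside])
  expect_lt(abs(mIn - mOut) / mOut, 0.05)
  # without compensation the disc is 40% darker
  expect_lt(mean(pixels(fl)[inside]) / mean(pixels(fl)[outside]), 0.65)
})
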