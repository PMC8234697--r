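test_that("component labelling uses 8-connectivity", {
  expect_identical(labelComponents(matrix(FALSE, 5, 5))$n, 0L)
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  lc <- labelComponents(sq)
  expect_identical(lc$n, 1L)
  expect_identical(lc$sizesPx, 9L)
  # pixels touching only diagonally belong to one component
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_identical(labelComponents(diag2)$n, 1L)
})

test_that("labelling matches the flood-fill oracle on random masks", {
  for (seed in c(101, 102, 103)) {
    set.seed(seed)
    m <- matrix(runif(1024) < 0.4, 32, 32)
    lc <- labelComponents(m)
    oracle <- oracle_label8(m)
    expect_identical(lc$n, max(oracle))
    # same partition: label images agree up to relabelling
    expect_identical(sort(tabulate(lc$labels[lc$labels > 0])),
                     sort(tabulate(oracle[oracle > 0])))
    both <- table(lc$labels[m], oracle[m])
    expect_true(all(rowSums(both > 0) == 1) && all(colSums(both > 0) == 1))
  }
})

test_that("metrics follow the area arithmetic of the pixel grid", {
  pitch <- 3000 / 512
  full <- computeMetrics(binaryFDMask(matrix(TRUE, 512, 512)))
  expect_identical(fdPercent(full), 100)
  expect_equal(totalFDAreaMm2(full), 9.0)  # the whole 3 x 3 mm frame

  m <- matrix(FALSE, 512, 512); m[5:7, 5:7] <- TRUE
  one <- computeMetrics(binaryFDMask(m))
  expect_identical(nFD(one), 1L)
  expect_equal(meanFDSizeUm2(one), 9 * pitch^2)  # ~308.99
  expect_equal(round(meanFDSizeUm2(one), 2), 308.99)

  half <- matrix(FALSE, 16, 16); half[, 1:8] <- TRUE
  expect_identical(fdPercent(computeMetrics(binaryFDMask(half))), 50)

  none <- computeMetrics(binaryFDMask(matrix(FALSE, 8, 8)))
  expect_identical(nFD(none), 0L)
  expect_true(is.nan(meanFDSizeUm2(none)))
  expect_identical(totalFDAreaMm2(none), 0)
})

test_that("count times mean size equals total deficit area exactly", {
  for (seed in c(7, 8)) {
    set.seed(seed)
    m <- matrix(runif(4096) < 0.3, 64, 64)
    met <- computeMetrics(binaryFDMask(m, pixelPitchUm = 5.2))
    expect_identical(nFD(met), length(componentSizesPx(met)))
    expect_equal(nFD(met) * meanFDSizeUm2(met),
                 totalFDAreaMm2(met) * 1e6, tolerance = 1e-12)
    expect_equal(sum(componentSizesPx(met)) * 5.2^2 / 1e6,
                 totalFDAreaMm2(met), tolerance = 1e-15)
  }
})

test_that("adding deficit pixels never decreases FD%", {
  set.seed(9)
  m <- matrix(runif(1024) < 0.2, 32, 32)
  base <- fdPercent(computeMetrics(binaryFDMask(m)))
  for (i in 1:5) {
    off <- which(!m)
    m[sample(off, 10)] <- TRUE
    grown <- fdPercent(computeMetrics(binaryFDMask(m)))
    expect_gte(grown, base)
    base <- grown
  }
})

test_that("pixel radii convert to the printed physical radii", {
  expect_equal(round(radiusPxToUm(c(4, 8, 10, 15)), 2),
               c(26.37, 49.80, 61.52, 90.82))
  # the plain r * pitch convention does not reproduce them
  expect_false(isTRUE(all.equal(round(4 * 3000 / 512, 2), 26.37)))
})

test_that("sensitivity analysis summarizes each radius", {
  allDef <- enFaceImage(matrix(0, 32, 32))
  suppressWarnings(sens <- sensitivityAnalysis(list(allDef),
                                               radii = c(2, 4, 15)))
  expect_identical(sens$perRadius$fd_percent_mean, c(100, 100, 100))
  # repeated radius: deterministic, identical rows
  set.seed(10)
  img <- enFaceImage(matrix(runif(4096), 64, 64))
  s2 <- sensitivityAnalysis(list(img), radii = c(15, 15))
  expect_identical(s2$perRadius$n_fd_mean[1], s2$perRadius$n_fd_mean[2])
  expect_error(sensitivityAnalysis(list(), c(4)), "at least one image")
  expect_error(sensitivityAnalysis(list(img), numeric(0)), "radius")
})

test_that("deficit count decreases with window radius on the default cohort", {
  # twenty default synthetic scenes through the full pipeline
  comp <- lapply(1:20, function(i) {
    sc <- generateScene(seed = i, eyeId = sprintf("s%02d", i))
    compensate(sc$flow, sc$structure)
  })
  sens <- sensitivityAnalysis(comp, radii = c(4, 8, 10, 15))
  counts <- sens$perRadius$n_fd_mean
  expect_true(all(diff(counts) < 0))
})
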