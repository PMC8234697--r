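test_that("group summaries reproduce the reference-cohort statistics", {
  neo <- neovascularReferenceCohort()
  cmt <- summarizeGroup(neo$cmt_um)
  expect_lte(abs(cmt$mean - 250.13), 0.005)  # printed precision
  expect_lte(abs(cmt$sd - 40.95), 0.005)
  ct <- summarizeGroup(neo$ct_um)
  expect_equal(ct$mean, 227)
  expect_equal(round(ct$sd, 2), 94.38)
  expect_equal(round(summarizeGroup(neo$bcva_logmar)$mean, 2), 0.12)
  expect_equal(round(summarizeGroup(neo$age_years)$sd, 2), 7.41)

  const <- summarizeGroup(c(5, 5, 5))
  expect_identical(const$mean, 5)
  expect_identical(const$sd, 0)
  expect_identical(summarizeGroup(c(3))$sd, NA_real_)
  expect_error(summarizeGroup(numeric(0)), "empty")
})

test_that("Fisher exact follows the minimum-likelihood two-sided rule", {
  expect_equal(round(fisherExactTwoSided(7, 1, 37, 52), 3), 0.021)
  expect_identical(fisherExactTwoSided(5, 5, 5, 5), 1)
  expect_warning(p0 <- fisherExactTwoSided(0, 0, 3, 4), "margin")
  expect_identical(p0, 1)
  expect_error(fisherExactTwoSided(-1, 2, 3, 4), "nonnegative")
  # matrix input, and invariance under simultaneous row and column swap
  set.seed(12)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    p <- fisherExactTwoSided(tab)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, fisherExactTwoSided(tab[2:1, 2:1]), tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with the independent stats::fisher.test", {
  set.seed(13)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(fisherExactTwoSided(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  p <- mannWhitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(p, 0.1)  # 2 / choose(6, 3)
  expect_equal(p, oracle_mann_whitney(c(1, 2, 3), c(10, 11, 12)))
  set.seed(14)
  for (i in 1:10) {
    x <- runif(4); y <- runif(5)
    expect_equal(mannWhitney(x, y), oracle_mann_whitney(x, y),
                 tolerance = 1e-12)
    expect_equal(mannWhitney(x, y), mannWhitney(y, x), tolerance = 1e-12)
  }
  # identical multisets carry no group signal
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-6)
  expect_error(mannWhitney(numeric(0), 1:3), "nonempty")
})

test_that("log-log size/number fit recovers exact power laws", {
  s <- c(10, 100, 1000)
  fit <- suppressWarnings(loglogSizeNumberFit(100 * s^(-0.5), s))
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$rSquared, 1, tolerance = 1e-12)
  # two points: perfect interpolation
  fit2 <- loglogSizeNumberFit(c(100, 10), c(50, 5000))
  expect_equal(fit2$rSquared, 1, tolerance = 1e-12)
  expect_error(loglogSizeNumberFit(c(10, 0, 5), c(1, 2, 3),
                                   eyeIds = c("a", "b", "c")), "b")
})

test_that("log-log fit recovers a planted shallow negative slope", {
  cohort <- generateCohort(nEyes = 89, seed = 7, neovascularPrevalence = 0)
  fit <- loglogSizeNumberFit(cohort$n_fd, cohort$mean_fd_size_um2,
                             cohort$eye_id)
  ci <- fit$slope + c(-1, 1) * qt(0.975, fit$n - 2) * fit$slopeSE
  expect_gt(-0.0604, ci[1])
  expect_lt(-0.0604, ci[2])
})

test_that("multivariate stage recovers exact linear data", {
  set.seed(15)
  d <- data.frame(age_years = rnorm(40, 80, 8),
                  flag = rbinom(40, 1, 0.5))
  d$outcome <- 2 * d$age_years - 3 * d$flag + 10
  # force both covariates into stage 2 so the model is fully specified
  # (suppress the perfect-fit diagnostics of noiseless data)
  res <- suppressWarnings(
    regressionScreen(d, "outcome", c("age_years", "flag"),
                     forceIn = c("age_years", "flag"),
                     log10Outcome = FALSE,
                     log10Covariates = character()))
  multi <- res[res$stage == "multivariate", ]
  expect_equal(multi$coef[multi$covariate == "age_years"], 2,
               tolerance = 1e-8)
  expect_equal(multi$coef[multi$covariate == "flag"], -3, tolerance = 1e-8)
  expect_true(all(res$selected))
})

test_that("the univariate screen excludes pure-noise covariates", {
  set.seed(16)
  d <- data.frame(y = rnorm(200), signal = rnorm(200), noisecov = rnorm(200))
  d$y <- d$y + 2 * d$signal
  res <- regressionScreen(d, "y", c("signal", "noisecov"),
                          log10Outcome = FALSE,
                          log10Covariates = character())
  uni <- res[res$stage == "univariate", ]
  expect_gt(uni$p[uni$covariate == "noisecov"], 0.20)
  multi <- res[res$stage == "multivariate", ]
  expect_false("noisecov" %in% multi$covariate)
  expect_true("signal" %in% multi$covariate)
  # forceIn overrides the screen
  res2 <- regressionScreen(d, "y", c("signal", "noisecov"),
                           forceIn = "noisecov", log10Outcome = FALSE,
                           log10Covariates = character())
  expect_true("noisecov" %in%
                res2$covariate[res2$stage == "multivariate"])
})

test_that("raising the screen threshold never drops a covariate", {
  for (seed in c(17, 18)) {
    cohort <- generateCohort(nEyes = 89, seed = seed,
                             neovascularPrevalence = 0)
    sel <- lapply(c(0.05, 0.20, 0.50, 1.0000001), function(th) {
      r <- regressionScreen(cohort, "fd_percent", threshold = th)
      sort(unique(r$covariate[r$stage == "univariate" & r$selected]))
    })
    for (i in seq_len(length(sel) - 1))
      expect_true(all(sel[[i]] %in% sel[[i + 1]]))
  }
})

test_that("collinear covariates are rejected with the dependency named", {
  set.seed(19)
  d <- data.frame(y = rnorm(30), a = rnorm(30))
  d$b <- 2 * d$a  # exactly dependent
  expect_error(regressionScreen(d, "y", c("a", "b"), threshold = 1.01,
                                log10Outcome = FALSE,
                                log10Covariates = character()),
               "collinear.*b")
})

test_that("multivariate residuals are orthogonal to the design", {
  cohort <- generateCohort(nEyes = 89, seed = 20, neovascularPrevalence = 0)
  res <- regressionScreen(cohort, "fd_percent", threshold = 1.0000001)
  multi <- res[res$stage == "multivariate", ]
  y <- log10(cohort$fd_percent)
  X <- cbind(age_years = log10(cohort$age_years),
             cmt_um = log10(cohort$cmt_um),
             ct_um = log10(cohort$ct_um),
             small_drusen = cohort$small_drusen,
             large_drusen = cohort$large_drusen,
             drusenoid_ped = cohort$drusenoid_ped,
             atrophy = cohort$atrophy,
             rpd = cohort$rpd)
  beta <- multi$coef[match(colnames(X), multi$covariate)]
  intercept <- mean(y) - sum(colMeans(X) * beta)
  r <- y - intercept - as.vector(X %*% beta)
  expect_lt(max(abs(crossprod(cbind(1, X), r))), 1e-8)
})

test_that("group comparison reports prevalence, counts and p-values", {
  neo <- neovascularReferenceCohort()
  non <- generateCohort(nEyes = 89, seed = 21, neovascularPrevalence = 0)
  shared <- intersect(names(non), names(neo))
  cohort <- rbind(non[shared], neo[shared])
  tab <- buildTable2(cohort)
  expect_equal(round(tab$prevalenceNeovascularPct, 2), 8.25)
  ped <- tab$flags[tab$flags$field == "drusenoid_ped", ]
  expect_identical(ped$neovascular_n, 7L)
  expect_equal(ped$neovascular_pct, 87.5)
  expect_true(all(tab$quantitative$p_mann_whitney >= 0 &
                    tab$quantitative$p_mann_whitney <= 1))
  expect_error(buildTable2(non), "both")
})

test_that("identical groups yield uninformative Fisher comparisons", {
  neo <- neovascularReferenceCohort()
  twin <- neo
  twin$eye_id <- paste0("twin", seq_len(nrow(twin)))
  twin$group <- "non_neovascular"
  tab <- suppressWarnings(buildTable2(rbind(neo, twin)))
  expect_true(all(tab$flags$p_fisher == 1))
})
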