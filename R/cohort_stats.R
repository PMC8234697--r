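#' Mean, standard deviation and count of a group of values
#'
#' Quantitative cohort variables are summarized as mean with sample
#' (n - 1 denominator) standard deviation.
#'
#' @param x numeric vector (NA removed).
#' @return A list with `mean`, `sd` (NA when fewer than 2 values) and `n`.
#' @examples
#' summarizeGroup(c(252, 211, 338, 249, 264, 244, 239, 204))
#' @export
summarizeGroup <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("cannot summarize an empty selection")
  list(mean = mean(x), sd = if (length(x) >= 2L) sd(x) else NA_real_,
       n = length(x))
}

#' Two-sided Fisher exact test for a 2 x 2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric point probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table (with
#' a relative tolerance of 1e-7 for numerical ties). Rows are groups and
#' columns flag present/absent. If any margin is zero the table carries no
#' information and `p = 1` is returned with a warning.
#'
#' @param a,b,c,d cell counts: `(a, b)` = first row, `(c, d)` = second row.
#'   Alternatively `a` may be a 2 x 2 matrix and `b`, `c`, `d` omitted.
#' @return Two-sided p-value in (0, 1\].
#' @examples
#' fisherExactTwoSided(7, 1, 37, 52)  # 0.021 to 2 dp
#' @export
fisherExactTwoSided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2L, 2L)
  }
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be nonnegative integers")
  if (sum(tab) == 0) stop("table total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin of the 2 x 2 table is zero; returning p = 1")
    return(1)
  }
  x <- tab[1, 1]
  k <- sum(tab[1, ])        # first row total (draws)
  K <- sum(tab[, 1])        # first column total (white balls)
  N <- sum(tab)
  support <- max(0L, k - (N - K)):min(k, K)
  probs <- dhyper(support, K, N - K, k)
  pObs <- dhyper(x, K, N - K, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact distribution when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y numeric samples (both nonempty).
#' @return Two-sided p-value.
#' @examples
#' mannWhitney(c(1, 2, 3), c(10, 11, 12))  # 0.1 (exact: 2 / choose(6, 3))
#' @export
mannWhitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be nonempty")
  z <- c(x, y)
  useExact <- (length(z) <= 20L) && !anyDuplicated(z)
  suppressWarnings(
    wilcox.test(x, y, exact = useExact, correct = TRUE)$p.value
  )
}

#' Log-log fit of flow-deficit count against size
#'
#' Ordinary least squares of `log10(n_fd)` on `log10(mean size)` across
#' eyes. An inverse linear relation on the log-log plot (negative slope)
#' reflects the trade-off between many small and few large deficits.
#'
#' @param nFD per-eye deficit counts (all > 0).
#' @param meanSizeUm2 per-eye mean deficit sizes in um^2 (all > 0).
#' @param eyeIds optional identifiers used in error messages.
#' @return A list with `slope`, `intercept` (both on the log10 scale),
#'   `slopeSE`, `rSquared` and `n`.
#' @examples
#' s <- c(10, 100, 1000)
#' loglogSizeNumberFit(100 * s^(-0.5), s)  # slope -0.5, intercept 2
#' @export
loglogSizeNumberFit <- function(nFD, meanSizeUm2, eyeIds = NULL) {
  stopifnot(length(nFD) == length(meanSizeUm2))
  if (is.null(eyeIds)) eyeIds <- as.character(seq_along(nFD))
  bad <- which(!(nFD > 0) | !(meanSizeUm2 > 0))
  if (length(bad))
    stop("nonpositive count or size for eye(s): ",
         paste(eyeIds[bad], collapse = ", "))
  if (length(nFD) < 2L) stop("need at least two eyes to fit")
  fit <- lm(log10(nFD) ~ log10(meanSizeUm2))
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       slopeSE = unname(sm$coefficients[2, "Std. Error"]),
       rSquared = sm$r.squared, n = length(nFD))
}

.defaultScreenCovariates <- c("age_years", "cmt_um", "ct_um", "small_drusen",
                              "large_drusen", "drusenoid_ped", "atrophy",
                              "rpd")
.defaultLog10Covariates <- c("age_years", "cmt_um", "ct_um")

# transform selected covariates to log10, erroring on nonpositive values
.buildDesign <- function(cohort, covariates, log10Covariates) {
  X <- lapply(covariates, function(cv) {
    if (is.null(cohort[[cv]])) stop("covariate '", cv, "' not in cohort")
    v <- cohort[[cv]]
    if (cv %in% log10Covariates) {
      if (any(v <= 0, na.rm = TRUE))
        stop("covariate '", cv, "' has nonpositive values; cannot log10")
      v <- log10(v)
    }
    v
  })
  names(X) <- covariates
  as.data.frame(X)
}

#' Univariate screen and multivariate linear regression
#'
#' Stage 1 fits a simple OLS of the (optionally log10-transformed) outcome
#' on each covariate separately; stage 2 fits a multivariate OLS on the
#' covariates whose univariate p-value is below `threshold` (default 0.20),
#' plus any covariates forced in via `forceIn`. Continuous covariates named
#' in `log10Covariates` (default: age, CMT, CT) enter on the log10 scale;
#' binary flags enter untransformed.
#'
#' @param cohort data.frame with one row per eye containing the outcome and
#'   covariate columns.
#' @param outcome outcome column: `"fd_percent"`, `"mean_fd_size_um2"` or
#'   `"n_fd"` (any numeric column is accepted).
#' @param covariates character vector of covariate columns.
#' @param threshold univariate p-value threshold for entering stage 2.
#' @param forceIn covariates always included in stage 2 regardless of their
#'   univariate p-value.
#' @param log10Outcome log10-transform the outcome (default TRUE).
#' @param log10Covariates continuous covariates to log10-transform.
#' @return data.frame with columns `stage` (`"univariate"`/
#'   `"multivariate"`), `outcome`, `covariate`, `coef`, `se`, `p`, `ci_lo`,
#'   `ci_hi` and `selected` (whether the covariate entered stage 2).
#' @examples
#' set.seed(1)
#' d <- data.frame(fd_percent = 10^(0.5 + rnorm(40, sd = 0.1)),
#'                 age_years = rnorm(40, 80, 8),
#'                 small_drusen = rbinom(40, 1, 0.5))
#' regressionScreen(d, "fd_percent", c("age_years", "small_drusen"))
#' @export
regressionScreen <- function(cohort, outcome = "fd_percent",
                             covariates = .defaultScreenCovariates,
                             threshold = 0.20, forceIn = character(),
                             log10Outcome = TRUE,
                             log10Covariates = .defaultLog10Covariates) {
  if (is.null(cohort[[outcome]])) stop("outcome '", outcome, "' not in cohort")
  y <- cohort[[outcome]]
  if (log10Outcome) {
    if (any(y <= 0, na.rm = TRUE))
      stop("outcome '", outcome, "' has nonpositive values; cannot log10")
    y <- log10(y)
  }
  X <- .buildDesign(cohort, covariates, log10Covariates)
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]

  uniRow <- function(cv) {
    fit <- lm(y ~ x, data = data.frame(y = y, x = X[[cv]]))
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)["x", ]
    data.frame(stage = "univariate", outcome = outcome, covariate = cv,
               coef = sm["x", "Estimate"], se = sm["x", "Std. Error"],
               p = sm["x", "Pr(>|t|)"], ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  uni <- do.call(rbind, lapply(covariates, uniRow))
  selected <- union(uni$covariate[uni$p < threshold],
                    intersect(forceIn, covariates))
  uni$selected <- uni$covariate %in% selected

  multi <- NULL
  if (length(selected)) {
    Xm <- X[, selected, drop = FALSE]
    qrX <- qr(cbind(1, as.matrix(Xm)))
    if (qrX$rank < ncol(Xm) + 1L) {
      dropped <- setdiff(seq_len(ncol(Xm) + 1L), qrX$pivot[seq_len(qrX$rank)])
      stop("collinear covariate set; linearly dependent column(s): ",
           paste(c("(Intercept)", selected)[dropped], collapse = ", "))
    }
    fit <- lm(y ~ ., data = data.frame(y = y, Xm, check.names = FALSE))
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    rows <- rownames(sm)[-1]
    multi <- data.frame(stage = "multivariate", outcome = outcome,
                        covariate = sub("^`|`$", "", rows),
                        coef = sm[-1, "Estimate"], se = sm[-1, "Std. Error"],
                        p = sm[-1, "Pr(>|t|)"],
                        ci_lo = ci[-1, 1], ci_hi = ci[-1, 2],
                        selected = TRUE,
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(uni, multi)
}

#' Group-comparison table (non-neovascular vs neovascular eyes)
#'
#' Summarizes each quantitative field as group mean (SD) with a two-sided
#' Mann-Whitney p-value, and each binary flag as group count (%) with a
#' two-sided Fisher exact p-value. Also reports the prevalence of the
#' neovascular group, `100 * n_neovascular / n_total`.
#'
#' @param cohort validated cohort data.frame with a `group` column holding
#'   both `"non_neovascular"` and `"neovascular"` eyes.
#' @param quantFields quantitative columns to compare.
#' @param flagFields binary flag columns to compare.
#' @return A list with `quantitative` (field, per-group mean/sd, p),
#'   `flags` (field, per-group count/pct, p), group sizes and
#'   `prevalenceNeovascularPct`.
#' @examples
#' neo <- neovascularReferenceCohort()
#' non <- generateCohort(nEyes = 89, seed = 1, neovascularPrevalence = 0)
#' tab <- buildTable2(rbind(non[names(neo)[names(neo) %in% names(non)]],
#'                          neo[names(neo) %in% names(non)]))
#' tab$prevalenceNeovascularPct
#' @export
buildTable2 <- function(cohort,
                        quantFields = c("age_years", "bcva_logmar",
                                        "cmt_um", "ct_um"),
                        flagFields = .cohortFlags) {
  nonNeo <- cohort[cohort$group == "non_neovascular", , drop = FALSE]
  neo <- cohort[cohort$group == "neovascular", , drop = FALSE]
  if (nrow(nonNeo) == 0L || nrow(neo) == 0L)
    stop("cohort must contain both non-neovascular and neovascular eyes")
  quantFields <- intersect(quantFields, names(cohort))
  quant <- do.call(rbind, lapply(quantFields, function(f) {
    a <- summarizeGroup(nonNeo[[f]]); b <- summarizeGroup(neo[[f]])
    data.frame(field = f,
               non_neovascular_mean = a$mean, non_neovascular_sd = a$sd,
               neovascular_mean = b$mean, neovascular_sd = b$sd,
               p_mann_whitney = mannWhitney(nonNeo[[f]], neo[[f]]),
               stringsAsFactors = FALSE)
  }))
  flags <- do.call(rbind, lapply(flagFields, function(f) {
    aYes <- sum(nonNeo[[f]] == 1); bYes <- sum(neo[[f]] == 1)
    data.frame(field = f,
               non_neovascular_n = aYes,
               non_neovascular_pct = 100 * aYes / nrow(nonNeo),
               neovascular_n = bYes,
               neovascular_pct = 100 * bYes / nrow(neo),
               p_fisher = fisherExactTwoSided(
                 bYes, nrow(neo) - bYes, aYes, nrow(nonNeo) - aYes),
               stringsAsFactors = FALSE)
  }))
  list(quantitative = quant, flags = flags,
       nNonNeovascular = nrow(nonNeo), nNeovascular = nrow(neo),
       prevalenceNeovascularPct = 100 * nrow(neo) / nrow(cohort))
}
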