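#' Generate a synthetic en face scene pair with known ground truth
#'
#' Builds a flow/structure slab pair emulating a 3 x 3 mm choriocapillaris
#' scan. The flow-deficit geometry is drawn by thresholding a smoothed
#' Gaussian noise field at the quantile that yields the target area
#' fraction, giving the irregular, scale-controllable morphology of real
#' deficit maps with exact control of the planted fraction. Drusen-like
#' shadowing is emulated by multiplying both channels by the same
#' attenuation field (discs at attenuation `attenuation`), which is the
#' artifact the compensation step removes.
#'
#' @param sizePx image side length in pixels (default 512).
#' @param pitchUm physical pixel size in microns (default 3000/512).
#' @param targetFdFraction planted deficit area fraction in \[0, 1\]
#'   (default 0.45, a typical value for intermediate-AMD fellow eyes).
#' @param fdTextureScalePx correlation length (blur sigma, pixels) of the
#'   deficit field (default 4, giving components of order 10 px across,
#'   i.e. a few thousand um^2 at the default pitch).
#' @param flowLevel,deficitLevel mean intensities of flow and deficit
#'   pixels before noise (defaults 0.30 and 0.10: en face flow slabs are
#'   dim, low-contrast images whose deficits sit near the noise floor —
#'   the regime local adaptive thresholding is designed for).
#' @param structureLevel mean intensity of the structure slab (default
#'   0.65, a mid-gray slab for which the multiplicative compensation is
#'   near exact at moderate attenuation).
#' @param noiseSd additive Gaussian noise standard deviation (default 0.04).
#' @param nDrusen number of attenuation discs (default 16).
#' @param drusenRadiusPx range (min, max) of disc radii in pixels (default
#'   c(20, 60), i.e. shadow radii of roughly 120-350 um: large drusen to
#'   drusenoid PEDs, jointly covering about a fifth of the field).
#' @param attenuation multiplicative attenuation inside discs, in (0, 1\]
#'   (default 0.6).
#' @param seed integer seed; the scene is fully determined by it.
#' @param eyeId identifier stamped on both slabs.
#' @return A list with `flow` and `structure` ([EnFaceImage-class]) and
#'   `truth`: `fdMask` (logical ground-truth mask, `TRUE` = deficit),
#'   `attenuationField`, `realizedFdFraction` and `params`.
#' @examples
#' sc <- generateScene(sizePx = 64, seed = 1)
#' sc$truth$realizedFdFraction
#' @export
generateScene <- function(sizePx = 512, pitchUm = 3000 / 512,
                          targetFdFraction = 0.45, fdTextureScalePx = 4,
                          flowLevel = 0.30, deficitLevel = 0.10,
                          structureLevel = 0.65, noiseSd = 0.04,
                          nDrusen = 16, drusenRadiusPx = c(20, 60),
                          attenuation = 0.6, seed = 1, eyeId = "synthetic") {
  if (targetFdFraction < 0 || targetFdFraction > 1)
    stop("'targetFdFraction' must lie in [0, 1]")
  if ((targetFdFraction == 0 || targetFdFraction == 1) &&
      fdTextureScalePx == 0)
    stop("degenerate deficit fraction ", targetFdFraction,
         " with zero texture scale")
  if (attenuation <= 0 || attenuation > 1)
    stop("'attenuation' must lie in (0, 1]")
  withr::with_seed(as.integer(seed), {
    n <- as.integer(sizePx)
    field <- gaussianBlur(matrix(rnorm(n * n), n, n), fdTextureScalePx)
    fdMask <- if (targetFdFraction == 0) {
      matrix(FALSE, n, n)
    } else if (targetFdFraction == 1) {
      matrix(TRUE, n, n)
    } else {
      field <= quantile(field, targetFdFraction)
    }
    att <- matrix(1, n, n)
    if (nDrusen > 0) {
      rows <- matrix(seq_len(n), n, n)
      cols <- matrix(seq_len(n), n, n, byrow = TRUE)
      for (i in seq_len(nDrusen)) {
        cx <- runif(1, 1, n); cy <- runif(1, 1, n)
        r <- runif(1, drusenRadiusPx[1], drusenRadiusPx[2])
        att[(rows - cx)^2 + (cols - cy)^2 <= r^2] <- attenuation
      }
    }
    flow <- ifelse(fdMask, deficitLevel, flowLevel) +
      rnorm(n * n, sd = noiseSd)
    structure <- structureLevel + rnorm(n * n, sd = noiseSd)
    flow <- pmin(1, pmax(0, flow * att))
    structure <- pmin(1, pmax(0, structure * att))
    list(
      flow = enFaceImage(matrix(flow, n, n), pixelPitchUm = pitchUm,
                         modality = "flow", eyeId = eyeId),
      structure = enFaceImage(matrix(structure, n, n),
                              pixelPitchUm = pitchUm,
                              modality = "structure", eyeId = eyeId),
      truth = list(fdMask = fdMask, attenuationField = att,
                   realizedFdFraction = mean(fdMask),
                   params = list(sizePx = n, pitchUm = pitchUm,
                                 targetFdFraction = targetFdFraction,
                                 fdTextureScalePx = fdTextureScalePx,
                                 flowLevel = flowLevel,
                                 deficitLevel = deficitLevel,
                                 structureLevel = structureLevel,
                                 noiseSd = noiseSd, nDrusen = nDrusen,
                                 drusenRadiusPx = drusenRadiusPx,
                                 attenuation = attenuation, seed = seed))
    )
  })
}

#' Generate a synthetic cohort table with planted statistical structure
#'
#' Samples per-eye clinical covariates from the stated distributions and
#' generates flow-deficit metrics from planted linear models on the same
#' design used by [regressionScreen()] (log10 outcome; age, CMT and CT as
#' log10). Deficit size and count are coupled through a planted log-log law
#' `log10(n) = loglogIntercept + loglogSlope * log10(size) + noise`, and the
#' total deficit area is derived consistently as `n * size`. Defaults
#' reproduce the covariate distributions and effect magnitudes typical of a
#' fellow-eye AMD cohort (mean age 80, FD% around 46, counts near 2000,
#' sizes near 5000 um^2).
#'
#' @param nEyes number of eyes (>= 3).
#' @param seed integer seed; the cohort is fully determined by it.
#' @param ageMean,ageSd,bcvaMean,bcvaSd,cmtMean,cmtSd,ctMean,ctSd normal
#'   covariate distributions (BCVA truncated at 0; CMT/CT floored at 50 and
#'   30 um as physiologic minima).
#' @param flagPrevalence named prevalences of the five binary flags.
#' @param femalePrevalence,neovascularPrevalence prevalences of female
#'   gender and of the neovascular group.
#' @param fdEffects named linear effects of (transformed) covariates on
#'   log10(FD%); default age 0.62, small drusen -0.13.
#' @param fdIntercept,fdResidSd intercept and residual SD of the log10(FD%)
#'   model.
#' @param sizeEffects named effects on log10(mean FD size, um^2); default
#'   age 2.69, CT -0.68.
#' @param sizeIntercept,sizeResidSd intercept and residual SD of the size
#'   model.
#' @param loglogSlope,loglogIntercept,loglogResidSd planted size-count law
#'   on the log10 scale.
#' @param log10Covariates covariates entering the planted models (and the
#'   screen) on the log10 scale.
#' @return A validated cohort data.frame with covariates and metric columns
#'   `fd_percent`, `n_fd`, `mean_fd_size_um2`, `total_fd_area_mm2`.
#' @examples
#' cohort <- generateCohort(nEyes = 89, seed = 1, neovascularPrevalence = 0)
#' summarizeGroup(cohort$fd_percent)
#' @export
generateCohort <- function(nEyes = 97, seed = 1,
                           ageMean = 80, ageSd = 7.66,
                           bcvaMean = 0.18, bcvaSd = 0.2,
                           cmtMean = 238.49, cmtSd = 67.49,
                           ctMean = 210.51, ctSd = 83.21,
                           flagPrevalence = c(small_drusen = 62 / 97,
                                              large_drusen = 69 / 97,
                                              drusenoid_ped = 44 / 97,
                                              rpd = 54 / 97,
                                              atrophy = 19 / 97),
                           femalePrevalence = 58 / 97,
                           neovascularPrevalence = 8 / 97,
                           fdEffects = c(age_years = 0.62,
                                         small_drusen = -0.13),
                           fdIntercept = 0.565, fdResidSd = 0.10,
                           sizeEffects = c(age_years = 2.69,
                                           ct_um = -0.68),
                           sizeIntercept = 0.16, sizeResidSd = 0.30,
                           loglogSlope = -0.0604, loglogIntercept = 3.52,
                           loglogResidSd = 0.20,
                           log10Covariates = .defaultLog10Covariates) {
  if (nEyes < 3) stop("'nEyes' must be >= 3")
  if (any(flagPrevalence < 0 | flagPrevalence > 1) ||
      neovascularPrevalence < 0 || neovascularPrevalence > 1 ||
      femalePrevalence < 0 || femalePrevalence > 1)
    stop("prevalences must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    df <- data.frame(
      eye_id = sprintf("sim%04d", seq_len(nEyes)),
      group = ifelse(rbinom(nEyes, 1, neovascularPrevalence) == 1,
                     "neovascular", "non_neovascular"),
      gender = ifelse(rbinom(nEyes, 1, femalePrevalence) == 1,
                      "female", "male"),
      age_years = pmax(50, rnorm(nEyes, ageMean, ageSd)),
      bcva_logmar = pmax(0, rnorm(nEyes, bcvaMean, bcvaSd)),
      cmt_um = pmax(50, rnorm(nEyes, cmtMean, cmtSd)),
      ct_um = pmax(30, rnorm(nEyes, ctMean, ctSd)),
      stringsAsFactors = FALSE
    )
    for (fl in names(flagPrevalence))
      df[[fl]] <- rbinom(nEyes, 1, flagPrevalence[[fl]])

    linpred <- function(intercept, effects) {
      z <- rep(intercept, nEyes)
      for (cv in names(effects)) {
        v <- df[[cv]]
        if (cv %in% log10Covariates) v <- log10(v)
        z <- z + effects[[cv]] * v
      }
      z
    }
    lpFd <- linpred(fdIntercept, fdEffects)
    # parameter-level feasibility: probability that the planted model puts
    # FD% above 100 (log10 scale: linear predictor + noise beyond 2)
    pOver <- if (fdResidSd > 0) {
      stats::pnorm(2, mean = lpFd, sd = fdResidSd, lower.tail = FALSE)
    } else {
      as.numeric(lpFd > 2)
    }
    if (mean(pOver) > 0.01)
      stop("planted effect sizes produce FD% above 100 in more than 1% ",
           "of draws; reduce intercept or effects")
    df$fd_percent <- pmin(100, 10^(lpFd + rnorm(nEyes, sd = fdResidSd)))
    logSize <- linpred(sizeIntercept, sizeEffects) +
      rnorm(nEyes, sd = sizeResidSd)
    df$mean_fd_size_um2 <- 10^logSize
    logN <- loglogIntercept + loglogSlope * logSize +
      rnorm(nEyes, sd = loglogResidSd)
    df$n_fd <- pmax(1L, as.integer(round(10^logN)))
    df$total_fd_area_mm2 <- df$n_fd * df$mean_fd_size_um2 / 1e6
    validateCohort(df)
  })
}
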