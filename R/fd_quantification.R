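#' Label flow-deficit components
#'
#' Extracts the 8-connected components of flow-deficit pixels (the Fiji
#' particle-analysis convention, with pass-everything size and circularity
#' bounds: no component is filtered out).
#'
#' @param mask a [BinaryFDMask-class] or logical matrix (`TRUE` = deficit).
#' @return A list with `labels` (integer matrix, 0 = flow background,
#'   components numbered in scan order), `sizesPx` (integer vector of
#'   component pixel counts) and `n` (number of components).
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' labelComponents(m)$n  # 1: diagonal contact joins under 8-connectivity
#' @export
labelComponents <- function(mask) {
  m <- if (is(mask, "BinaryFDMask")) maskMatrix(mask) else mask
  stopifnot(is.logical(m), is.matrix(m))
  lab <- cc_label8(m)
  n <- attr(lab, "nComponents")
  sizes <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  list(labels = lab, sizesPx = as.integer(sizes), n = as.integer(n))
}

#' Compute per-eye flow-deficit metrics
#'
#' Computes the four per-eye statistics of a binarized slab: FD% (percentage
#' of all image pixels classified as deficit), number of 8-connected deficit
#' components, mean component area in square microns, and total deficit area
#' in square millimetres. Areas are pixel counts scaled by the squared pixel
#' pitch, so `nFD * meanFDSizeUm2` equals the total deficit area in um^2
#' exactly.
#'
#' @param mask a [BinaryFDMask-class].
#' @param pitchUm physical pixel size in microns (defaults to the mask's).
#' @param radiusPx threshold window radius recorded on the result (defaults
#'   to the mask's `params$radiusPx` when present).
#' @return An [FDMetrics-class].
#' @examples
#' m <- matrix(FALSE, 512, 512); m[1:3, 1:3] <- TRUE
#' met <- computeMetrics(binaryFDMask(m))
#' meanFDSizeUm2(met)  # 9 * (3000/512)^2
#' @export
computeMetrics <- function(mask, pitchUm = pixelPitchUm(mask),
                           radiusPx = NA_real_) {
  stopifnot(is(mask, "BinaryFDMask"))
  if (!is.finite(pitchUm) || pitchUm <= 0)
    stop("'pitchUm' must be a positive number")
  if (is.na(radiusPx) && !is.null(mask@params$radiusPx))
    radiusPx <- mask@params$radiusPx
  comp <- labelComponents(mask)
  m <- maskMatrix(mask)
  nDeficit <- sum(m)
  totalUm2 <- sum(comp$sizesPx) * pitchUm^2
  new("FDMetrics",
      fdPercent = 100 * nDeficit / length(m),
      nFD = comp$n,
      meanFDSizeUm2 = if (comp$n > 0L) totalUm2 / comp$n else NaN,
      totalFDAreaMm2 = totalUm2 / 1e6,
      componentSizesPx = comp$sizesPx,
      radiusPx = as.numeric(radiusPx),
      pixelPitchUm = pitchUm,
      eyeId = eyeId(mask))
}

#' Convert a window radius from pixels to microns
#'
#' Uses the centre-pixel-inclusive convention: the physical radius of a
#' discrete circular window of radius `radiusPx` is
#' `(radiusPx + 0.5) * pitchUm`, i.e. it extends half a pixel beyond the
#' centre of the outermost included pixel. With the default pitch of a
#' 3 x 3 mm scan sampled at 512 x 512 (3000/512 um/px) this yields
#' 26.37, 49.80, 61.52 and 90.82 um for radii 4, 8, 10 and 15 px.
#'
#' @param radiusPx window radius in pixels (>= 1).
#' @param pitchUm physical pixel size in microns.
#' @return Physical radius in microns.
#' @examples
#' round(radiusPxToUm(15), 2)  # 90.82
#' @export
radiusPxToUm <- function(radiusPx, pitchUm = 3000 / 512) {
  stopifnot(all(radiusPx >= 1), pitchUm > 0)
  (radiusPx + 0.5) * pitchUm
}

#' Per-eye flow-deficit metrics as a data.frame row
#'
#' @param metrics an [FDMetrics-class].
#' @return One-row data.frame with columns `eye_id`, `radius_px`,
#'   `fd_percent`, `n_fd`, `mean_fd_size_um2`, `total_fd_area_mm2`.
#' @export
metricsAsRow <- function(metrics) {
  stopifnot(is(metrics, "FDMetrics"))
  data.frame(eye_id = eyeId(metrics),
             radius_px = metrics@radiusPx,
             fd_percent = fdPercent(metrics),
             n_fd = nFD(metrics),
             mean_fd_size_um2 = meanFDSizeUm2(metrics),
             total_fd_area_mm2 = totalFDAreaMm2(metrics),
             stringsAsFactors = FALSE)
}

#' Window-radius sensitivity analysis
#'
#' Re-binarizes a set of compensated slabs at each window radius and
#' summarizes the cohort distribution of FD%, deficit count and mean deficit
#' size per radius. Smaller windows adapt to finer structure and fragment
#' the deficit map into more, smaller components; the per-radius table makes
#' this dependence explicit.
#'
#' @param images list of compensated [EnFaceImage-class] objects (one per
#'   eye).
#' @param radii numeric vector of window radii in pixels.
#' @param params a [PhansalkarParams-class] supplying the formula constants;
#'   its radius is overridden by each element of `radii`.
#' @return A list with `perRadius` (one row per radius: cohort mean and SD
#'   of `fd_percent`, `n_fd` and `mean_fd_size_um2`, plus the physical
#'   radius in microns) and `perEye` (one row per eye and radius, as
#'   [metricsAsRow()]).
#' @examples
#' imgs <- list(enFaceImage(matrix(runif(4096), 64, 64)))
#' sens <- sensitivityAnalysis(imgs, radii = c(2, 4))
#' sens$perRadius
#' @export
sensitivityAnalysis <- function(images, radii = c(4, 8, 10, 15),
                                params = phansalkarParams()) {
  if (length(images) < 1L) stop("need at least one image")
  if (length(radii) < 1L || any(radii < 1)) stop("need at least one radius >= 1")
  perEye <- do.call(rbind, lapply(radii, function(r) {
    pr <- phansalkarParams(radiusPx = r, k = params@k, rNorm = params@rNorm,
                           p = params@p, q = params@q)
    do.call(rbind, lapply(images, function(img) {
      metricsAsRow(computeMetrics(binarize(img, pr)))
    }))
  }))
  perRadius <- do.call(rbind, lapply(radii, function(r) {
    sub <- perEye[perEye$radius_px == r, , drop = FALSE]
    data.frame(radius_px = r,
               radius_um = radiusPxToUm(r, pixelPitchUm(images[[1]])),
               n_eyes = nrow(sub),
               fd_percent_mean = mean(sub$fd_percent),
               fd_percent_sd = sd(sub$fd_percent),
               n_fd_mean = mean(sub$n_fd),
               n_fd_sd = sd(sub$n_fd),
               mean_fd_size_um2_mean = mean(sub$mean_fd_size_um2),
               mean_fd_size_um2_sd = sd(sub$mean_fd_size_um2))
  }))
  list(perRadius = perRadius, perEye = perEye)
}
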