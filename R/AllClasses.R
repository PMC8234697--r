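#' EnFaceImage: a grayscale en face OCTA slab
#'
#' One en face slab (flow or structure signal) of a macular OCTA scan, stored
#' as an intensity matrix normalized to \[0, 1\] together with its physical
#' pixel pitch. Flow and structure slabs of the same eye must share
#' dimensions and pitch so that they can be combined pixelwise.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\] (rows = image rows,
#'   origin top-left).
#' @slot pixelPitchUm physical size of one pixel in microns; the default
#'   3000/512 corresponds to a 3 x 3 mm scan sampled at 512 x 512.
#' @slot modality `"flow"` or `"structure"`.
#' @slot eyeId opaque eye identifier.
#' @slot sourceBitDepth bit depth of the source raster (8 or 16).
#'
#' @seealso [enFaceImage()], [readEnface()]
#' @exportClass EnFaceImage
setClass("EnFaceImage",
  representation(
    pixels = "matrix",
    pixelPitchUm = "numeric",
    modality = "character",
    eyeId = "character",
    sourceBitDepth = "integer"
  ),
  prototype(
    pixelPitchUm = 3000 / 512,
    modality = "flow",
    eyeId = "",
    sourceBitDepth = 8L
  )
)

setValidity("EnFaceImage", function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.numeric(px)) msg <- c(msg, "'pixels' must be a numeric matrix")
  if (nrow(px) < 1L || ncol(px) < 1L)
    msg <- c(msg, "image dimensions must be at least 1 x 1")
  if (anyNA(px) || (length(px) && (min(px) < 0 || max(px) > 1)))
    msg <- c(msg, "all intensities must be finite and in [0, 1]")
  if (length(object@pixelPitchUm) != 1L || !is.finite(object@pixelPitchUm) ||
      object@pixelPitchUm <= 0)
    msg <- c(msg, "'pixelPitchUm' must be a single positive number")
  if (!object@modality %in% c("flow", "structure"))
    msg <- c(msg, "'modality' must be \"flow\" or \"structure\"")
  if (!object@sourceBitDepth %in% c(8L, 16L))
    msg <- c(msg, "'sourceBitDepth' must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' Construct an EnFaceImage
#'
#' @param pixels numeric matrix with values in \[0, 1\].
#' @param pixelPitchUm physical pixel size in microns (default 3000/512).
#' @param modality `"flow"` or `"structure"`.
#' @param eyeId eye identifier string.
#' @param sourceBitDepth integer, 8 or 16.
#' @return An [EnFaceImage-class] object.
#' @examples
#' img <- enFaceImage(matrix(runif(64), 8, 8), modality = "flow")
#' dim(img)
#' @export
enFaceImage <- function(pixels, pixelPitchUm = 3000 / 512,
                        modality = c("flow", "structure"),
                        eyeId = "", sourceBitDepth = 8L) {
  modality <- match.arg(modality)
  new("EnFaceImage", pixels = pixels, pixelPitchUm = pixelPitchUm,
      modality = modality, eyeId = as.character(eyeId),
      sourceBitDepth = as.integer(sourceBitDepth))
}

#' PhansalkarParams: parameters of the Phansalkar local threshold
#'
#' The threshold at a pixel is `T = m * (1 + p * exp(-q * m) + k * (s/r - 1))`
#' where `m` and `s` are the mean and population standard deviation of the
#' intensities in the circular window of radius `radiusPx` centred on the
#' pixel (boundaries handled by reflection), and `r` is the normalization
#' constant `rNorm` of the dynamic range. `k`, `rNorm`, `p`, `q` default to
#' the original publication's values for low-contrast images.
#'
#' @slot radiusPx circular window radius in pixels (default 15).
#' @slot k sensitivity weight of the standard-deviation term (default 0.25).
#' @slot rNorm dynamic-range normalization of sigma (default 0.5).
#' @slot p amplitude of the low-mean exponential boost (default 2).
#' @slot q decay rate of the exponential boost (default 10).
#' @seealso [binarize()], [phansalkarThreshold()]
#' @exportClass PhansalkarParams
setClass("PhansalkarParams",
  representation(radiusPx = "numeric", k = "numeric", rNorm = "numeric",
                 p = "numeric", q = "numeric"),
  prototype(radiusPx = 15, k = 0.25, rNorm = 0.5, p = 2, q = 10)
)

setValidity("PhansalkarParams", function(object) {
  msg <- character()
  if (object@radiusPx < 1) msg <- c(msg, "'radiusPx' must be >= 1")
  if (object@rNorm <= 0) msg <- c(msg, "'rNorm' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct PhansalkarParams
#'
#' @param radiusPx window radius in pixels.
#' @param k,rNorm,p,q formula constants; see [PhansalkarParams-class].
#' @return A [PhansalkarParams-class] object.
#' @examples
#' phansalkarParams(radiusPx = 4)
#' @export
phansalkarParams <- function(radiusPx = 15, k = 0.25, rNorm = 0.5,
                             p = 2, q = 10) {
  new("PhansalkarParams", radiusPx = radiusPx, k = k, rNorm = rNorm,
      p = p, q = q)
}

#' CompensationParams: parameters of the drusen-shadow compensation
#'
#' @slot blurSigmaPx standard deviation (pixels) of the Gaussian smoothing
#'   applied to the inverted structure slab before multiplication (default 2).
#' @slot rescale post-multiplication normalization policy; `"minmax"` rescales
#'   the product to span \[0, 1\].
#' @seealso [compensate()]
#' @exportClass CompensationParams
setClass("CompensationParams",
  representation(blurSigmaPx = "numeric", rescale = "character"),
  prototype(blurSigmaPx = 2, rescale = "minmax")
)

setValidity("CompensationParams", function(object) {
  msg <- character()
  if (object@blurSigmaPx < 0) msg <- c(msg, "'blurSigmaPx' must be >= 0")
  if (!object@rescale %in% "minmax")
    msg <- c(msg, "'rescale' must be \"minmax\"")
  if (length(msg)) msg else TRUE
})

#' Construct CompensationParams
#'
#' @param blurSigmaPx Gaussian sigma in pixels (>= 0).
#' @param rescale normalization policy, currently `"minmax"`.
#' @return A [CompensationParams-class] object.
#' @examples
#' compensationParams(blurSigmaPx = 2)
#' @export
compensationParams <- function(blurSigmaPx = 2, rescale = "minmax") {
  new("CompensationParams", blurSigmaPx = blurSigmaPx, rescale = rescale)
}

#' BinaryFDMask: per-pixel flow-deficit classification
#'
#' Logical matrix on the same grid as the source slab; `TRUE` marks a
#' flow-deficit (black) pixel, `FALSE` a flow (white) pixel.
#'
#' @slot mask logical matrix, `TRUE` = flow deficit.
#' @slot pixelPitchUm physical pixel size in microns.
#' @slot params list echoing the thresholding parameters used.
#' @slot eyeId source eye identifier.
#' @seealso [binarize()], [writeMask()]
#' @exportClass BinaryFDMask
setClass("BinaryFDMask",
  representation(mask = "matrix", pixelPitchUm = "numeric",
                 params = "list", eyeId = "character"),
  prototype(pixelPitchUm = 3000 / 512, params = list(), eyeId = "")
)

setValidity("BinaryFDMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "'mask' must be logical")
  if (anyNA(object@mask)) msg <- c(msg, "'mask' must not contain NA")
  if (nrow(object@mask) < 1L || ncol(object@mask) < 1L)
    msg <- c(msg, "mask dimensions must be at least 1 x 1")
  if (length(object@pixelPitchUm) != 1L || object@pixelPitchUm <= 0)
    msg <- c(msg, "'pixelPitchUm' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryFDMask
#'
#' @param mask logical matrix, `TRUE` = flow deficit.
#' @param pixelPitchUm physical pixel size in microns.
#' @param params list of thresholding parameters (metadata only).
#' @param eyeId source eye identifier.
#' @return A [BinaryFDMask-class] object.
#' @examples
#' binaryFDMask(matrix(c(TRUE, FALSE), 2, 2))
#' @export
binaryFDMask <- function(mask, pixelPitchUm = 3000 / 512, params = list(),
                         eyeId = "") {
  new("BinaryFDMask", mask = mask, pixelPitchUm = pixelPitchUm,
      params = params, eyeId = as.character(eyeId))
}

#' FDMetrics: per-eye flow-deficit statistics
#'
#' The four per-eye summary statistics of a binarized choriocapillaris slab,
#' plus the underlying component sizes: percentage of image area that is
#' flow deficit, number of 8-connected deficit components, mean component
#' area in square microns, and total deficit area in square millimetres.
#'
#' @slot fdPercent percentage of image area classified as flow deficit.
#' @slot nFD integer number of 8-connected deficit components.
#' @slot meanFDSizeUm2 mean component area (um^2); `NaN` when `nFD == 0`.
#' @slot totalFDAreaMm2 summed deficit area (mm^2).
#' @slot componentSizesPx integer vector of component pixel counts.
#' @slot radiusPx threshold window radius used to produce the mask.
#' @slot pixelPitchUm physical pixel size in microns.
#' @slot eyeId source eye identifier.
#' @seealso [computeMetrics()]
#' @exportClass FDMetrics
setClass("FDMetrics",
  representation(fdPercent = "numeric", nFD = "integer",
                 meanFDSizeUm2 = "numeric", totalFDAreaMm2 = "numeric",
                 componentSizesPx = "integer", radiusPx = "numeric",
                 pixelPitchUm = "numeric", eyeId = "character")
)

setValidity("FDMetrics", function(object) {
  msg <- character()
  if (object@fdPercent < 0 || object@fdPercent > 100)
    msg <- c(msg, "'fdPercent' must lie in [0, 100]")
  if (object@nFD != length(object@componentSizesPx))
    msg <- c(msg, "'nFD' must equal length(componentSizesPx)")
  totUm2 <- sum(object@componentSizesPx) * object@pixelPitchUm^2
  if (abs(totUm2 / 1e6 - object@totalFDAreaMm2) > 1e-9 * max(1, totUm2 / 1e6))
    msg <- c(msg, "'totalFDAreaMm2' inconsistent with component sizes")
  if (object@nFD > 0L &&
      abs(object@meanFDSizeUm2 * object@nFD - totUm2) > 1e-6 * max(1, totUm2))
    msg <- c(msg, "'meanFDSizeUm2' inconsistent with total area")
  if (length(msg)) msg else TRUE
})
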