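#' Accessors for ccfd classes
#'
#' Accessor generics for the image, mask and metrics classes. `pixels()`
#' returns the intensity matrix of an [EnFaceImage-class]; `maskMatrix()` the
#' logical matrix of a [BinaryFDMask-class] (`TRUE` = flow deficit);
#' `pixelPitchUm()`, `modality()` and `eyeId()` return the physical pitch,
#' slab modality and eye identifier; `fdPercent()`, `nFD()`,
#' `meanFDSizeUm2()`, `totalFDAreaMm2()` and `componentSizesPx()` return the
#' per-eye flow-deficit statistics of an [FDMetrics-class].
#'
#' @param x an object of the appropriate class.
#' @return The slot value.
#' @name accessors
#' @examples
#' img <- enFaceImage(matrix(0.5, 4, 4))
#' pixelPitchUm(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelPitchUm", function(x) standardGeneric("pixelPitchUm"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("fdPercent", function(x) standardGeneric("fdPercent"))
#' @rdname accessors
#' @export
setGeneric("nFD", function(x) standardGeneric("nFD"))
#' @rdname accessors
#' @export
setGeneric("meanFDSizeUm2", function(x) standardGeneric("meanFDSizeUm2"))
#' @rdname accessors
#' @export
setGeneric("totalFDAreaMm2", function(x) standardGeneric("totalFDAreaMm2"))
#' @rdname accessors
#' @export
setGeneric("componentSizesPx", function(x) standardGeneric("componentSizesPx"))

#' @rdname accessors
#' @export
setMethod("pixels", "EnFaceImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixelPitchUm", "EnFaceImage", function(x) x@pixelPitchUm)
#' @rdname accessors
#' @export
setMethod("modality", "EnFaceImage", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("eyeId", "EnFaceImage", function(x) x@eyeId)

#' @rdname accessors
#' @export
setMethod("maskMatrix", "BinaryFDMask", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("pixelPitchUm", "BinaryFDMask", function(x) x@pixelPitchUm)
#' @rdname accessors
#' @export
setMethod("eyeId", "BinaryFDMask", function(x) x@eyeId)

#' @rdname accessors
#' @export
setMethod("fdPercent", "FDMetrics", function(x) x@fdPercent)
#' @rdname accessors
#' @export
setMethod("nFD", "FDMetrics", function(x) x@nFD)
#' @rdname accessors
#' @export
setMethod("meanFDSizeUm2", "FDMetrics", function(x) x@meanFDSizeUm2)
#' @rdname accessors
#' @export
setMethod("totalFDAreaMm2", "FDMetrics", function(x) x@totalFDAreaMm2)
#' @rdname accessors
#' @export
setMethod("componentSizesPx", "FDMetrics", function(x) x@componentSizesPx)
#' @rdname accessors
#' @export
setMethod("pixelPitchUm", "FDMetrics", function(x) x@pixelPitchUm)
#' @rdname accessors
#' @export
setMethod("eyeId", "FDMetrics", function(x) x@eyeId)

#' @describeIn EnFaceImage-class image dimensions (rows, columns).
#' @param x an `EnFaceImage`.
#' @export
setMethod("dim", "EnFaceImage", function(x) dim(x@pixels))

#' @describeIn BinaryFDMask-class mask dimensions (rows, columns).
#' @param x a `BinaryFDMask`.
#' @export
setMethod("dim", "BinaryFDMask", function(x) dim(x@mask))

setMethod("show", "EnFaceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("EnFaceImage [%s] %d x %d px, pitch %.3f um/px (%.2f x %.2f mm)\n",
              object@modality, d[1], d[2], object@pixelPitchUm,
              d[1] * object@pixelPitchUm / 1000, d[2] * object@pixelPitchUm / 1000))
  if (nzchar(object@eyeId)) cat("  eye:", object@eyeId, "\n")
  cat(sprintf("  intensity range [%.4f, %.4f], source depth %d-bit\n",
              min(object@pixels), max(object@pixels), object@sourceBitDepth))
})

setMethod("show", "BinaryFDMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryFDMask %d x %d px, %.2f%% flow deficit\n",
              d[1], d[2], 100 * mean(object@mask)))
  if (nzchar(object@eyeId)) cat("  eye:", object@eyeId, "\n")
})

setMethod("show", "FDMetrics", function(object) {
  cat("FDMetrics",
      if (nzchar(object@eyeId)) paste0("(eye ", object@eyeId, ")"), "\n")
  cat(sprintf("  FD%%:            %.2f\n", object@fdPercent))
  cat(sprintf("  FD count:       %d\n", object@nFD))
  cat(sprintf("  mean FD size:   %.2f um^2\n", object@meanFDSizeUm2))
  cat(sprintf("  total FD area:  %.4f mm^2\n", object@totalFDAreaMm2))
  cat(sprintf("  (radius %g px, pitch %.3f um/px)\n",
              object@radiusPx, object@pixelPitchUm))
})

setMethod("show", "PhansalkarParams", function(object) {
  cat(sprintf("PhansalkarParams: radius %g px, k=%g, r=%g, p=%g, q=%g\n",
              object@radiusPx, object@k, object@rNorm, object@p, object@q))
})

setMethod("show", "CompensationParams", function(object) {
  cat(sprintf("CompensationParams: blur sigma %g px, rescale=%s\n",
              object@blurSigmaPx, object@rescale))
})
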