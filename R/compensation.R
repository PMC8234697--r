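#' Invert an en face slab
#'
#' Replaces every intensity `v` by `1 - v` (the analogue of Fiji's
#' \dQuote{Invert}), preserving dimensions, pitch and metadata. Under drusen
#' the structure slab darkens, so its inverse brightens exactly there; this
#' is the first step of the shadow compensation.
#'
#' @param image an [EnFaceImage-class].
#' @return The inverted [EnFaceImage-class].
#' @examples
#' img <- enFaceImage(matrix(0.25, 4, 4))
#' pixels(invertImage(img))[1, 1]  # 0.75
#' @export
invertImage <- function(image) {
  stopifnot(is(image, "EnFaceImage"))
  image@pixels <- 1 - image@pixels
  validObject(image)
  image
}

# index into 1..n with symmetric (edge-repeating) reflection
.reflectIdx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# sampled, truncated (4 sigma), normalized 1-D Gaussian kernel
.gaussKernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian blur of an image or matrix
#'
#' Separable 2-D Gaussian convolution with a sampled kernel truncated at
#' 4 sigma and reflective (symmetric, edge-repeating) boundary handling.
#' Reflection avoids the artificial darkening of frame edges that would
#' inflate flow-deficit percentages there. `sigmaPx = 0` returns the input
#' unchanged.
#'
#' @param x an [EnFaceImage-class] or a numeric matrix.
#' @param sigmaPx Gaussian standard deviation in pixels (>= 0).
#' @return Blurred object of the same class as `x`; `EnFaceImage` results
#'   are clipped to \[0, 1\].
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 1
#' sum(gaussianBlur(m, 1))  # mass conserved: 1
#' @export
setGeneric("gaussianBlur", function(x, sigmaPx) standardGeneric("gaussianBlur"))

#' @rdname gaussianBlur
#' @export
setMethod("gaussianBlur", "matrix", function(x, sigmaPx) {
  if (length(sigmaPx) != 1L || is.na(sigmaPx) || sigmaPx < 0)
    stop("'sigmaPx' must be a single number >= 0")
  if (sigmaPx == 0) return(x)
  w <- .gaussKernel(sigmaPx)
  r <- (length(w) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  # rows
  xp <- x[.reflectIdx(seq.int(1L - r, nr + r), nr), , drop = FALSE]
  acc <- matrix(0, nr, nc)
  for (d in seq_along(w))
    acc <- acc + w[d] * xp[seq.int(d, nr + d - 1L), , drop = FALSE]
  # columns
  xp <- acc[, .reflectIdx(seq.int(1L - r, nc + r), nc), drop = FALSE]
  acc <- matrix(0, nr, nc)
  for (d in seq_along(w))
    acc <- acc + w[d] * xp[, seq.int(d, nc + d - 1L), drop = FALSE]
  acc
})

#' @rdname gaussianBlur
#' @export
setMethod("gaussianBlur", "EnFaceImage", function(x, sigmaPx) {
  x@pixels <- pmin(1, pmax(0, gaussianBlur(x@pixels, sigmaPx)))
  validObject(x)
  x
})

# min-max rescale to span [0, 1]; a constant input maps to all zeros
.rescaleMinMax <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(array(0, dim = dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Compensate drusen shadowing on a flow slab
#'
#' Multiplies the flow slab pixelwise by the Gaussian-smoothed inverse of
#' its co-registered structure slab, then min-max rescales the product to
#' \[0, 1\]. Because drusen attenuate both channels, the bright inverse of
#' the structure slab boosts the flow signal exactly where it was shadowed,
#' so flow deficits are not overcalled beneath drusen.
#'
#' @param flow [EnFaceImage-class] with modality `"flow"`.
#' @param structure [EnFaceImage-class] with modality `"structure"`, same
#'   dimensions and pitch as `flow`.
#' @param params a [CompensationParams-class]; `blurSigmaPx` controls the
#'   smoothing of the inverted structure slab.
#' @return Compensated flow [EnFaceImage-class], spanning \[0, 1\] unless
#'   the product is constant (then all zeros).
#' @examples
#' fl <- enFaceImage(matrix(runif(256), 16, 16), modality = "flow")
#' st <- enFaceImage(matrix(0.65, 16, 16), modality = "structure")
#' comp <- compensate(fl, st)
#' range(pixels(comp))
#' @export
compensate <- function(flow, structure, params = compensationParams()) {
  stopifnot(is(flow, "EnFaceImage"), is(structure, "EnFaceImage"),
            is(params, "CompensationParams"))
  if (modality(flow) != "flow" || modality(structure) != "structure")
    stop("'flow' must have modality \"flow\" and 'structure' modality ",
         "\"structure\"")
  if (!identical(dim(flow), dim(structure)))
    stop(sprintf("dimension mismatch: flow is %d x %d but structure is %d x %d",
                 dim(flow)[1], dim(flow)[2],
                 dim(structure)[1], dim(structure)[2]))
  if (!isTRUE(all.equal(pixelPitchUm(flow), pixelPitchUm(structure))))
    stop("flow and structure slabs must share the same pixel pitch")
  smoothedInverse <- gaussianBlur(1 - pixels(structure), params@blurSigmaPx)
  product <- pixels(flow) * smoothedInverse
  out <- flow
  out@pixels <- .rescaleMinMax(product)
  validObject(out)
  out
}
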