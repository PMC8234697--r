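#' Read an en face slab image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG raster and returns an
#' [EnFaceImage-class] with intensities normalized to \[0, 1\] by
#' `raw / (2^bitdepth - 1)`, independent of bit depth. Format is chosen by
#' file extension (`.tif`/`.tiff` or `.png`).
#'
#' @param path path to the raster file.
#' @param pixelPitchUm physical pixel size in microns; the default 3000/512
#'   corresponds to a 3 x 3 mm scan at 512 x 512.
#' @param modality `"flow"` or `"structure"`.
#' @param eyeId eye identifier recorded on the image.
#' @return An [EnFaceImage-class].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(matrix(runif(64), 8, 8), f, bits.per.sample = 8L)
#' img <- readEnface(f, modality = "flow", eyeId = "eye1")
#' @export
readEnface <- function(path, pixelPitchUm = 3000 / 512,
                       modality = c("flow", "structure"), eyeId = "") {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(path, info = TRUE)
    } else if (ext == "png") {
      png::readPNG(path, info = TRUE)
    } else {
      stop("unsupported image format '", ext, "' (use TIFF or PNG)")
    }
  }, error = function(e) stop("failed to read '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  if (length(dim(raw)) == 3L)
    stop("expected a single-channel image, got ", dim(raw)[3], " channels: ",
         path)
  bits <- if (ext == "png") {
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  } else {
    b <- attr(raw, "bits.per.sample")
    if (!is.null(b)) as.integer(b) else 8L
  }
  # readTIFF/readPNG already divide by (2^bits - 1); strip attributes
  px <- matrix(as.numeric(raw), nrow = nrow(raw), ncol = ncol(raw))
  enFaceImage(px, pixelPitchUm = pixelPitchUm, modality = modality,
              eyeId = eyeId, sourceBitDepth = bits)
}

#' Write a binary flow-deficit mask to an image file
#'
#' Flow-deficit pixels are written as 0 (black) and flow pixels as 255
#' (white), following the convention that deficits are contiguous black
#' pixel areas. A written mask read back with [readMask()] reproduces the
#' original exactly.
#'
#' @param mask a [BinaryFDMask-class].
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @examples
#' m <- binaryFDMask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' f <- tempfile(fileext = ".tif")
#' writeMask(m, f)
#' identical(maskMatrix(readMask(f)), maskMatrix(m))
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryFDMask"))
  raster <- matrix(as.numeric(!mask@mask), nrow(mask@mask), ncol(mask@mask))
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(raster, path, bits.per.sample = 8L)
    } else if (ext == "png") {
      png::writePNG(raster, path)
    } else {
      stop("unsupported image format '", ext, "' (use TIFF or PNG)")
    }
    TRUE
  }, error = function(e) stop("failed to write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a binary flow-deficit mask written by [writeMask()]
#'
#' @param path image path; pixels below half intensity are flow deficit.
#' @param pixelPitchUm physical pixel size in microns.
#' @param eyeId eye identifier.
#' @return A [BinaryFDMask-class].
#' @export
readMask <- function(path, pixelPitchUm = 3000 / 512, eyeId = "") {
  img <- readEnface(path, pixelPitchUm = pixelPitchUm, eyeId = eyeId)
  binaryFDMask(pixels(img) < 0.5, pixelPitchUm = pixelPitchUm, eyeId = eyeId)
}

.cohortRequired <- c("eye_id", "group", "age_years", "bcva_logmar",
                     "small_drusen", "large_drusen", "drusenoid_ped", "rpd",
                     "atrophy", "cmt_um", "ct_um")
.cohortFlags <- c("small_drusen", "large_drusen", "drusenoid_ped", "rpd",
                  "atrophy")

#' Validate a cohort table
#'
#' Checks the per-eye cohort schema: required columns present, unique
#' `eye_id`, `group` in `{non_neovascular, neovascular}`, binary flags coded
#' 0/1, and positive age, central macular thickness (CMT) and choroidal
#' thickness (CT).
#'
#' @param cohort a data.frame with one row per eye.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validateCohort <- function(cohort) {
  missing <- setdiff(.cohortRequired, names(cohort))
  if (length(missing))
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(cohort$eye_id))
    stop("duplicate eye_id in cohort table: ",
         paste(unique(cohort$eye_id[duplicated(cohort$eye_id)]),
               collapse = ", "))
  badGroup <- setdiff(unique(cohort$group),
                      c("non_neovascular", "neovascular"))
  if (length(badGroup))
    stop("invalid group value(s): ", paste(badGroup, collapse = ", "))
  for (fl in .cohortFlags) {
    v <- cohort[[fl]]
    if (!all(v %in% c(0, 1)))
      stop("flag column '", fl, "' must contain only 0/1, got: ",
           paste(unique(v[!v %in% c(0, 1)]), collapse = ", "))
  }
  if (nrow(cohort)) {
    if (any(cohort$age_years <= 0)) stop("age_years must be > 0")
    if (any(cohort$cmt_um <= 0)) stop("cmt_um must be > 0")
    if (any(cohort$ct_um <= 0)) stop("ct_um must be > 0")
  }
  cohort
}

#' Read a cohort table from CSV
#'
#' Reads a UTF-8 CSV with header whose columns follow the per-eye record
#' schema (`eye_id`, `group`, `age_years`, `bcva_logmar`, the five 0/1
#' drusen/atrophy flags, `cmt_um`, `ct_um`; extra columns such as `gender`
#' or precomputed flow-deficit metrics are kept). The table is validated
#' with [validateCohort()].
#'
#' @param path CSV file path.
#' @return A validated data.frame, one row per eye.
#' @examples
#' cohort <- neovascularReferenceCohort()
#' nrow(cohort)
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCohort(df)
}

#' Write a cohort table to CSV
#'
#' @param cohort a data.frame with one row per eye.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
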