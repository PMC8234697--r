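#' Reference cohort of eight neovascular fellow eyes
#'
#' Returns the packaged per-eye record of eight fellow eyes with subclinical
#' non-exudative macular neovascularization (gender, age, BCVA, the five
#' drusen/atrophy flags, CMT and CT), used in worked examples and as the
#' neovascular arm in group comparisons.
#'
#' @return A validated cohort data.frame with 8 rows, `group` =
#'   `"neovascular"`.
#' @examples
#' neo <- neovascularReferenceCohort()
#' sum(neo$drusenoid_ped)  # 7 of 8
#' @export
neovascularReferenceCohort <- function() {
  readCohort(system.file("extdata", "neovascular_eyes.csv",
                         package = "ccfd", mustWork = TRUE))
}

.readManifest <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest,
                                                          stringsAsFactors = FALSE)
  need <- c("eye_id", "flow_path", "structure_path")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(manifest) == 0L) stop("empty manifest")
  manifest
}

#' Run the full flow-deficit quantification pipeline
#'
#' For every eye in the manifest and every window radius: read the flow and
#' structure slabs, compensate drusen shadowing, binarize with the
#' Phansalkar threshold and compute flow-deficit metrics. Writes per-eye
#' metrics, a per-radius sensitivity summary and, when a cohort table is
#' supplied, the group-comparison, regression and log-log fit reports, plus
#' a machine-readable run manifest (package version, configuration and its
#' MD5 hash, seed). Per-eye read or processing failures are recorded and
#' skipped so one corrupt scan does not void a cohort run; outputs are
#' deterministic given inputs and configuration.
#'
#' @param manifest data.frame (or CSV path) with columns `eye_id`,
#'   `flow_path`, `structure_path`.
#' @param cohort optional cohort data.frame or CSV path with clinical
#'   covariates per eye; metric columns are attached from the main-radius
#'   results (by `eye_id`) before the statistics are computed.
#' @param radii window radii in pixels (default `c(4, 8, 10, 15)`).
#' @param compensation a [CompensationParams-class].
#' @param phansalkar a [PhansalkarParams-class] (constants; radius comes
#'   from `radii`).
#' @param outDir output directory, created if needed.
#' @param mainRadiusPx radius used for the cohort statistics (default 15).
#' @param pixelPitchUm physical pixel size of the input slabs.
#' @param seed integer recorded in the run manifest (the analysis itself is
#'   deterministic; randomness only enters synthetic input generation).
#' @return Invisibly, a list with `perEye`, `perRadius`, `table2`,
#'   `regressions`, `loglog`, `errors` and `files` (paths written).
#' @export
runPipeline <- function(manifest, cohort = NULL, radii = c(4, 8, 10, 15),
                        compensation = compensationParams(),
                        phansalkar = phansalkarParams(),
                        outDir, mainRadiusPx = 15,
                        pixelPitchUm = 3000 / 512, seed = 1L) {
  manifest <- .readManifest(manifest)
  if (length(radii) < 1L || any(radii < 1)) stop("'radii' must be positive")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  errors <- list()
  images <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$eye_id[i]
    res <- tryCatch({
      fl <- readEnface(manifest$flow_path[i], pixelPitchUm = pixelPitchUm,
                       modality = "flow", eyeId = id)
      st <- readEnface(manifest$structure_path[i],
                       pixelPitchUm = pixelPitchUm,
                       modality = "structure", eyeId = id)
      compensate(fl, st, compensation)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
      message("skipping eye ", id, ": ", conditionMessage(res))
    } else {
      images[[id]] <- res
    }
  }
  if (length(images) == 0L) stop("no eye could be processed")

  sens <- sensitivityAnalysis(images, radii = radii, params = phansalkar)
  perEyePath <- file.path(outDir, "per_eye_metrics.csv")
  write.csv(sens$perEye, perEyePath, row.names = FALSE)
  radiusPath <- file.path(outDir, "radius_summary.csv")
  write.csv(sens$perRadius, radiusPath, row.names = FALSE)
  files <- c(files, perEyePath, radiusPath)

  table2 <- NULL; regressions <- NULL; loglog <- NULL
  if (!is.null(cohort)) {
    if (is.character(cohort)) cohort <- readCohort(cohort)
    main <- sens$perEye[sens$perEye$radius_px == mainRadiusPx, , drop = FALSE]
    if (nrow(main)) {
      cohort <- merge(
        cohort[, setdiff(names(cohort),
                         c("fd_percent", "n_fd", "mean_fd_size_um2",
                           "total_fd_area_mm2")), drop = FALSE],
        main[, c("eye_id", "fd_percent", "n_fd", "mean_fd_size_um2",
                 "total_fd_area_mm2")],
        by = "eye_id")
    }
    if (nrow(cohort) == 0L) {
      message("cohort and manifest share no eye_id; skipping statistics")
    } else {
      if (all(c("non_neovascular", "neovascular") %in% cohort$group)) {
        table2 <- buildTable2(cohort)
        p1 <- file.path(outDir, "group_comparison_quantitative.csv")
        p2 <- file.path(outDir, "group_comparison_flags.csv")
        write.csv(table2$quantitative, p1, row.names = FALSE)
        write.csv(table2$flags, p2, row.names = FALSE)
        files <- c(files, p1, p2)
      }
      nonNeo <- cohort[cohort$group == "non_neovascular", , drop = FALSE]
      if (nrow(nonNeo) >= 10) {
        regressions <- do.call(rbind, lapply(
          c("fd_percent", "mean_fd_size_um2", "n_fd"), function(oc) {
            sub <- nonNeo[nonNeo[[oc]] > 0, , drop = FALSE]
            tryCatch(regressionScreen(sub, outcome = oc),
                     error = function(e) NULL)
          }))
        if (!is.null(regressions)) {
          p3 <- file.path(outDir, "regression_screen.csv")
          write.csv(regressions, p3, row.names = FALSE)
          files <- c(files, p3)
        }
      }
      ok <- nonNeo$n_fd > 0 & nonNeo$mean_fd_size_um2 > 0
      if (sum(ok) >= 3) {
        loglog <- loglogSizeNumberFit(nonNeo$n_fd[ok],
                                      nonNeo$mean_fd_size_um2[ok],
                                      nonNeo$eye_id[ok])
        p4 <- file.path(outDir, "loglog_fit.json")
        jsonlite::write_json(loglog, p4, auto_unbox = TRUE, digits = NA)
        files <- c(files, p4)
      }
    }
  }

  config <- list(radii = radii, mainRadiusPx = mainRadiusPx,
                 pixelPitchUm = pixelPitchUm, seed = as.integer(seed),
                 blurSigmaPx = compensation@blurSigmaPx,
                 rescale = compensation@rescale,
                 phansalkar = list(k = phansalkar@k, rNorm = phansalkar@rNorm,
                                   p = phansalkar@p, q = phansalkar@q))
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA)
  runManifest <- list(package = "ccfd",
                      version = as.character(utils::packageVersion("ccfd")),
                      config = config,
                      configMd5 = unname(tools::md5sum(cfgPath)),
                      nEyesProcessed = length(images),
                      nEyesFailed = length(errors),
                      failedEyes = names(errors))
  manPath <- file.path(outDir, "run_manifest.json")
  jsonlite::write_json(runManifest, manPath, auto_unbox = TRUE, digits = NA)
  files <- c(files, cfgPath, manPath)

  invisible(list(perEye = sens$perEye, perRadius = sens$perRadius,
                 table2 = table2, regressions = regressions, loglog = loglog,
                 errors = errors, files = files))
}

#' Write a synthetic cohort of scenes to disk with a manifest
#'
#' Generates `nEyes` synthetic scene pairs (see [generateScene()]), writes
#' flow/structure TIFFs and ground-truth masks under `outDir`, and returns
#' the manifest data.frame that [runPipeline()] consumes. Scene seeds are
#' derived as `seed + eye index`, so the whole set is reproducible from one
#' seed.
#'
#' @param nEyes number of scenes.
#' @param outDir output directory.
#' @param seed base integer seed.
#' @param ... further arguments passed to [generateScene()].
#' @return Manifest data.frame with `eye_id`, `flow_path`,
#'   `structure_path`, `truth_path` and `realized_fd_fraction`.
#' @export
writeSyntheticScenes <- function(nEyes, outDir, seed = 1, ...) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(nEyes), function(i) {
    id <- sprintf("scene%03d", i)
    sc <- generateScene(seed = seed + i, eyeId = id, ...)
    fp <- file.path(outDir, paste0(id, "_flow.tif"))
    sp <- file.path(outDir, paste0(id, "_structure.tif"))
    tp <- file.path(outDir, paste0(id, "_truth.tif"))
    tiff::writeTIFF(pixels(sc$flow), fp, bits.per.sample = 16L)
    tiff::writeTIFF(pixels(sc$structure), sp, bits.per.sample = 16L)
    writeMask(binaryFDMask(sc$truth$fdMask,
                           pixelPitchUm = pixelPitchUm(sc$flow),
                           eyeId = id), tp)
    data.frame(eye_id = id, flow_path = fp, structure_path = sp,
               truth_path = tp,
               realized_fd_fraction = sc$truth$realizedFdFraction,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  manifest
}
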