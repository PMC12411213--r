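## End-to-end pipeline: load -> field of view -> smooth -> skull strip ->
## register -> resample -> NWU, plus batch drivers used by the command-line
## interface.

#' Pipeline run configuration
#'
#' @param side ipsilateral side: `"auto"`, `"left"`, or `"right"`.
#' @param window inclusive HU window for density calculation.
#' @param smoothing_sigma_mm Gaussian sigma in mm; `NULL` = half the in-plane
#'   voxel size.
#' @param air_threshold HU threshold for field-of-view selection.
#' @param fov_margin crop margin in voxels.
#' @param bone_threshold,brain_window skull-stripping thresholds (HU).
#' @param registration a [registration_config()].
#' @param weight weighting rule for the weighted average NWU.
#' @param seed integer seed recorded with outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(side = "auto", window = c(20, 50),
                       smoothing_sigma_mm = NULL, air_threshold = -500,
                       fov_margin = 2L, bone_threshold = 300,
                       brain_window = c(0, 100),
                       registration = registration_config(),
                       weight = "anatomical", seed = 1L) {
  check_window(window)
  if (!side %in% c("auto", "left", "right")) {
    rlang::abort("side must be auto/left/right", class = "nwuct_parameter_error")
  }
  structure(list(side = side, window = window,
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 air_threshold = air_threshold, fov_margin = fov_margin,
                 bone_threshold = bone_threshold, brain_window = brain_window,
                 registration = registration, weight = weight,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; registration
#' settings live under a `registration:` block with the arguments of
#' [registration_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  reg <- do.call(registration_config, y$registration %||% list())
  y$registration <- NULL
  do.call(run_config, c(y, list(registration = reg)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full NWU pipeline on one volume
#'
#' Applies the preprocessing chain (field-of-view selection, Gaussian
#' smoothing, skull stripping, affine registration to the atlas, resampling
#' onto the atlas grid) and computes net water uptake over the ten ASPECTS
#' region pairs.
#'
#' @param vol a [ct_volume] in scanner space.
#' @param atlas a `region_atlas`.
#' @param config a [run_config()].
#' @return List with `result` (an `nwu_result`), `transform` (atlas-to-
#'   subject [affine_transform]), `volume_atlas` (the resampled volume), and
#'   `report` (crop bounds, brain voxel count, registration metric,
#'   convergence flag).
#' @export
nwu_pipeline <- function(vol, atlas, config = run_config()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(atlas, "region_atlas"))
  fov <- select_field_of_view(vol, config$air_threshold, config$fov_margin)
  sigma <- config$smoothing_sigma_mm %||% (0.5 * fov$volume$spacing[1])
  smoothed <- ct_smooth(fov$volume, sigma)
  brain <- skull_strip(smoothed, config$bone_threshold, config$brain_window)
  reg <- register_to_atlas(smoothed, brain, atlas, config = config$registration)
  vol_atlas <- resample_volume(smoothed, reg$transform, atlas$template)
  result <- compute_nwu(vol_atlas, atlas, side = config$side,
                        window = config$window, weight = config$weight)
  list(result = result,
       transform = reg$transform,
       volume_atlas = vol_atlas,
       report = list(crop_bounds = fov$crop_bounds,
                     brain_voxel_count = sum(brain$data),
                     registration_metric_final =
                       reg$report$registration_metric_final,
                     converged = reg$report$converged))
}

load_input_volume <- function(path) {
  if (dir.exists(path)) read_dicom_series(path) else read_nifti(path)
}

#' Batch NWU computation (CLI `compute`)
#'
#' Processes each input (NIfTI file or DICOM series directory) through
#' [nwu_pipeline()], writing a per-subject JSON result and one batch summary
#' CSV. Per-subject failures are logged and skipped; the exit code is
#' non-zero only when every input fails.
#'
#' @param inputs character vector of NIfTI paths and/or DICOM directories.
#' @param atlas a `region_atlas` or an atlas directory for [load_atlas()].
#' @param output_dir output directory.
#' @param config a [run_config()].
#' @return Invisibly, 0 if at least one subject succeeded, 1 otherwise.
#' @export
cmd_compute <- function(inputs, atlas, output_dir, config = run_config()) {
  if (is.character(atlas)) atlas <- load_atlas(atlas)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  summaries <- list()
  failures <- character(0)
  for (path in inputs) {
    subject <- sub("\\.nii(\\.gz)?$", "", basename(path))
    res <- tryCatch({
      t0 <- proc.time()[["elapsed"]]
      out <- nwu_pipeline(load_input_volume(path), atlas, config)
      elapsed <- proc.time()[["elapsed"]] - t0
      per <- tidy(out$result)
      jsonlite::write_json(
        list(subject = subject, input = path,
             ipsilateral_side = out$result$ipsilateral_side,
             average_nwu = out$result$average_nwu,
             weighted_average_nwu = out$result$weighted_average_nwu,
             regions_excluded = out$result$regions_excluded,
             per_region = per,
             transform = out$transform$matrix,
             report = out$report[c("brain_voxel_count",
                                   "registration_metric_final", "converged")],
             seconds = elapsed, seed = config$seed),
        file.path(output_dir, paste0(subject, "_nwu.json")),
        auto_unbox = TRUE, digits = NA)
      wide <- stats::setNames(as.list(per$nwu), paste0("nwu_", per$region))
      tibble::as_tibble(c(list(subject = subject,
                               side = out$result$ipsilateral_side),
                          wide,
                          list(average_nwu = out$result$average_nwu,
                               weighted_average_nwu =
                                 out$result$weighted_average_nwu,
                               converged = out$report$converged,
                               seconds = elapsed)))
    }, error = function(e) {
      message(sprintf("FAILED %s: %s", path, conditionMessage(e)))
      failures <<- c(failures, path)
      NULL
    })
    if (!is.null(res)) summaries[[subject]] <- res
  }
  if (length(summaries)) {
    utils::write.csv(dplyr::bind_rows(summaries),
                     file.path(output_dir, "nwu_summary.csv"),
                     row.names = FALSE)
  }
  if (length(failures)) {
    writeLines(failures, file.path(output_dir, "failures.log"))
  }
  invisible(if (length(summaries) > 0) 0L else 1L)
}

#' Generate a phantom scan (CLI `phantom`)
#'
#' @param spec a [phantom_spec()] or a YAML file with its fields (`lesions`,
#'   `side`, `artifacts`, `noise_sd`, `seed`).
#' @param atlas a `region_atlas` or atlas directory.
#' @param output_dir directory receiving `phantom.nii.gz` and
#'   `phantom_truth.json`.
#' @return Invisibly 0.
#' @export
cmd_phantom <- function(spec, atlas, output_dir) {
  if (is.character(atlas)) atlas <- load_atlas(atlas)
  if (is.character(spec)) {
    y <- yaml::read_yaml(spec)
    spec <- phantom_spec(lesions = y$lesions %||% list(),
                         side = y$side %||% "left",
                         artifacts = y$artifacts %||% list(),
                         noise_sd = y$noise_sd %||% 0,
                         seed = y$seed %||% 1L)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  ph <- generate_phantom(spec, atlas)
  write_nifti(ph$volume, file.path(output_dir, "phantom.nii.gz"))
  jsonlite::write_json(
    list(true_regional_nwu = as.list(ph$truth$true_regional_nwu),
         true_side = ph$truth$true_side,
         applied_pose = ph$truth$applied_pose$matrix,
         warnings = ph$truth$warnings,
         noise_sd = spec$noise_sd, seed = spec$seed),
    file.path(output_dir, "phantom_truth.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(0L)
}

#' Simulate a cohort table (CLI `cohort`)
#'
#' @param n number of subjects.
#' @param out_csv output CSV path.
#' @param model a [cohort_model()] or YAML file with its arguments.
#' @param seed integer seed.
#' @return Invisibly 0.
#' @export
cmd_cohort <- function(n, out_csv, model = cohort_model(), seed = 1L) {
  if (is.character(model)) model <- do.call(cohort_model, yaml::read_yaml(model))
  tab <- generate_cohort(n, model, seed)
  utils::write.csv(tab, out_csv, row.names = FALSE)
  invisible(0L)
}

#' Evaluate NWU-based vs ASPECTS-based outcome models (CLI `evaluate`)
#'
#' Fits two covariate-adjusted logistic models on a stratified 80:20 split —
#' one using average NWU, one using ASPECTS, both adjusted for age, NIHSS,
#' tPA and EVT — scores the held-out set, and compares the AUROCs with the
#' DeLong paired test. Writes a JSON result and a plain-text report.
#'
#' @param cohort a cohort tibble or CSV path with the documented schema.
#' @param output_dir output directory.
#' @param covariates adjustment covariates present in both models.
#' @param biomarker_a,biomarker_b the competing biomarker columns.
#' @param test_fraction,seed split settings.
#' @return Invisibly, the `model_comparison`.
#' @export
cmd_evaluate <- function(cohort, output_dir,
                         covariates = c("age", "nihss", "tpa", "evt"),
                         biomarker_a = "avg_nwu", biomarker_b = "aspects",
                         test_fraction = 0.2, seed = 1L) {
  if (is.character(cohort)) {
    cohort <- tibble::as_tibble(utils::read.csv(cohort))
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  cmp <- compare_models(cohort,
                        predictors_a = c(biomarker_a, covariates),
                        predictors_b = c(biomarker_b, covariates),
                        test_fraction = test_fraction, seed = seed)
  jsonlite::write_json(
    list(comparison = glance(cmp),
         model_a = list(biomarker = biomarker_a, terms = tidy(cmp$fit_a)),
         model_b = list(biomarker = biomarker_b, terms = tidy(cmp$fit_b))),
    file.path(output_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  fmt_fit <- function(fit, name) {
    td <- tidy(fit)
    c(sprintf("%s model", name),
      sprintf("  %-20s OR %6.2f  [%5.2f, %5.2f]  p = %.4g", td$term,
              td$odds.ratio, td$conf.low, td$conf.high, td$p.value))
  }
  writeLines(c(
    "Outcome model comparison (stratified 80:20 split)",
    sprintf("n_train = %d, n_test = %d, seed = %d",
            cmp$n_train, cmp$n_test, cmp$split_seed),
    "",
    fmt_fit(cmp$fit_a, paste0("A (", biomarker_a, ")")),
    "",
    fmt_fit(cmp$fit_b, paste0("B (", biomarker_b, ")")),
    "",
    sprintf("Test-set AUROC: A = %.3f, B = %.3f", cmp$auroc_a, cmp$auroc_b),
    sprintf("DeLong paired test: z = %.3f, two-sided p = %.3f",
            cmp$delong_z, cmp$delong_p)
  ), file.path(output_dir, "evaluation.txt"))
  invisible(cmp)
}
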