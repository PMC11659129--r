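# Volume I/O (NIfTI-1), pipeline configuration (YAML), and the end-to-end
# pipeline driver.

#' Read / write a NIfTI volume
#'
#' Thin wrappers over RNifti preserving voxel data bit-exactly and the
#' affine to floating precision. 4D series round-trip with their frame
#' count intact.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param data Numeric array (3D or 4D) for writing.
#' @param reference Optional RNifti image supplying header/affine.
#' @return `read_volume` returns a numeric array with attribute
#'   `"nifti_image"`; `write_volume` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "nifti_image") <- img
  arr
}

#' @rdname read_volume
#' @export
write_volume <- function(data, path, reference = NULL) {
  img <- if (is.null(reference)) RNifti::asNifti(data)
         else RNifti::asNifti(data, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (and validates) every knob of the end-to-end run: the
#' acquisition protocol, the synthetic-cohort settings, fitting options,
#' and statistics options. Can be read from a YAML file with
#' [read_pipeline_config()]; unknown keys are rejected.
#'
#' @param cohort A [cohort_config()].
#' @param models Character vector of models to fit (subset of
#'   `"tofts"`, `"etm"`, `"brix2c"`, `"ath"`, `"dp"`, `"iauc"`).
#' @param fit A [fit_options()].
#' @param aggregate_statistic ROI aggregation statistic, `"median"` or
#'   `"mean"`.
#' @param seed Integer seed for the synthetic subject.
#' @return List of class `dce_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            models = KINETIC_MODELS,
                            fit = fit_options(),
                            aggregate_statistic = "median",
                            seed = 1) {
  stopifnot(inherits(cohort, "dce_cohort_config"),
            inherits(fit, "dce_fit_options"))
  models <- match.arg(models, KINETIC_MODELS, several.ok = TRUE)
  aggregate_statistic <- match.arg(aggregate_statistic, c("median", "mean"))
  structure(list(cohort = cohort, models = models, fit = fit,
                 aggregate_statistic = aggregate_statistic,
                 seed = as.integer(seed)),
            class = "dce_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `protocol`, `cohort`, `models`, `fit`,
#' `stats`, `seed`; within each, only the arguments of the corresponding
#' constructor are accepted. Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("protocol", "cohort", "models", "fit", "stats", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  take <- function(x, fn) {
    x <- x %||% list()
    bad <- setdiff(names(x), names(formals(fn)))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    x
  }
  protocol <- do.call(acquisition_protocol, take(raw$protocol, acquisition_protocol))
  cohort_args <- take(raw$cohort, cohort_config)
  if (!is.null(cohort_args$grid)) cohort_args$grid <- as.integer(unlist(cohort_args$grid))
  cohort_args$protocol <- protocol
  cohort <- do.call(cohort_config, cohort_args)
  fit <- do.call(fit_options, take(raw$fit, fit_options))
  stats_args <- raw$stats %||% list()
  pipeline_config(cohort = cohort,
                  models = unlist(raw$models %||% KINETIC_MODELS),
                  fit = fit,
                  aggregate_statistic = stats_args$aggregate_statistic %||% "median",
                  seed = raw$seed %||% 1L)
}

#' Run the full pipeline on a synthetic subject
#'
#' Executes every stage in order: simulate the subject, estimate T1/M0
#' from the VFA series, convert the dynamic signal to concentration,
#' extract the AIF from the artery voxels, fit the requested kinetic
#' models voxel-wise (plus IAUC summaries), aggregate parameters over
#' ROIs, and compute the statistics report. A manifest records the seed,
#' configuration hash, and per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, NIfTI volumes, the ROI
#'   table, report CSVs and the manifest JSON are written there.
#' @return List of class `dce_pipeline_result`: `subject`, `t1_map`,
#'   `conc`, `aif`, `fits` (named list of `dce_param_maps`), `roi_table`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "dce_pipeline_config"))
  cc <- config$cohort
  p <- cc$protocol
  t <- protocol_times(p)
  log_stage <- function(...) message(sprintf(...))

  log_stage("stage simulate: grid %s, model %s, seed %d",
            paste(cc$grid, collapse = "x"), cc$model, config$seed)
  subject <- generate_subject(cc, seed = config$seed)
  tissue_mask <- subject$labels == 1L | subject$labels == 2L

  log_stage("stage t1map: %d flip angles", length(p$vfa_flips_deg))
  t1m <- vfa_t1_map(subject$vfa_series, p,
                    mask = subject$labels != 0L)

  log_stage("stage tissue-conc: %d frames", p$n_dynamics)
  cm <- concentration_map(subject$dynamic_series, t1m, p,
                          mask = subject$labels != 0L,
                          max_bad_frac = config$fit$max_bad_frac)

  log_stage("stage aif: %d artery voxels", sum(subject$labels == 3L))
  aif <- extract_aif(cm$conc, artery_mask = subject$labels == 3L, t = t,
                     hematocrit = p$hematocrit)

  fits <- list()
  voxel_tables <- list()
  for (m in setdiff(config$models, "iauc")) {
    log_stage("stage fit[%s]: %d voxels", m, sum(tissue_mask))
    pm <- fit_volume(m, cm$conc, t, aif, tissue_mask, options = config$fit)
    fits[[m]] <- pm
    log_stage("  fitted %d, valid %d (%s)", nrow(pm$table), sum(pm$table$valid),
              paste(sprintf("%s=%d", pm$exclusions$exclusion_reason,
                            pm$exclusions$n), collapse = ", "))
    voxel_tables[[m]] <- pm$table
  }
  if ("iauc" %in% config$models) {
    log_stage("stage fit[iauc]")
    voxel_tables$iauc <- iauc_volume(cm$conc, t, aif, tissue_mask)
  }

  log_stage("stage stats: aggregating ROIs (%s)", config$aggregate_statistic)
  roi_table <- build_roi_table(voxel_tables, subject$truth,
                               statistic = config$aggregate_statistic)
  report <- build_report(roi_table)
  dropped <- sum(!stats::complete.cases(
    roi_table[, setdiff(names(roi_table), c("roi_id", "subject_id", "tissue_class"))]))
  log_stage("stage stats: %d lesion + %d normal ROIs (%d with missing entries)",
            report$n_roi["lesion"], report$n_roi["normal"], dropped)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dcekin")),
    seed = config$seed,
    models = config$models,
    config_hash = rlang::hash(unclass_all(config)),
    n_voxels_fitted = vapply(fits, function(f) nrow(f$table), integer(1)),
    n_voxels_valid = vapply(fits, function(f) sum(f$table$valid), integer(1)),
    n_roi = as.list(report$n_roi),
    output_hash = rlang::hash(roi_table))

  result <- structure(list(subject = subject, t1_map = t1m, conc = cm,
                           aif = aif, fits = fits, roi_table = roi_table,
                           report = report, manifest = manifest),
                      class = "dce_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else unclass(x)
}

# Per-voxel IAUC summaries over a masked volume.
iauc_volume <- function(conc_4d, t, aif, mask) {
  d <- dim(conc_4d)
  idx <- which(mask != 0)
  mat <- matrix(conc_4d, nrow = prod(d[1:3]), ncol = d[4])
  arrival <- attr(aif, "bolus_arrival_index") %||% detect_bolus_arrival(aif$cp_mM)
  purrr::map_dfr(idx, function(i) {
    y <- mat[i, ]
    ok <- is.finite(y)
    row <- if (mean(!ok) > 0.1) {
      tibble::tibble(IAUC60 = NA_real_, IAUC90 = NA_real_,
                     IAUC60No = NA_real_, IAUC90No = NA_real_)
    } else {
      y[!ok] <- 0
      iauc(y, t = t, bolus_arrival_index = arrival, aorta = aif)
    }
    dplyr::mutate(row, model = "iauc", voxel = i,
                  valid = all(is.finite(unlist(row))),
                  exclusion_reason = ifelse(all(is.finite(unlist(row))),
                                            "none", "non_invertible_frames"))
  })
}

# Join per-model voxel tables with the truth table's ROI assignment and
# aggregate every parameter over ROIs.
build_roi_table <- function(voxel_tables, truth, statistic = "median") {
  key <- truth[, c("voxel", "roi_id", "tissue_class")]
  long <- purrr::map_dfr(names(voxel_tables), function(m) {
    tab <- voxel_tables[[m]]
    pars <- setdiff(names(tab), c("model", "voxel", "rss", "n_iter",
                                  "converged", "valid", "exclusion_reason"))
    tidyr::pivot_longer(
      tab[, c("voxel", "valid", pars)], dplyr::all_of(pars),
      names_to = "parameter", values_to = "value") |>
      dplyr::mutate(parameter = paste0(m, "_", .data$parameter))
  })
  long <- dplyr::inner_join(long, key, by = "voxel")
  agg <- purrr::map_dfr(
    split(long, long$parameter),
    function(g) dplyr::mutate(
      aggregate_roi(g, statistic = statistic),
      parameter = g$parameter[1]))
  tidyr::pivot_wider(
    agg[, c("roi_id", "tissue_class", "parameter", "value")],
    names_from = "parameter", values_from = "value")
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- result$subject
  write_volume(s$dynamic_series, file.path(out_dir, "dynamic.nii.gz"))
  for (i in seq_along(s$vfa_series)) {
    write_volume(s$vfa_series[[i]],
                 file.path(out_dir, sprintf("vfa_flip%02d.nii.gz",
                                            s$protocol$vfa_flips_deg[i])))
  }
  write_volume(array(as.numeric(s$labels), dim(s$labels)),
               file.path(out_dir, "labels.nii.gz"))
  for (m in names(result$fits)) {
    for (pn in names(result$fits[[m]]$maps)) {
      write_volume(result$fits[[m]]$maps[[pn]],
                   file.path(out_dir, sprintf("%s_%s.nii.gz", m, pn)))
    }
  }
  utils::write.csv(s$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(result$roi_table, file.path(out_dir, "roi_table.csv"),
                   row.names = FALSE)
  utils::write.csv(
    tibble::tibble(t_s = result$aif$t_s, cp_mM = result$aif$cp_mM),
    file.path(out_dir, "aif.csv"), row.names = FALSE)
  write_report(result$report, file.path(out_dir, "report"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
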