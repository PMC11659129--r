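# Cohort-level statistics report: per-parameter medians + U tests, ROC
# table, and the DP x ETM Spearman matrix.

#' Build the full cohort statistics report
#'
#' Input is an aggregated ROI table: one row per ROI with `roi_id`,
#' optional `subject_id`, `tissue_class` (`"lesion"`/`"normal"`), and one
#' column per (model, parameter) pair named `<model>_<parameter>` (e.g.
#' `tofts_Ktrans`, `dp_PS`). For each parameter column the report contains
#' the class medians and the Mann-Whitney U test, the ROC analysis with
#' Youden cutoff, and — when both DP and ETM columns are present — the
#' Spearman correlation matrix between the two models per tissue class.
#'
#' @param roi_table Aggregated ROI tibble (see above).
#' @param alpha Significance level for the U test flag (default 0.05).
#' @return Object of class `dce_stats_report`: list with `medians`,
#'   `roc`, `spearman` (possibly `NULL`), `n_roi` counts.
#' @export
build_report <- function(roi_table, alpha = 0.05) {
  stopifnot(is.data.frame(roi_table))
  if (!all(c("roi_id", "tissue_class") %in% names(roi_table))) {
    stop("roi_table needs roi_id and tissue_class columns", call. = FALSE)
  }
  meta <- c("roi_id", "subject_id", "tissue_class")
  params <- setdiff(names(roi_table), meta)
  params <- params[vapply(roi_table[params], is.numeric, logical(1))]
  if (length(params) == 0) stop("no parameter columns found", call. = FALSE)
  bad <- params[!grepl("^[a-z0-9]+_", params)]
  if (length(bad)) {
    stop("parameter columns must be named <model>_<parameter>; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  roi_table <- dplyr::arrange(roi_table, .data$roi_id)
  les <- roi_table[roi_table$tissue_class == "lesion", , drop = FALSE]
  nor <- roi_table[roi_table$tissue_class == "normal", , drop = FALSE]
  if (nrow(les) == 0 || nrow(nor) == 0) {
    stop("both tissue classes must be present", call. = FALSE)
  }
  has_data <- function(pc) {
    any(is.finite(les[[pc]])) && any(is.finite(nor[[pc]]))
  }
  medians <- purrr::map_dfr(params, function(pc) {
    if (!has_data(pc)) {
      message("parameter ", pc, " has no finite values in one class; ",
              "statistics set to NA")
      return(tibble::tibble(parameter = pc, model = sub("_.*$", "", pc),
                            median_lesion = NA_real_, median_normal = NA_real_,
                            U = NA_real_, p = NA_real_, significant = NA))
    }
    x <- les[[pc]][is.finite(les[[pc]])]
    y <- nor[[pc]][is.finite(nor[[pc]])]
    u <- mann_whitney_u(x, y)
    tibble::tibble(
      parameter = pc,
      model = sub("_.*$", "", pc),
      median_lesion = stats::median(x),
      median_normal = stats::median(y),
      U = u$U, p = u$p, significant = u$p <= alpha)
  })
  roc <- purrr::map_dfr(params, function(pc) {
    if (!has_data(pc)) {
      return(tibble::tibble(parameter = pc, auc = NA_real_, cutoff = NA_real_,
                            sensitivity = NA_real_, specificity = NA_real_,
                            accuracy = NA_real_, direction = NA_character_))
    }
    r <- roc_analysis(les[[pc]], nor[[pc]])
    dplyr::mutate(r, parameter = pc, .before = 1)
  })
  spearman <- NULL
  dp_cols <- grep("^dp_", params, value = TRUE)
  etm_cols <- grep("^etm_", params, value = TRUE)
  if (length(dp_cols) >= 1 && length(etm_cols) >= 1) {
    keys <- intersect(meta, names(roi_table))
    dp_tab <- dplyr::rename_with(
      roi_table[c(keys, dp_cols)], ~ sub("^dp_", "", .x), dplyr::all_of(dp_cols))
    etm_tab <- dplyr::rename_with(
      roi_table[c(keys, etm_cols)], ~ sub("^etm_", "", .x), dplyr::all_of(etm_cols))
    spearman <- tryCatch(
      spearman_matrix(dp_tab, etm_tab,
                      row_params = sub("^dp_", "", dp_cols),
                      col_params = sub("^etm_", "", etm_cols)),
      error = function(e) {
        message("Spearman block skipped: ", conditionMessage(e))
        NULL
      })
  }
  structure(list(
    medians = medians, roc = roc, spearman = spearman,
    n_roi = c(lesion = nrow(les), normal = nrow(nor)),
    alpha = alpha
  ), class = "dce_stats_report")
}

#' @export
print.dce_stats_report <- function(x, ...) {
  cat(sprintf("<dce_stats_report> %d lesion / %d normal ROIs, %d parameters\n",
              x$n_roi["lesion"], x$n_roi["normal"], nrow(x$medians)))
  eff <- x$roc$parameter[which(x$roc$auc > 0.8)]
  cat(sprintf("  %d parameters with AUC > 0.8%s\n", length(eff),
              if (length(eff)) paste0(": ", paste(utils::head(eff, 8), collapse = ", "),
                                      if (length(eff) > 8) ", ..." else "") else ""))
  invisible(x)
}

#' Write a statistics report to CSV/JSON files
#'
#' @param report A [build_report()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dce_stats_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    medians = file.path(dir, "medians.csv"),
    roc = file.path(dir, "roc.csv"),
    summary = file.path(dir, "summary.json"))
  utils::write.csv(report$medians, paths["medians"], row.names = FALSE)
  utils::write.csv(report$roc, paths["roc"], row.names = FALSE)
  if (!is.null(report$spearman)) {
    paths["spearman"] <- file.path(dir, "spearman.csv")
    utils::write.csv(report$spearman, paths["spearman"], row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_roi = as.list(report$n_roi),
         n_parameters = nrow(report$medians),
         auc_above_0.8 = report$roc$parameter[which(report$roc$auc > 0.8)]),
    paths["summary"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
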