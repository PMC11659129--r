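# broom-style tidiers and autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort kinetic fit
#'
#' @param x A [fit_kinetic()] object.
#' @param ... Unused.
#' @return Long tibble: identifier, `tissue_class` (if present),
#'   `parameter`, `estimate`, plus per-curve `rss`, `converged`, `valid`.
#' @export
#' @method tidy dce_fit
tidy.dce_fit <- function(x, ...) {
  res <- x$results
  meta <- intersect(c(x$id_col, "tissue_class", "rss", "converged", "valid",
                      "exclusion_reason"), names(res))
  pars <- setdiff(names(res), c(meta, "model", "n_iter"))
  tidyr::pivot_longer(res[, c(meta, pars)], dplyr::all_of(pars),
                      names_to = "parameter", values_to = "estimate")
}

#' Summarize a cohort kinetic fit in one row
#'
#' @param x A [fit_kinetic()] object.
#' @param ... Unused.
#' @return One-row tibble: model, number of curves, valid/converged
#'   counts, median residual sum of squares.
#' @export
#' @method glance dce_fit
glance.dce_fit <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    model = x$model,
    n_curves = nrow(r),
    n_converged = sum(r$converged),
    n_valid = sum(r$valid),
    n_excluded = sum(!r$valid),
    median_rss = stats::median(r$rss, na.rm = TRUE))
}

#' Plot fitted versus observed curves for a cohort fit
#'
#' @param object A [fit_kinetic()] object.
#' @param n_curves Number of curves to display (default 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dce_fit
autoplot.dce_fit <- function(object, n_curves = 6, ...) {
  ids <- utils::head(unique(object$data[[object$id_col]]), n_curves)
  obs <- dplyr::filter(object$data, .data[[object$id_col]] %in% ids)
  xy <- as_aif_xy(object$aif)
  fitted <- purrr::map_dfr(ids, function(id) {
    row <- object$results[object$results[[object$id_col]] == id, ]
    if (!isTRUE(row$converged[1])) return(NULL)
    free <- unlist(row[1, free_param_names(object$model)])
    tibble::tibble(!!object$id_col := id, t_s = xy$t,
                   conc = forward_model(object$model, xy$t, xy$cp, free))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t_s, y = .data$conc)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = fitted, color = "firebrick") +
    ggplot2::facet_wrap(object$id_col, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "concentration (mM)",
                  title = sprintf("%s model fits", object$model)) +
    ggplot2::theme_minimal()
}

#' Tidy a statistics report
#'
#' @param x A [build_report()] object.
#' @param ... Unused.
#' @return Per-parameter tibble joining class medians, U test and ROC
#'   metrics.
#' @export
#' @method tidy dce_stats_report
tidy.dce_stats_report <- function(x, ...) {
  dplyr::inner_join(x$medians, x$roc, by = "parameter")
}

#' Summarize a statistics report in one row
#'
#' @param x A [build_report()] object.
#' @param ... Unused.
#' @return One-row tibble with ROI counts, parameter count, and the number
#'   of parameters with AUC above 0.8.
#' @export
#' @method glance dce_stats_report
glance.dce_stats_report <- function(x, ...) {
  tibble::tibble(
    n_lesion_roi = unname(x$n_roi["lesion"]),
    n_normal_roi = unname(x$n_roi["normal"]),
    n_parameters = nrow(x$medians),
    n_significant = sum(x$medians$significant, na.rm = TRUE),
    n_auc_above_0.8 = sum(x$roc$auc > 0.8, na.rm = TRUE),
    best_parameter = x$roc$parameter[which.max(x$roc$auc)],
    best_auc = max(x$roc$auc))
}

#' Plot per-parameter AUC values of a statistics report
#'
#' @param object A [build_report()] object.
#' @param ... Unused.
#' @return A ggplot object (AUC per parameter, 0.8 effectiveness line).
#' @export
#' @method autoplot dce_stats_report
autoplot.dce_stats_report <- function(object, ...) {
  df <- dplyr::mutate(object$roc,
                      parameter = stats::reorder(.data$parameter, .data$auc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$parameter)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0.8, linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = "ROC AUC (lesion vs normal)", y = NULL,
                  title = "Discriminative power per kinetic parameter") +
    ggplot2::theme_minimal()
}

#' Plot one slice of a fitted parameter map
#'
#' @param maps A [fit_volume()] result (`dce_param_maps`).
#' @param parameter Parameter name (default the first map).
#' @param slice Slice index along z (default middle).
#' @return A ggplot raster of the requested slice.
#' @export
plot_parameter_map <- function(maps, parameter = NULL, slice = NULL) {
  stopifnot(inherits(maps, "dce_param_maps"))
  parameter <- parameter %||% names(maps$maps)[1]
  m <- maps$maps[[parameter]]
  if (is.null(m)) stop("unknown parameter: ", parameter, call. = FALSE)
  slice <- slice %||% ceiling(dim(m)[3] / 2)
  df <- expand.grid(x = seq_len(dim(m)[1]), y = seq_len(dim(m)[2]))
  df$value <- as.numeric(m[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s %s (slice %d)", maps$model, parameter, slice),
                  fill = parameter) +
    ggplot2::theme_minimal()
}
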