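# Group statistics: ROI aggregation, Mann-Whitney U, empirical ROC with
# Youden cutoff, Spearman correlation matrix with strength categories.

#' Aggregate a parameter over the voxels of each ROI
#'
#' Aggregates valid voxels only; an ROI is dropped (value `NA`,
#' `dropped = TRUE`) when fewer than `min_valid_frac` of its voxels carry a
#' valid value.
#'
#' @param data Tibble with columns `roi_id`, `value`, and optionally
#'   `valid` (defaults to `is.finite(value)`); extra grouping columns
#'   (e.g. `tissue_class`, `subject_id`) are carried through.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param min_valid_frac Minimum fraction of valid voxels (default 0.25).
#' @return Tibble with one row per ROI: carried columns, `value`,
#'   `n_voxels`, `n_valid`, `dropped`.
#' @examples
#' df <- tibble::tibble(roi_id = rep(1:2, each = 4), value = c(1, 3, 1, 3, 7, 7, 7, 7))
#' aggregate_roi(df)
#' @export
aggregate_roi <- function(data, statistic = c("median", "mean"),
                          min_valid_frac = 0.25) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("roi_id", "value") %in% names(data)))
  if (!"valid" %in% names(data)) data$valid <- is.finite(data$value)
  fn <- switch(statistic, median = stats::median, mean = mean)
  carry <- intersect(c("tissue_class", "subject_id"), names(data))
  out <- dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(c("roi_id", carry)))),
    n_voxels = dplyr::n(),
    n_valid = sum(.data$valid & is.finite(.data$value)),
    value = if (sum(.data$valid & is.finite(.data$value)) > 0) {
      fn(.data$value[.data$valid & is.finite(.data$value)])
    } else NA_real_,
    .groups = "drop")
  dplyr::mutate(out,
    dropped = .data$n_valid < min_valid_frac * .data$n_voxels | .data$n_valid == 0,
    value = ifelse(.data$dropped, NA_real_, .data$value))
}

#' Two-sided Mann-Whitney U test
#'
#' The statistic is `U = #\{(i, j): x_i > y_j\} + 0.5 #\{ties\}` (the
#' count convention for the first sample; `U = 0` when every `x` is below
#' every `y`). The p-value is exact whenever feasible — via the Wilcoxon
#' null distribution for tie-free data with `n_x n_y <= 400`, or by full
#' enumeration of group assignments for tied data when `choose(n_x + n_y,
#' n_x) <= 2e5` — and otherwise uses the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A one-row tibble with `U`, `p`, and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty", call. = FALSE)
  U <- u_stat(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx * ny <= 400) {
    # exact via the null distribution of U (tie-free)
    p <- 2 * min(stats::pwilcox(U, nx, ny), 1 - stats::pwilcox(U - 1, nx, ny))
    p <- min(1, p)
    method <- "exact"
  } else if (ties && choose(nx + ny, nx) <= 2e5) {
    pooled <- c(x, y)
    combs <- utils::combn(nx + ny, nx)
    us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    mu <- nx * ny / 2
    p <- min(1, mean(abs(us - mu) >= abs(U - mu) - 1e-12))
    method <- "exact-enumeration"
  } else {
    r <- rank(c(x, y))
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal-approximation"
  }
  tibble::tibble(U = U, p = p, method = method)
}

u_stat <- function(x, y) {
  r <- rank(c(x, y))
  rx <- sum(r[seq_along(x)])
  # rank-sum form; equals #{x_i > y_j} + 0.5 #{ties}
  rx - length(x) * (length(x) + 1) / 2
}

#' Empirical ROC analysis with Youden-index cutoff
#'
#' Builds the empirical ROC over all observed thresholds. The AUC uses the
#' rank (Mann-Whitney) formulation, which equals the trapezoid under the
#' empirical curve with ties counted half. Orientation is fixed
#' per-parameter so that AUC >= 0.5 (lesions are usually but not always
#' the higher-valued class); the direction used is reported. The cutoff
#' maximizes the Youden index `J = sensitivity + specificity - 1`; ties
#' are broken toward higher specificity. Accuracy is evaluated at the
#' chosen cutoff.
#'
#' @param lesion_vals,normal_vals Numeric parameter values per class
#'   (lesions are the positive class).
#' @return A one-row tibble: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `direction` (`">="` when high values call
#'   lesion, `"<="` otherwise). The ROC points are attached as attribute
#'   `"roc_points"`.
#' @examples
#' roc_analysis(rnorm(50, 2), rnorm(50, 0))
#' @export
roc_analysis <- function(lesion_vals, normal_vals) {
  x <- lesion_vals[is.finite(lesion_vals)]
  y <- normal_vals[is.finite(normal_vals)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  auc_raw <- u_stat(x, y) / (length(x) * length(y))  # P(lesion > normal) + 0.5 ties
  direction <- if (auc_raw >= 0.5) ">=" else "<="
  if (direction == "<=") { x <- -x; y <- -y }
  auc <- max(auc_raw, 1 - auc_raw)
  thr <- sort(unique(c(x, y)))
  stats_at <- function(cut) {
    sens <- mean(x >= cut)
    spec <- mean(y < cut)
    c(sens = sens, spec = spec, youden = sens + spec - 1)
  }
  m <- vapply(thr, stats_at, numeric(3))
  jmax <- max(m["youden", ])
  best <- which(m["youden", ] >= jmax - 1e-12)
  # ties toward higher specificity = larger threshold (oriented scale)
  pick <- best[which.max(m["spec", best])]
  cutoff <- thr[pick]
  sens <- unname(m["sens", pick]); spec <- unname(m["spec", pick])
  acc <- (sens * length(x) + spec * length(y)) / (length(x) + length(y))
  out <- tibble::tibble(
    auc = auc,
    cutoff = if (direction == "<=") -cutoff else cutoff,
    sensitivity = sens, specificity = spec, accuracy = acc,
    direction = direction)
  attr(out, "roc_points") <- tibble::tibble(
    threshold = if (direction == "<=") -thr else thr,
    sensitivity = m["sens", ], specificity = m["spec", ])
  out
}

spearman_category <- function(r) {
  a <- abs(r)
  dplyr::case_when(
    a > 0.8 ~ "strong",
    a > 0.5 ~ "moderate",
    a > 0.3 ~ "weak",
    TRUE ~ "none"
  )
}

#' Spearman correlation matrix between two models' parameters
#'
#' Computes Spearman's rho (average ranks for ties) and its p-value for
#' every pair of a row-model parameter and a column-model parameter,
#' separately per tissue class, and labels the correlation strength:
#' strong for `0.8 < |r| <= 1`, moderate for `0.5 < |r| <= 0.8`, weak for
#' `0.3 < |r| <= 0.5`, none for `|r| <= 0.3`.
#'
#' @param row_table,col_table Tibbles keyed by `roi_id` (and optionally
#'   `tissue_class`) with one column per parameter, e.g. DP parameters
#'   (`F`, `MTT`, `Vp`, `Ve`, `PS`, `E`) against ETM parameters
#'   (`Ktrans`, `Ve`, `Vp`, `Kep`).
#' @param row_params,col_params Parameter columns to correlate; default all
#'   shared numeric columns except keys.
#' @return Tibble with `tissue_class` (if present), `row_param`,
#'   `col_param`, `r`, `p`, `category`.
#' @export
spearman_matrix <- function(row_table, col_table,
                            row_params = NULL, col_params = NULL) {
  keys <- intersect(c("roi_id", "tissue_class", "subject_id"),
                    intersect(names(row_table), names(col_table)))
  if (!"roi_id" %in% keys) stop("both tables need a roi_id key", call. = FALSE)
  row_params <- row_params %||% setdiff(names(row_table), keys)
  col_params <- col_params %||% setdiff(names(col_table), keys)
  joined <- dplyr::inner_join(
    dplyr::rename_with(row_table, ~ paste0("row.", .x), dplyr::all_of(row_params)),
    dplyr::rename_with(col_table, ~ paste0("col.", .x), dplyr::all_of(col_params)),
    by = keys)
  split_by <- if ("tissue_class" %in% keys) "tissue_class" else character(0)
  groups <- if (length(split_by)) {
    dplyr::group_split(dplyr::group_by(joined, .data$tissue_class))
  } else list(joined)
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(row_params, function(rp) {
      purrr::map_dfr(col_params, function(cp) {
        a <- g[[paste0("row.", rp)]]
        b <- g[[paste0("col.", cp)]]
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) < 3) stop("fewer than 3 paired observations", call. = FALSE)
        ct <- suppressWarnings(
          stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
        tibble::tibble(
          tissue_class = if (length(split_by)) g$tissue_class[1] else NA_character_,
          row_param = rp, col_param = cp,
          r = unname(ct$estimate), p = ct$p.value,
          category = spearman_category(unname(ct$estimate)))
      })
    })
  })
}
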