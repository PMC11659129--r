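# Voxel-wise bounded least-squares fitting of the kinetic models, with
# multistart initialization, convergence flags, and physiological
# exclusion rules.

#' Fitting options
#'
#' @param bounds Optional named list overriding per-parameter bounds; each
#'   entry `c(lower, upper)`. Defaults per model via [default_bounds()].
#' @param n_starts_per_dim Start-lattice levels per free parameter (the
#'   lattice is capped at 27 starts; 4-parameter models use 2 levels plus
#'   the lattice midpoint).
#' @param ftol,ptol Function and step tolerances of the
#'   Levenberg-Marquardt optimizer.
#' @param max_iter Maximum optimizer iterations per start.
#' @param dp_segments Capillary segments for the DP model forward solver.
#' @param max_bad_frac Maximum tolerated fraction of missing
#'   (non-invertible) frames before a voxel is excluded.
#' @param limits Physiological limits, see [physiological_limits()].
#' @return List of class `dce_fit_options`.
#' @export
fit_options <- function(bounds = NULL, n_starts_per_dim = 3,
                        ftol = 1e-8, ptol = 1e-8, max_iter = 200,
                        dp_segments = 50, max_bad_frac = 0.1,
                        limits = physiological_limits()) {
  structure(list(bounds = bounds, n_starts_per_dim = n_starts_per_dim,
                 ftol = ftol, ptol = ptol, max_iter = max_iter,
                 dp_segments = dp_segments, max_bad_frac = max_bad_frac,
                 limits = limits),
            class = "dce_fit_options")
}

#' Default physiological limits for voxel exclusion
#'
#' Voxels whose fitted (free or derived) parameters exceed these limits are
#' excluded as non-physiological. Defaults: `Ve`, `Vp` in `[0, 100]`% with
#' `Ve + Vp <= 100`; `E < 100`%; `F <= 300` mL/min/100 mL;
#' `Ktrans <= 5`/min; `MTT <= 120` s; all rates/volumes non-negative.
#'
#' @param F_max,Ktrans_max,MTT_max,E_max Upper limits (units above).
#' @return Named list of limits.
#' @export
physiological_limits <- function(F_max = 300, Ktrans_max = 5, MTT_max = 120,
                                 E_max = 100) {
  list(F_max = F_max, Ktrans_max = Ktrans_max, MTT_max = MTT_max,
       E_max = E_max)
}

#' Check a full parameter set against physiological limits
#'
#' @param params One-row data frame or named vector of parameters (free +
#'   derived, as from [derive_params()]).
#' @param limits See [physiological_limits()].
#' @return List with `valid` (logical) and `reason` (`"none"` or
#'   `"non_physiological"`).
#' @examples
#' physiological_filter(derive_params("tofts", c(Ktrans = 0.2, Ve = 15)))
#' @export
physiological_filter <- function(params, limits = physiological_limits()) {
  if (is.data.frame(params)) {
    params <- params[, setdiff(names(params), "model"), drop = FALSE]
    params <- unlist(params[1, , drop = TRUE])
  }
  g <- function(nm) if (nm %in% names(params)) params[[nm]] else NULL
  bad <- FALSE
  num <- params[vapply(params, is.numeric, logical(1))]
  if (any(!is.finite(unlist(num)))) bad <- TRUE
  ve <- g("Ve"); vp <- g("Vp")
  if (!bad && !is.null(ve) && (ve < 0 || ve > 100)) bad <- TRUE
  if (!bad && !is.null(vp) && (vp < 0 || vp > 100)) bad <- TRUE
  if (!bad && !is.null(ve) && !is.null(vp) && ve + vp > 100 + 1e-9) bad <- TRUE
  if (!bad && !is.null(g("E")) && (g("E") < 0 || g("E") >= limits$E_max)) bad <- TRUE
  if (!bad && !is.null(g("F")) && (g("F") < 0 || g("F") > limits$F_max)) bad <- TRUE
  if (!bad && !is.null(g("PS")) && g("PS") < 0) bad <- TRUE
  if (!bad && !is.null(g("Ktrans")) &&
      (g("Ktrans") < 0 || g("Ktrans") > limits$Ktrans_max)) bad <- TRUE
  if (!bad && !is.null(g("MTT")) && (g("MTT") < 0 || g("MTT") > limits$MTT_max)) bad <- TRUE
  list(valid = !bad, reason = if (bad) "non_physiological" else "none")
}

#' Default fitting bounds per model
#'
#' @param model Kinetic model name.
#' @return Named list of `c(lower, upper)` per free parameter. Lower bounds
#'   on volume fractions are small positive numbers so rate constants stay
#'   defined.
#' @export
default_bounds <- function(model) {
  switch(model,
    tofts  = list(Ktrans = c(0, 5), Ve = c(0.05, 100)),
    etm    = list(Ktrans = c(0, 5), Ve = c(0.05, 100), Vp = c(0, 50)),
    brix2c = list(F = c(0.01, 300), PS = c(0, 300), Vp = c(0.01, 50),
                  Ve = c(0.05, 100)),
    ath    = list(F = c(0.01, 300), Tc = c(0, 60), E = c(0, 0.99),
                  Ve = c(0.05, 100)),
    dp     = list(F = c(0.01, 300), Vp = c(0.02, 50), Ve = c(0.05, 100),
                  PS = c(0, 300)),
    stop(sprintf("no fitting bounds for model '%s'", model), call. = FALSE)
  )
}

# Physiologically typical start levels per free parameter (soft-tissue
# perfusion ranges); the multistart lattice is built from these so at
# least one start sits within a factor of a few of any plausible voxel.
start_levels <- function(model, n_per_dim = 3) {
  three <- list(
    tofts  = list(Ktrans = c(0.03, 0.15, 0.7), Ve = c(4, 12, 35)),
    etm    = list(Ktrans = c(0.03, 0.15, 0.7), Ve = c(4, 12, 35),
                  Vp = c(0.3, 3, 10)),
    brix2c = list(F = c(8, 40), PS = c(2, 15), Vp = c(1, 8), Ve = c(4, 20)),
    ath    = list(F = c(12, 45), Tc = c(0.4, 5), E = c(0.08, 0.35),
                  Ve = c(4, 20)),
    dp     = list(F = c(8, 40), Vp = c(0.5, 5), Ve = c(4, 20),
                  PS = c(3, 20)))
  lv <- three[[model]]
  if (n_per_dim < 3) lv <- lapply(lv, function(x) x[seq_len(min(n_per_dim, length(x)))])
  lv
}

# Deterministic coarse start lattice: physiological levels clipped to the
# bounds, capped at 27 starts (4-parameter models use 2 levels per
# dimension plus the geometric midpoint).
start_lattice <- function(bounds, n_per_dim = 3, cap = 27, model = NULL) {
  levels <- if (!is.null(model)) start_levels(model, n_per_dim) else NULL
  if (is.null(levels)) {
    k <- length(bounds)
    npd <- if (n_per_dim^k > cap) max(2, floor(cap^(1 / k))) else n_per_dim
    levels <- lapply(bounds, function(b) {
      lo <- max(b[1], b[2] * 1e-4)
      exp(seq(log(lo), log(b[2] * 0.5), length.out = npd))
    })
  }
  levels <- purrr::imap(levels, function(l, nm) {
    b <- bounds[[nm]]
    unique(pmin(pmax(l, b[1]), b[2]))
  })
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(bounds)
  if (nrow(grid) < cap && all(lengths(levels) <= 2)) {
    mid <- vapply(levels, function(l) exp(mean(log(pmax(l, 1e-12)))), numeric(1))
    grid <- rbind(grid, as.list(mid))
  }
  utils::head(grid, cap)
}

#' Fit one kinetic model to one concentration curve
#'
#' Bounded least-squares minimization of the sum of squared differences
#' between the model curve and the observed concentrations, by
#' Levenberg-Marquardt from a fixed coarse lattice of starting values; the
#' best converged start wins. The result is flagged invalid when the fit
#' failed on every start, when too many frames are missing, or when the
#' full (free + derived) parameter set violates the physiological limits.
#'
#' @param model One of `"tofts"`, `"etm"`, `"brix2c"`, `"ath"`, `"dp"`.
#' @param conc Concentration curve (tibble with `t_s` + `conc`/`ct_mM`, or
#'   numeric vector with `t` supplied).
#' @param aif AIF tibble on the same grid.
#' @param t Time grid (only for bare-vector `conc`).
#' @param options A [fit_options()] list.
#' @return A one-row tibble: the free parameters, derived parameters,
#'   `rss`, `n_iter`, `converged`, `valid`, `exclusion_reason`.
#' @examples
#' t <- seq(0, 238, by = 2)
#' aif <- population_aif(t)
#' ct <- tofts_forward(aif, 0.15, 12.61)
#' fit_voxel("tofts", ct, aif)
#' @export
fit_voxel <- function(model, conc, aif, t = NULL, options = fit_options()) {
  model <- match.arg(model, setdiff(KINETIC_MODELS, "iauc"))
  cc <- as_curve_xy(conc, t)
  xy <- as_aif_xy(aif)
  if (length(cc$t) != length(xy$t) || max(abs(cc$t - xy$t)) > 1e-9) {
    stop("concentration curve and AIF must share one time grid", call. = FALSE)
  }
  y <- cc$y
  bad_frac <- mean(!is.finite(y))
  empty <- fit_failure_row(model)
  if (bad_frac > options$max_bad_frac) {
    empty$exclusion_reason <- "non_invertible_frames"
    return(empty)
  }
  keep <- is.finite(y)
  t_fit <- cc$t
  bounds <- options$bounds %||% default_bounds(model)
  pn <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  starts <- start_lattice(bounds, options$n_starts_per_dim, model = model)
  resid_fn <- function(par) {
    par <- stats::setNames(pmin(pmax(par, lower), upper), pn)
    ct <- forward_model(model, t_fit, xy$cp, par, n_seg = options$dp_segments)
    (ct - y)[keep]
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- unlist(starts[s, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = options$ftol, ptol = options$ptol,
          maxiter = options$max_iter)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:5) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    # info 5 = iteration cap: still a candidate (the polish stage below
    # finishes the job); info 1-4 = converged by tolerance
    if (is.null(best) || rss < best$rss) {
      best <- list(par = stats::setNames(as.numeric(fit$par), pn),
                   rss = rss, n_iter = fit$niter, info = fit$info)
    }
  }
  if (is.null(best)) {
    empty$exclusion_reason <- "fit_failure"
    return(empty)
  }
  # polish the winner at machine-precision tolerances: on nearly flat
  # ridges (e.g. ATH with a sub-frame transit time) the standard stopping
  # rule halts early, while the exact minimum is still reachable
  for (round in 1:4) {
    pol <- tryCatch(
      minpack.lm::nls.lm(
        par = best$par, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-15, ptol = 1e-15, gtol = 0, maxiter = 1024)),
      error = function(e) NULL)
    if (is.null(pol)) break
    rss_p <- sum(pol$fvec^2)
    improved <- rss_p < best$rss * (1 - 1e-6)
    if (rss_p <= best$rss) {
      best <- list(par = stats::setNames(as.numeric(pol$par), pn),
                   rss = rss_p, n_iter = best$n_iter + pol$niter,
                   info = pol$info)
    }
    if (!improved) break
  }
  full <- tryCatch(derive_params(model, best$par), error = function(e) NULL)
  if (is.null(full)) {
    empty$exclusion_reason <- "fit_failure"
    return(empty)
  }
  phys <- physiological_filter(full, options$limits)
  converged <- best$info %in% 1:4
  dplyr::mutate(full,
    rss = best$rss, n_iter = best$n_iter, converged = converged,
    valid = phys$valid && converged,
    exclusion_reason = if (!converged) "fit_failure" else phys$reason)
}

fit_failure_row <- function(model) {
  skel <- switch(model,
    tofts  = derive_params(model, c(Ktrans = 0, Ve = 1)),
    etm    = derive_params(model, c(Ktrans = 0, Ve = 1, Vp = 0)),
    brix2c = derive_params(model, c(F = 1, PS = 0, Vp = 1, Ve = 1)),
    ath    = derive_params(model, c(F = 1, Tc = 1, E = 0, Ve = 1)),
    dp     = derive_params(model, c(F = 1, Vp = 1, Ve = 1, PS = 0)))
  skel[, setdiff(names(skel), "model")] <- NA_real_
  dplyr::mutate(skel, rss = NA_real_, n_iter = 0L, converged = FALSE,
                valid = FALSE, exclusion_reason = "fit_failure")
}

#' Fit a kinetic model to every curve of a cohort table
#'
#' Tidy front end over [fit_voxel()]: fits each ROI/voxel curve of a long
#' data frame and collects the results, ground for [generics::tidy()] /
#' [generics::glance()] and [ggplot2::autoplot()].
#'
#' @param data Long tibble with columns `roi_id` (or `voxel`), optional
#'   `tissue_class`, `t_s`, `conc`.
#' @param aif AIF tibble on the same time grid.
#' @param model Kinetic model to fit.
#' @param options A [fit_options()] list.
#' @return Object of class `dce_fit` with elements `results` (one row per
#'   curve), `model`, `aif`, `data`.
#' @export
fit_kinetic <- function(data, aif, model = "tofts", options = fit_options()) {
  id_col <- intersect(c("roi_id", "voxel"), names(data))[1]
  if (is.na(id_col)) stop("data needs an identifier column roi_id or voxel", call. = FALSE)
  stopifnot(all(c("t_s", "conc") %in% names(data)))
  groups <- dplyr::group_split(dplyr::group_by(data, .data[[id_col]]))
  res <- purrr::map_dfr(groups, function(g) {
    g <- dplyr::arrange(g, .data$t_s)
    row <- fit_voxel(model, tibble::tibble(t_s = g$t_s, conc = g$conc), aif,
                     options = options)
    row[[id_col]] <- g[[id_col]][1]
    if ("tissue_class" %in% names(g)) row$tissue_class <- g$tissue_class[1]
    row
  })
  structure(list(results = dplyr::relocate(res, dplyr::any_of(c(id_col, "tissue_class"))),
                 model = model, aif = aif, data = data, id_col = id_col),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("<dce_fit> model %s: %d curves, %d valid\n",
              x$model, nrow(x$results), sum(x$results$valid)))
  print(utils::head(x$results, 5))
  invisible(x)
}

#' Fit a kinetic model voxel-wise over a masked volume
#'
#' Applies [fit_voxel()] to every masked voxel of a 4D concentration array
#' and assembles per-parameter 3D maps plus an exclusion accounting table.
#' Deterministic: the start lattice is fixed, no randomness is involved.
#'
#' @param model Kinetic model.
#' @param conc_4d 4D concentration array `(x, y, z, t)` (mM; `NA` allowed).
#' @param t Time grid, seconds.
#' @param aif AIF tibble on the same grid.
#' @param mask 3D array; non-zero voxels are fitted.
#' @param options A [fit_options()] list.
#' @return List of class `dce_param_maps`: `maps` (named list of 3D
#'   arrays, `NA` outside valid voxels), `valid` (3D logical), `table`
#'   (tibble of per-voxel fit rows), `exclusions` (tibble of counts per
#'   exclusion reason).
#' @export
fit_volume <- function(model, conc_4d, t, aif, mask, options = fit_options()) {
  d <- dim(conc_4d)
  if (length(d) != 4) stop("conc_4d must be 4D", call. = FALSE)
  check_same_grid(d[1:3], dim(mask), "mask")
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  mat <- matrix(conc_4d, nrow = prod(d[1:3]), ncol = d[4])
  rows <- purrr::map_dfr(idx, function(i) {
    row <- fit_voxel(model, mat[i, ], aif, t = t, options = options)
    row$voxel <- i
    row
  })
  par_names <- setdiff(names(rows),
                       c("model", "voxel", "rss", "n_iter", "converged",
                         "valid", "exclusion_reason"))
  maps <- lapply(par_names, function(pn) {
    m <- array(NA_real_, d[1:3])
    ok <- rows$valid
    m[rows$voxel[ok]] <- rows[[pn]][ok]
    m
  })
  names(maps) <- par_names
  valid <- array(FALSE, d[1:3])
  valid[rows$voxel[rows$valid]] <- TRUE
  excl <- dplyr::count(rows, .data$exclusion_reason, name = "n")
  structure(list(maps = maps, valid = valid, table = rows,
                 exclusions = excl, model = model),
            class = "dce_param_maps")
}
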