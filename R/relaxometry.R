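# Variable flip angle T1 mapping and signal <-> concentration conversion
# through the spoiled gradient-echo (SPGR) steady-state equation:
#   S = m0 sin(a) (1 - E1) / (1 - E1 cos(a)),  E1 = exp(-TR * R1).

spgr_signal <- function(r1, m0, flip_deg, tr_ms) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / 1000 * r1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Synthesize a dynamic SPGR signal from a concentration curve
#'
#' Forward model of the acquisition: `R1(t) = 1/T10 + r1 * C(t)` and the
#' SPGR steady-state equation at the dynamic flip angle.
#'
#' @param conc Concentration curve: data frame with `t_s` and `ct_mM` (or
#'   `conc`), or a bare numeric vector in mM.
#' @param t10_s Native (pre-contrast) T1 in seconds.
#' @param protocol An [acquisition_protocol()].
#' @param m0 Equilibrium signal scale (arbitrary units).
#' @return A tibble with columns `t_s` (when available) and `signal`.
#' @examples
#' p <- acquisition_protocol()
#' signal_from_concentration(rep(0, 5), t10_s = 1.4, protocol = p, m0 = 1000)
#' @export
signal_from_concentration <- function(conc, t10_s, protocol, m0 = 1000) {
  if (t10_s <= 0) stop("t10_s must be positive", call. = FALSE)
  has_t <- is.data.frame(conc)
  cc <- if (has_t) as_curve_xy(conc) else list(t = NULL, y = as.numeric(conc))
  if (any(cc$y < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  r1 <- 1 / t10_s + protocol$r1_relaxivity * cc$y
  s <- spgr_signal(r1, m0, protocol$dyn_flip_deg, protocol$tr_ms)
  if (has_t) tibble::tibble(t_s = cc$t, signal = s) else tibble::tibble(signal = s)
}

#' Fit T1 and M0 from a variable flip angle series
#'
#' Linearized DESPOT1 fit: regressing `S/sin(a)` on `S/tan(a)` gives slope
#' `E1 = exp(-TR/T1)` and intercept `m0 (1 - E1)`. The voxel is flagged
#' invalid when the slope falls outside `(0, 1)` (non-physical T1) or the
#' regression is degenerate (e.g. all-zero signals).
#'
#' @param signals Numeric vector, one signal per flip angle.
#' @param flips_deg Flip angles in degrees (>= 2 distinct values).
#' @param tr_ms Repetition time, ms.
#' @return A one-row tibble with `t1_s`, `m0`, `valid`.
#' @examples
#' p <- acquisition_protocol()
#' s <- spgr_signal(1 / 1.4, 1000, p$vfa_flips_deg, p$tr_ms)
#' fit_vfa_t1(s, p$vfa_flips_deg, p$tr_ms)
#' @export
fit_vfa_t1 <- function(signals, flips_deg, tr_ms) {
  if (length(unique(flips_deg)) < 2) {
    stop("at least two distinct flip angles are required", call. = FALSE)
  }
  if (length(signals) != length(flips_deg)) {
    stop("one signal per flip angle is required", call. = FALSE)
  }
  if (any(signals < 0)) stop("signals must be non-negative", call. = FALSE)
  a <- flips_deg * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  bad <- tibble::tibble(t1_s = NA_real_, m0 = NA_real_, valid = FALSE)
  if (!all(is.finite(c(x, y)))) return(bad)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) return(bad)
  slope <- stats::cov(x, y) / vx
  if (!is.finite(slope) || slope <= 0 || slope >= 1) return(bad)
  intercept <- mean(y) - slope * mean(x)
  m0 <- intercept / (1 - slope)
  if (!is.finite(m0) || m0 <= 0) return(bad)
  t1 <- -(tr_ms / 1000) / log(slope)
  tibble::tibble(t1_s = t1, m0 = m0, valid = TRUE)
}

#' Voxel-wise T1/M0 maps from a variable flip angle volume series
#'
#' @param vfa A list of 3D arrays, one per flip angle (matching
#'   `protocol$vfa_flips_deg`), or a matrix (voxels x angles).
#' @param protocol An [acquisition_protocol()].
#' @param mask Optional logical 3D array restricting the fit.
#' @return For array input, a list of 3D arrays `t1_s`, `m0`, `valid`;
#'   for matrix input, a tibble with one row per voxel.
#' @export
vfa_t1_map <- function(vfa, protocol, mask = NULL) {
  flips <- protocol$vfa_flips_deg
  if (is.list(vfa) && !is.data.frame(vfa)) {
    if (length(vfa) != length(flips)) {
      stop("one VFA volume per flip angle is required", call. = FALSE)
    }
    dims <- dim(vfa[[1]])
    for (v in vfa) check_same_grid(dim(v), dims, "VFA volume")
    mat <- vapply(vfa, as.numeric, numeric(prod(dims)))
    idx <- if (is.null(mask)) seq_len(prod(dims)) else which(mask != 0)
    t1 <- m0 <- array(NA_real_, dims)
    valid <- array(FALSE, dims)
    for (i in idx) {
      f <- fit_vfa_t1(mat[i, ], flips, protocol$tr_ms)
      t1[i] <- f$t1_s; m0[i] <- f$m0; valid[i] <- f$valid
    }
    list(t1_s = t1, m0 = m0, valid = valid)
  } else {
    mat <- as.matrix(vfa)
    out <- purrr::map_dfr(seq_len(nrow(mat)), function(i) {
      fit_vfa_t1(mat[i, ], flips, protocol$tr_ms)
    })
    dplyr::mutate(out, voxel = dplyr::row_number(), .before = 1)
  }
}

#' Convert a dynamic signal curve to contrast concentration
#'
#' Inverts the SPGR equation per frame: with `B = S / (m0 sin(a))`,
#' `E1 = (1 - B) / (1 - B cos(a))` and `R1 = -log(E1) / TR`; the
#' concentration is the relaxation-rate difference
#' `C(t) = (R1(t) - R1_pre) / r1`, where `R1_pre` is the mean R1 over the
#' baseline frames. Frames outside the invertible domain (signal at or
#' above the SPGR saturation value `m0 sin(a)`) are flagged and set to
#' `NA`, never silently clipped.
#'
#' @param dyn_signal Data frame with `t_s` and `signal`, or numeric vector.
#' @param t1_s Native T1 in seconds (from [fit_vfa_t1()]); used for the
#'   reported VFA-based baseline `R1` (stored as attribute
#'   `r1_pre_vfa`).
#' @param m0 Equilibrium signal scale; must be positive.
#' @param protocol An [acquisition_protocol()].
#' @return A tibble with columns `t_s` (if available), `conc` (mM; `NA` on
#'   non-invertible frames) and `invertible`. Attributes: `r1_pre`
#'   (baseline-frame estimate), `r1_pre_vfa` (1/t1_s), and
#'   `frac_non_invertible`.
#' @export
concentration_from_signal <- function(dyn_signal, t1_s, m0, protocol) {
  if (!is.finite(m0) || m0 <= 0) stop("invalid map: m0 must be positive", call. = FALSE)
  has_t <- is.data.frame(dyn_signal)
  s <- if (has_t) dyn_signal$signal else as.numeric(dyn_signal)
  tt <- if (has_t) dyn_signal$t_s else NULL
  a <- protocol$dyn_flip_deg * pi / 180
  tr <- protocol$tr_ms / 1000
  B <- s / (m0 * sin(a))
  e1 <- (1 - B) / (1 - B * cos(a))
  invertible <- is.finite(B) & B >= 0 & B < 1 & (B * cos(a)) < 1 &
    e1 > 0 & e1 <= 1
  r1 <- rep(NA_real_, length(s))
  r1[invertible] <- -log(e1[invertible]) / tr
  nb <- protocol$n_baseline
  base <- r1[seq_len(min(nb, length(r1)))]
  r1_pre <- mean(base, na.rm = TRUE)
  conc <- (r1 - r1_pre) / protocol$r1_relaxivity
  out <- if (!is.null(tt)) {
    tibble::tibble(t_s = tt, conc = conc, invertible = invertible)
  } else {
    tibble::tibble(conc = conc, invertible = invertible)
  }
  attr(out, "r1_pre") <- r1_pre
  attr(out, "r1_pre_vfa") <- if (is.finite(t1_s) && t1_s > 0) 1 / t1_s else NA_real_
  attr(out, "frac_non_invertible") <- mean(!invertible)
  out
}

#' Convert a 4D dynamic signal volume to a concentration volume
#'
#' Applies [concentration_from_signal()] voxel-wise. Voxels whose fraction
#' of non-invertible frames exceeds `max_bad_frac` are marked invalid
#' (mirroring the exclusion of failed voxels downstream).
#'
#' @param dyn 4D signal array `(x, y, z, t)`.
#' @param t1m Output of [vfa_t1_map()] (list form with `t1_s`, `m0`,
#'   `valid`).
#' @param protocol An [acquisition_protocol()].
#' @param mask Optional logical 3D array restricting conversion.
#' @param max_bad_frac Maximum tolerated fraction of non-invertible frames
#'   per voxel (default 0.1).
#' @return List with `conc` (4D array, mM, `NA` where not invertible),
#'   `valid` (3D logical), `t` (seconds).
#' @export
concentration_map <- function(dyn, t1m, protocol, mask = NULL,
                              max_bad_frac = 0.1) {
  d <- dim(dyn)
  if (length(d) != 4) stop("dyn must be a 4D array", call. = FALSE)
  check_same_grid(d[1:3], dim(t1m$m0), "T1/M0 map")
  idx <- if (is.null(mask)) seq_len(prod(d[1:3])) else which(mask != 0)
  mat <- matrix(dyn, nrow = prod(d[1:3]), ncol = d[4])
  conc <- array(NA_real_, d)
  cm <- matrix(NA_real_, prod(d[1:3]), d[4])
  valid <- array(FALSE, d[1:3])
  for (i in idx) {
    if (!isTRUE(t1m$valid[i])) next
    cf <- concentration_from_signal(mat[i, ], t1m$t1_s[i], t1m$m0[i], protocol)
    cm[i, ] <- cf$conc
    valid[i] <- attr(cf, "frac_non_invertible") <= max_bad_frac
  }
  conc[] <- cm
  list(conc = conc, valid = valid, t = protocol_times(protocol))
}

check_same_grid <- function(d1, d2, what = "volume") {
  if (length(d1) != length(d2) || any(d1 != d2)) {
    stop(sprintf("grid mismatch for %s: %s vs %s", what,
                 paste(d1, collapse = "x"), paste(d2, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
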