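# Forward (generative) tracer-kinetic models.
#
# Unit conventions, used consistently across the package:
#   F, PS   : mL/min/100 mL tissue  -> internal 1/s via x/6000
#   Ktrans  : 1/min                 -> internal 1/s via x/60
#   Ve, Vp  : percent               -> internal fraction via x/100
#   Tc, MTT : seconds
#   E (ATH) : dimensionless fraction in [0, 1)
# Concentrations in mM; time in seconds.

PER_MIN_100ML <- 6000   # (mL/min/100mL) -> 1/s

check_model_time <- function(t, ca) {
  if (length(t) != length(ca)) {
    stop("time grid and AIF must have equal length", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
}

# --- kernels: numeric vectors in, numeric vector out ------------------------

.tofts <- function(t, ca, Ktrans, Ve) {
  if (Ktrans < 0) stop("Ktrans must be non-negative", call. = FALSE)
  if (Ktrans == 0) return(rep(0, length(t)))
  if (Ve <= 0) stop("Ve must be positive when Ktrans > 0 (Kep undefined)", call. = FALSE)
  kt <- Ktrans / 60
  kep <- kt / (Ve / 100)
  kt * exp_conv(kep, t, ca)
}

.etm <- function(t, ca, Ktrans, Ve, Vp) {
  if (Vp < 0) stop("Vp must be non-negative", call. = FALSE)
  (Vp / 100) * ca + .tofts(t, ca, Ktrans, Ve)
}

# Two-compartment exchange: well-mixed plasma and interstitial pools.
#   vp dC1/dt = Fp (Ca - C1) + PS (C2 - C1)
#   ve dC2/dt = PS (C1 - C2),   Ct = vp C1 + ve C2
# Impulse response is bi-exponential; the repeated-root case falls back to
# the (a + b t) exp(lambda t) closed form convolved on the grid.
.brix2c <- function(t, ca, F, PS, Vp, Ve) {
  if (Vp <= 0 || Ve <= 0) stop("brix2c requires Vp > 0 and Ve > 0", call. = FALSE)
  if (F < 0 || PS < 0) stop("F and PS must be non-negative", call. = FALSE)
  Fp <- F / PER_MIN_100ML
  PSs <- PS / PER_MIN_100ML
  vp <- Vp / 100
  ve <- Ve / 100
  if (Fp == 0) return(rep(0, length(t)))
  kp <- (Fp + PSs) / vp
  q <- PSs / vp
  r <- PSs / ve
  # A = [[-kp, q], [r, -r]], b = (Fp/vp, 0), w = (vp, ve)
  tr <- -(kp + r)
  det <- kp * r - q * r
  disc <- tr^2 - 4 * det
  disc <- max(disc, 0)
  sq <- sqrt(disc)
  l1 <- (tr + sq) / 2
  l2 <- (tr - sq) / 2
  b1 <- Fp / vp
  wAb <- vp * (-kp * b1) + ve * (r * b1)     # w^T A b
  wb <- vp * b1                              # w^T b = Fp
  if (sq > 1e-12 * max(abs(l1), abs(l2), 1e-30)) {
    # h(t) = a1 exp(l1 t) + a2 exp(l2 t) with
    # a1 = w^T (A - l2 I) b / (l1 - l2), a2 = -w^T (A - l1 I) b / (l1 - l2)
    a1 <- (wAb - l2 * wb) / (l1 - l2)
    a2 <- -(wAb - l1 * wb) / (l1 - l2)
    a1 * exp_conv(-l1, t, ca) + a2 * exp_conv(-l2, t, ca)
  } else {
    # repeated root: h(t) = (wb + (wAb - l wb) t) exp(l t)
    l <- (l1 + l2) / 2
    h <- (wb + (wAb - l * wb) * t) * exp(l * t)
    conv_trapz(t, ca, h)
  }
}

# Adiabatic tissue homogeneity: plug-flow vascular phase of duration Tc,
# then adiabatic exchange with rate Kep = E F / Ve.
#   Ct(t) = Fp [ int_{max(0, t-Tc)}^{t} Ca  +  E G(t - Tc) ]
# with G the exponential convolution of Ca; the Tc breakpoint is handled by
# exact integration of the piecewise-linear AIF (Tc may be below the frame
# spacing).
.ath <- function(t, ca, F, Tc, E, Ve) {
  if (E < 0 || E >= 1) stop("E must lie in [0, 1)", call. = FALSE)
  if (Tc < 0) stop("Tc must be non-negative", call. = FALSE)
  if (F < 0) stop("F must be non-negative", call. = FALSE)
  Fp <- F / PER_MIN_100ML
  if (Fp == 0) return(rep(0, length(t)))
  n <- length(t)
  t0 <- t[1]
  cum_eval <- pl_cum_eval(t, ca)
  box <- cum_eval(t) - cum_eval(pmax(t0, t - Tc))
  if (E == 0) return(Fp * box)
  if (Ve <= 0) stop("Ve must be positive when E > 0", call. = FALSE)
  k <- E * Fp / (Ve / 100)
  # exponential term evaluated on the Tc-shifted grid
  s_rel <- (t - t0) - Tc
  keep <- s_rel > 0
  g <- numeric(n)
  if (any(keep)) {
    s <- c(0, s_rel[keep])
    ca_s <- stats::approx(t - t0, ca, xout = s, rule = 2)$y
    gv <- exp_conv_nu(k, s, ca_s)
    g[keep] <- gv[-1]
  }
  Fp * (box + E * g)
}

# Distributed parameter model: plug-flow capillary with axially local,
# well-mixed interstitial exchange, solved along flow characteristics
# (Lagrangian scheme, compiled). Transit time Tc = Vp/F.
.dp <- function(t, ca, F, Vp, Ve, PS, n_seg = 50) {
  if (n_seg < 8) stop("dp_forward refuses fewer than 8 capillary segments", call. = FALSE)
  if (Vp <= 0 || Ve <= 0) stop("dp requires Vp > 0 and Ve > 0", call. = FALSE)
  if (F <= 0) return(rep(0, length(t)))
  Fp <- F / PER_MIN_100ML
  PSs <- PS / PER_MIN_100ML
  vp <- Vp / 100
  ve <- Ve / 100
  Tc <- vp / Fp
  t0 <- t[1]
  tmax <- t[length(t)] - t0
  dt <- min(diff(t))
  # step resolves both the transit time and the frame grid; bounded so the
  # fine grid stays tractable when Tc is far below the frame spacing (the
  # capillary phase is then unresolved by the data anyway)
  h <- min(Tc / n_seg, dt)
  # when Tc is far below the frame spacing the capillary phase is
  # unresolved by the data: fewer internal segments lose nothing, and the
  # total step count stays bounded
  max_steps <- 3e4
  if (tmax / h > max_steps) h <- tmax / max_steps
  n_seg_eff <- min(max(1L, as.integer(round(Tc / h))), 50000L)
  h <- Tc / n_seg_eff
  nf <- as.integer(ceiling(tmax / h)) + 1L
  tf <- seq(0, by = h, length.out = nf)
  ca_f <- stats::approx(t - t0, ca, xout = tf, rule = 2)$y
  a <- if (vp > 0) PSs / vp else 0
  b <- if (ve > 0) PSs / ve else 0
  ct_f <- dp_lagrangian(ca_f, h, n_seg_eff, a, b, vp, ve)
  stats::approx(tf, ct_f, xout = t - t0, rule = 2)$y
}

# --- exported tidy wrappers -------------------------------------------------

model_curve <- function(t, ct) tibble::tibble(t_s = t, ct_mM = ct)

#' Tofts model tissue curve
#'
#' `Ct(t) = Ktrans * int_0^t Ca(tau) exp(-Kep (t - tau)) dtau` with
#' `Kep = Ktrans / Ve`.
#'
#' @param aif AIF data frame with columns `t_s`, `cp_mM` (plasma, mM).
#' @param Ktrans Transfer constant, 1/min.
#' @param Ve Extravascular extracellular volume fraction, percent.
#' @return A tibble with columns `t_s`, `ct_mM`.
#' @examples
#' aif <- population_aif(seq(0, 238, by = 2))
#' tofts_forward(aif, Ktrans = 0.15, Ve = 12.61)
#' @export
tofts_forward <- function(aif, Ktrans, Ve) {
  xy <- as_aif_xy(aif)
  check_model_time(xy$t, xy$cp)
  model_curve(xy$t, .tofts(xy$t, xy$cp, Ktrans, Ve))
}

#' Extended Tofts model tissue curve
#'
#' Adds a plasma term to the Tofts model: `Ct = Vp Ca + Tofts(Ktrans, Ve)`.
#'
#' @inheritParams tofts_forward
#' @param Vp Plasma volume fraction, percent.
#' @return A tibble with columns `t_s`, `ct_mM`.
#' @export
etm_forward <- function(aif, Ktrans, Ve, Vp) {
  xy <- as_aif_xy(aif)
  check_model_time(xy$t, xy$cp)
  model_curve(xy$t, .etm(xy$t, xy$cp, Ktrans, Ve, Vp))
}

#' Two-compartment exchange model tissue curve
#'
#' Conventional two-compartment (plasma + interstitium, both well mixed)
#' exchange model: plasma flow `F` feeds the vascular pool, permeability
#' `PS` exchanges with the interstitial pool. Solved through its
#' bi-exponential impulse response.
#'
#' @inheritParams tofts_forward
#' @param F Plasma flow, mL/min/100 mL tissue.
#' @param PS Permeability-surface-area product, mL/min/100 mL tissue.
#' @param Vp,Ve Plasma and interstitial volume fractions, percent.
#' @return A tibble with columns `t_s`, `ct_mM`.
#' @export
brix2c_forward <- function(aif, F, PS, Vp, Ve) {
  xy <- as_aif_xy(aif)
  check_model_time(xy$t, xy$cp)
  model_curve(xy$t, .brix2c(xy$t, xy$cp, F, PS, Vp, Ve))
}

#' Adiabatic tissue homogeneity model tissue curve
#'
#' Plug-flow capillary with transit time `Tc` followed by adiabatic
#' exchange with the interstitium: residue `R(t) = 1` for `t < Tc` and
#' `R(t) = E exp(-(E F / Ve)(t - Tc))` after. The `Tc` breakpoint is
#' integrated analytically, so `Tc` below the frame spacing is handled
#' without grid artifacts.
#'
#' @inheritParams brix2c_forward
#' @param Tc Capillary transit time, seconds.
#' @param E First-pass extraction fraction, in `[0, 1)`.
#' @return A tibble with columns `t_s`, `ct_mM`.
#' @export
ath_forward <- function(aif, F, Tc, E, Ve) {
  xy <- as_aif_xy(aif)
  check_model_time(xy$t, xy$cp)
  model_curve(xy$t, .ath(xy$t, xy$cp, F, Tc, E, Ve))
}

#' Distributed parameter model tissue curve
#'
#' Axially distributed capillary-interstitium exchange: tracer advects along
#' a plug-flow capillary while exchanging locally with a stationary
#' interstitium,
#' `vp dCc/dt + F L dCc/dx = -PS (Cc - Ce)`,
#' `ve dCe/dt = PS (Cc - Ce)`, inlet `Cc(0, t) = Ca(t)`.
#' Solved along flow characteristics with `n_seg` capillary segments and an
#' exact two-pool exchange update per step.
#'
#' @inheritParams brix2c_forward
#' @param n_seg Number of capillary segments (minimum 8; default 50).
#' @return A tibble with columns `t_s`, `ct_mM`.
#' @export
dp_forward <- function(aif, F, Vp, Ve, PS, n_seg = 50) {
  xy <- as_aif_xy(aif)
  check_model_time(xy$t, xy$cp)
  model_curve(xy$t, .dp(xy$t, xy$cp, F, Vp, Ve, PS, n_seg = n_seg))
}

#' Initial area under the concentration curve
#'
#' Trapezoidal integral of the tissue concentration from bolus arrival to
#' arrival + 60 s and + 90 s, with the window endpoint interpolated inside
#' its frame. When an arterial (aorta/input-function) curve is supplied the
#' normalized variants divide by the same integral of that curve.
#'
#' @param conc A data frame with columns `t_s` and a concentration column
#'   (`ct_mM` or `cp_mM`), or a numeric vector paired with `t`.
#' @param t Time grid in seconds (only when `conc` is a bare vector).
#' @param bolus_arrival_index 1-based frame index of bolus arrival.
#' @param aorta Optional arterial curve in the same format, used for the
#'   normalized `IAUC60No`/`IAUC90No` ratios.
#' @param windows Integration windows in seconds (default 60 and 90).
#' @return A one-row tibble with columns `IAUC60`, `IAUC90`, `IAUC60No`,
#'   `IAUC90No` (the last two `NA` when no arterial curve is given).
#' @examples
#' t <- seq(0, 238, by = 2)
#' conc <- tibble::tibble(t_s = t, ct_mM = as.numeric(t >= 20))
#' iauc(conc, bolus_arrival_index = 11)
#' @export
iauc <- function(conc, t = NULL, bolus_arrival_index, aorta = NULL,
                 windows = c(60, 90)) {
  cc <- as_curve_xy(conc, t)
  t <- cc$t
  y <- cc$y
  i0 <- as.integer(bolus_arrival_index)
  if (i0 < 1 || i0 > length(t)) stop("bolus_arrival_index out of range", call. = FALSE)
  t_arr <- t[i0]
  vals <- vapply(windows, function(w) {
    t_end <- t_arr + w
    if (t_end > t[length(t)] + 1e-9) {
      stop(sprintf(
        "IAUC window of %g s extends %.1f s past the last frame (%.1f s)",
        w, t_end - t[length(t)], t[length(t)]), call. = FALSE)
    }
    pl_integral(t, y, t_arr, min(t_end, t[length(t)]))
  }, numeric(1))
  out <- tibble::tibble(IAUC60 = vals[1], IAUC90 = vals[2],
                        IAUC60No = NA_real_, IAUC90No = NA_real_)
  if (!is.null(aorta)) {
    ac <- as_curve_xy(aorta, t)
    avals <- vapply(windows, function(w) {
      pl_integral(ac$t, ac$y, t_arr, t_arr + w)
    }, numeric(1))
    out$IAUC60No <- vals[1] / avals[1]
    out$IAUC90No <- vals[2] / avals[2]
  }
  out
}

# Accept a curve as tibble (t_s, ct_mM/cp_mM/conc) or a bare vector + t.
as_curve_xy <- function(conc, t = NULL) {
  if (is.data.frame(conc)) {
    ycol <- intersect(c("ct_mM", "cp_mM", "conc"), names(conc))[1]
    if (is.na(ycol) || !"t_s" %in% names(conc)) {
      stop("curve data frame needs t_s and one of ct_mM/cp_mM/conc", call. = FALSE)
    }
    list(t = conc$t_s, y = conc[[ycol]])
  } else {
    if (is.null(t)) stop("supply a time grid for a bare concentration vector", call. = FALSE)
    list(t = t, y = as.numeric(conc))
  }
}
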