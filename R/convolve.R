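# Convolution and quadrature primitives shared by all kinetic models.
# Concentration curves are treated as piecewise linear in time; the
# exponential convolutions below are analytically exact under that
# interpolation, which keeps forward models accurate at 2 s sampling.

# y(t_i) = int_0^{t_i} ca(tau) exp(-k (t_i - tau)) dtau, uniform grid.
# Recursion y_{i+1} = E y_i + I_i with the interval integral I_i closed-form
# for linear ca; vectorized via stats::filter.
exp_conv <- function(k, t, ca) {
  n <- length(t)
  if (n < 2) return(rep(0, n))
  dt <- t[2] - t[1]
  if (max(abs(diff(t) - dt)) > 1e-9 * dt) {
    return(exp_conv_nu(k, t, ca))
  }
  kd <- k * dt
  c0 <- ca[-n]
  c1 <- ca[-1]
  if (kd < 1e-6) {
    A <- dt * (1 - kd / 2 + kd^2 / 6)
    B <- dt * (0.5 - kd / 6)
    E <- exp(-kd)
  } else {
    E <- exp(-kd)
    A <- -expm1(-kd) / k            # int exp(-k(dt-u)) du over [0,dt]
    B <- (1 - A / dt) / k           # weight of the linear ramp term
  }
  I <- c0 * A + (c1 - c0) * B
  c(0, stats::filter(I, E, method = "recursive"))
}

# Non-uniform-grid variant (plain loop); used for shifted grids (ATH).
exp_conv_nu <- function(k, t, ca) {
  n <- length(t)
  y <- numeric(n)
  if (n < 2) return(y)
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    if (dt <= 0) stop("time grid must be strictly increasing", call. = FALSE)
    kd <- k * dt
    if (kd < 1e-6) {
      A <- dt * (1 - kd / 2 + kd^2 / 6)
      B <- dt * (0.5 - kd / 6)
      E <- exp(-kd)
    } else {
      E <- exp(-kd)
      A <- -expm1(-kd) / k
      B <- (1 - A / dt) / k
    }
    y[i] <- E * y[i - 1] + ca[i - 1] * A + (ca[i] - ca[i - 1]) * B
  }
  y
}

# Cumulative trapezoid of a sampled curve.
cum_trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(rep(0, n))
  c(0, cumsum((y[-n] + y[-1]) / 2 * diff(t)))
}

# Exact integral of the piecewise-linear interpolant of (t, y) over [a, b]
# (vectorized over bounds), with a, b inside [t[1], t[n]]. Used for boxcar
# residues and IAUC windows.
pl_integral <- function(t, y, a, b) {
  if (any(b < a)) stop("integration bounds reversed", call. = FALSE)
  eval_cum <- pl_cum_eval(t, y)
  eval_cum(b) - eval_cum(a)
}

# Closure evaluating the exact cumulative integral of the piecewise-linear
# interpolant at arbitrary points (vectorized).
pl_cum_eval <- function(t, y) {
  Fcum <- cum_trapz(t, y)
  n <- length(t)
  function(s) {
    i <- findInterval(s, t, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    dt <- t[i + 1] - t[i]
    u <- s - t[i]
    slope <- (y[i + 1] - y[i]) / dt
    Fcum[i] + y[i] * u + 0.5 * slope * u^2
  }
}

#' Convolve an impulse residue function with an arterial input function
#'
#' Shared engine for flow-scaled residue-function models: computes
#' `Ct(t) = flow_scale * integral_0^t Ca(tau) R(t - tau) dtau` by
#' trapezoidal discretization on the (uniform) frame grid. The flow scale
#' is given in mL/min/100 mL and converted to 1/s internally.
#'
#' @param aif An AIF as returned by [population_aif()] or [extract_aif()]
#'   (a data frame with columns `t_s` and `cp_mM`).
#' @param residue A function of time (seconds) returning the dimensionless
#'   residue, with `residue(0) = 1`.
#' @param flow_scale Plasma flow in mL/min/100 mL tissue.
#' @return A tibble with columns `t_s` and `ct_mM`.
#' @examples
#' aif <- population_aif(seq(0, 120, by = 2))
#' convolve_with_aif(aif, function(t) exp(-t / 20), flow_scale = 30)
#' @export
convolve_with_aif <- function(aif, residue, flow_scale) {
  xy <- as_aif_xy(aif)
  t <- xy$t
  ca <- xy$cp
  n <- length(t)
  if (n >= 2) {
    dt <- t[2] - t[1]
    if (max(abs(diff(t) - dt)) > 1e-9 * dt) {
      stop("convolve_with_aif requires a uniform time grid; resample first",
           call. = FALSE)
    }
  }
  r <- residue(t - t[1])
  ct <- conv_trapz(t, ca, r) * flow_scale / 6000
  tibble::tibble(t_s = t, ct_mM = ct)
}

# Direct O(n^2) trapezoidal convolution of sampled kernel r with ca.
conv_trapz <- function(t, ca, r) {
  n <- length(t)
  if (n < 2) return(rep(0, n))
  dt <- t[2] - t[1]
  out <- numeric(n)
  for (i in 2:n) {
    integrand <- ca[1:i] * r[i:1]
    out[i] <- sum((integrand[-1] + integrand[-i]) / 2) * dt
  }
  out
}

# Accept an AIF as a tibble (t_s, cp_mM) or a two-element list/vectors.
as_aif_xy <- function(aif) {
  if (is.data.frame(aif)) {
    if (!all(c("t_s", "cp_mM") %in% names(aif))) {
      stop("AIF data frame must have columns t_s and cp_mM", call. = FALSE)
    }
    list(t = aif$t_s, cp = aif$cp_mM)
  } else if (is.list(aif) && all(c("t", "cp") %in% names(aif))) {
    list(t = aif$t, cp = aif$cp)
  } else {
    stop("unrecognized AIF representation", call. = FALSE)
  }
}
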