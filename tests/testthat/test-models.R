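test_that("convolution engine matches the closed-form exponential convolution", {
  t <- std_t
  a <- 0.05; k <- 0.02
  aife <- tibble::tibble(t_s = t, cp_mM = exp(-a * t))
  got <- convolve_with_aif(aife, function(u) exp(-k * u), flow_scale = 6000)$ct_mM
  exact <- (exp(-a * t) - exp(-k * t)) / (k - a)
  expect_lt(max(abs(got - exact)) / max(exact), 0.005)
})

test_that("convolution error shrinks at second order under grid refinement", {
  a <- 0.05; k <- 0.02
  err_at <- function(dt) {
    t <- seq(0, 200, by = dt)
    got <- convolve_with_aif(tibble::tibble(t_s = t, cp_mM = exp(-a * t)),
                             function(u) exp(-k * u), flow_scale = 6000)$ct_mM
    exact <- (exp(-a * t) - exp(-k * t)) / (k - a)
    max(abs(got - exact))
  }
  e2 <- err_at(2); e1 <- err_at(1)
  expect_lt(e1, e2 / 3)   # O(dt^2): halving dt should shrink error ~4x
  expect_equal(convolve_with_aif(tibble::tibble(t_s = std_t, cp_mM = 0),
                                 function(u) rep(1, length(u)), 50)$ct_mM,
               rep(0, length(std_t)))
  expect_error(
    convolve_with_aif(tibble::tibble(t_s = c(0, 1, 3), cp_mM = c(0, 1, 0)),
                      function(u) exp(-u), 50),
    "uniform")
})

test_that("Tofts model obeys its trivial limits", {
  expect_equal(tofts_forward(std_aif, 0, 12.6)$ct_mM, rep(0, length(std_t)))
  # constant input: Ct -> Ve * c0 at steady state
  tlong <- seq(0, 6000, by = 2)
  aifc <- tibble::tibble(t_s = tlong, cp_mM = 2)
  expect_equal(tail(tofts_forward(aifc, 0.3, 20)$ct_mM, 1), 0.2 * 2,
               tolerance = 1e-6)
  expect_error(tofts_forward(std_aif, 0.1, 0), "Kep undefined")
})

test_that("extended Tofts nests Tofts and is exactly Vp*Ca at Ktrans=0", {
  tf <- tofts_forward(std_aif, 0.15, 12.61)$ct_mM
  expect_lt(max(abs(etm_forward(std_aif, 0.15, 12.61, 0)$ct_mM - tf)), 1e-12)
  expect_equal(etm_forward(std_aif, 0, 10, 3)$ct_mM, 0.03 * std_aif$cp_mM)
  # algebraic identity on random bounded parameters
  set.seed(11)
  for (r in 1:10) {
    kt <- runif(1, 0.01, 1); ve <- runif(1, 1, 40); vp <- runif(1, 0.1, 10)
    d <- etm_forward(std_aif, kt, ve, vp)$ct_mM -
      tofts_forward(std_aif, kt, ve)$ct_mM
    expect_lt(max(abs(d - vp / 100 * std_aif$cp_mM)), 1e-12)
  }
})

test_that("two-compartment exchange reduces to vascular washout at PS=0", {
  got <- brix2c_forward(std_aif, F = 25, PS = 0, Vp = 4, Ve = 6)$ct_mM
  Fp <- 25 / 6000
  ref <- Fp * dcekin:::exp_conv(Fp / 0.04, std_t, std_aif$cp_mM)
  expect_lt(max(abs(got - ref)), 1e-12)
})

test_that("two-compartment exchange matches an independent ODE integrator", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  capp <- stats::approxfun(std_t, std_aif$cp_mM, rule = 2)
  for (r in 1:5) {
    F <- runif(1, 5, 60); PS <- runif(1, 0.5, 20)
    Vp <- runif(1, 0.5, 10); Ve <- runif(1, 2, 30)
    got <- brix2c_forward(std_aif, F, PS, Vp, Ve)$ct_mM
    Fp <- F / 6000; PSs <- PS / 6000; vp <- Vp / 100; ve <- Ve / 100
    rhs <- function(tt, y, parms) {
      list(c((Fp * (capp(tt) - y[1]) + PSs * (y[2] - y[1])) / vp,
             PSs * (y[1] - y[2]) / ve))
    }
    sol <- deSolve::ode(c(0, 0), std_t, rhs, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    ref <- vp * sol[, 2] + ve * sol[, 3]
    expect_lt(max(abs(got - ref)) / max(ref), 0.005)
  }
})

test_that("repeated-eigenvalue degenerate branch stays continuous", {
  # eigenvalues coincide when the discriminant vanishes; approach it by
  # nearly-symmetric parameters and compare with a slight perturbation
  f1 <- brix2c_forward(std_aif, F = 10, PS = 10, Vp = 5, Ve = 5.0001)$ct_mM
  f2 <- brix2c_forward(std_aif, F = 10, PS = 10, Vp = 5, Ve = 5.01)$ct_mM
  expect_lt(max(abs(f1 - f2)) / max(f2), 0.01)
})

test_that("ATH limits: Tc=0 is Tofts with Ktrans = E*F, E=0 is the vascular boxcar", {
  F <- 32.6; E <- 0.2709; Ve <- 10.32
  got <- ath_forward(std_aif, F, Tc = 0, E = E, Ve = Ve)$ct_mM
  # E*F in mL/min/100mL equals a transfer constant of E*F/100 in 1/min
  ref <- tofts_forward(std_aif, E * F / 100, Ve)$ct_mM
  expect_lt(max(abs(got - ref)) / max(ref), 0.001)
  Tc <- 8
  vas <- ath_forward(std_aif, F, Tc = Tc, E = 0, Ve = Ve)$ct_mM
  box <- (F / 6000) * vapply(std_t, function(tt) {
    dcekin:::pl_integral(std_t, std_aif$cp_mM, max(0, tt - Tc), tt)
  }, numeric(1))
  expect_lt(max(abs(vas - box)), 1e-12)
  expect_error(ath_forward(std_aif, F, 2, E = 1, Ve = Ve), "E must lie")
})

test_that("DP with PS=0 is the pure plug-flow boxcar", {
  F <- 20.01; Vp <- 2.18
  got <- dp_forward(std_aif, F, Vp, Ve = 9.36, PS = 0)$ct_mM
  Tc <- (Vp / 100) / (F / 6000)
  box <- (F / 6000) * vapply(std_t, function(tt) {
    dcekin:::pl_integral(std_t, std_aif$cp_mM, max(0, tt - Tc), tt)
  }, numeric(1))
  expect_lt(max(abs(got - box)) / max(box), 0.002)
})

test_that("DP approaches ATH in the short-transit (adiabatic) regime", {
  F <- 30; Vp <- 0.9; Ve <- 10; PS <- 15
  Tc <- (Vp / 100) / (F / 6000)   # 1.8 s, below the 2 s frame spacing
  dpc <- dp_forward(std_aif, F, Vp, Ve, PS)$ct_mM
  athc <- ath_forward(std_aif, F, Tc, E = 1 - exp(-PS / F), Ve = Ve)$ct_mM
  expect_lt(rel_l2(dpc, athc), 0.02)
})

test_that("DP converges in segment count and matches the inverse-Laplace oracle", {
  skip_if_not_installed("pracma")
  F <- 20.01; Vp <- 2.18; Ve <- 9.36; PS <- 11.63
  d50 <- dp_forward(std_aif, F, Vp, Ve, PS, n_seg = 50)$ct_mM
  d100 <- dp_forward(std_aif, F, Vp, Ve, PS, n_seg = 100)$ct_mM
  expect_lt(rel_l2(d50, d100), 0.002)
  # independent oracle: residue from numeric inverse Laplace transform of
  # the axially distributed exchange system, convolved on a fine grid
  Fp <- F / 6000; vp <- Vp / 100; ve <- Ve / 100; PSs <- PS / 6000
  g <- function(s) vp * s + PSs * ve * s / (PSs + ve * s)
  Rlap <- function(s) (1 - exp(-g(s) / Fp)) / s
  h <- 0.25
  tf <- seq(0, max(std_t), by = h)
  R <- c(1, vapply(tf[-1], function(x) {
    utils::tail(pracma::invlap(Rlap, 0, x, nnt = 6)$y, 1)
  }, numeric(1)))
  ca_f <- stats::approx(std_t, std_aif$cp_mM, tf)$y
  ct_or <- stats::approx(tf, dcekin:::conv_trapz(tf, ca_f, R) * Fp, std_t)$y
  expect_lt(rel_l2(d50, ct_or), 0.005)
  expect_error(dp_forward(std_aif, F, Vp, Ve, PS, n_seg = 4), "8")
})

test_that("all forward models are linear in the AIF", {
  aif2 <- population_aif(std_t, 10, dose_scale = 3)
  pars <- list(
    tofts = function(a) tofts_forward(a, 0.15, 12.61)$ct_mM,
    etm = function(a) etm_forward(a, 0.12, 11.44, 0.79)$ct_mM,
    brix2c = function(a) brix2c_forward(a, 25.46, 4.32, 4.11, 6.60)$ct_mM,
    ath = function(a) ath_forward(a, 32.6, 1.28, 0.2709, 10.32)$ct_mM,
    dp = function(a) dp_forward(a, 20.01, 2.18, 9.36, 11.63)$ct_mM)
  for (nm in names(pars)) {
    c1 <- pars[[nm]](std_aif)
    c3 <- pars[[nm]](aif2)
    expect_lt(max(abs(c3 - 3 * c1)) / max(abs(c3)), 1e-9,
              label = paste("linearity of", nm))
    expect_true(all(c1 >= -1e-12), label = paste("non-negativity of", nm))
  }
})

test_that("washout models decay toward zero after a finite bolus", {
  tlong <- seq(0, 3000, by = 2)
  along <- population_aif(tlong, 10, coefs = within(aif_coefficients(), a2 <- 0))
  for (ct in list(tofts_forward(along, 0.3, 10)$ct_mM,
                  ath_forward(along, 30, 2, 0.3, 10)$ct_mM,
                  dp_forward(along, 20, 2, 9, 11)$ct_mM)) {
    expect_lt(utils::tail(ct, 1), 0.02 * max(ct))
  }
})

test_that("IAUC integrates rectangles and triangles exactly and self-normalizes", {
  t <- std_t
  arr <- 11L  # arrival at 20 s
  rect <- ifelse(t >= 20, 1, 0)
  r <- iauc(rect, t = t, bolus_arrival_index = arr)
  expect_equal(r$IAUC60, 60)
  expect_equal(r$IAUC90, 90)
  ramp <- pmax(0, (t - 20) / 60)
  r2 <- iauc(ramp, t = t, bolus_arrival_index = arr)
  expect_equal(r2$IAUC60, 30)
  slf <- iauc(tibble::tibble(t_s = t, ct_mM = rect), bolus_arrival_index = arr,
              aorta = tibble::tibble(t_s = t, cp_mM = rect))
  expect_equal(slf$IAUC60No, 1)
  expect_equal(slf$IAUC90No, 1)
  expect_error(iauc(rect, t = t, bolus_arrival_index = 110L), "past the last frame")
})
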