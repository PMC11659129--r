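test_that("Tofts and ETM fits recover noise-free generator parameters", {
  ct <- tofts_forward(std_aif, 0.15, 12.61)
  f <- fit_voxel("tofts", ct, std_aif)
  expect_true(f$converged && f$valid)
  expect_equal(f$Ktrans, 0.15, tolerance = 0.005)
  expect_equal(f$Ve, 12.61, tolerance = 0.005)
  ce <- etm_forward(std_aif, 0.12, 11.44, 0.79)
  fe <- fit_voxel("etm", ce, std_aif)
  expect_equal(fe$Ktrans, 0.12, tolerance = 0.005)
  expect_equal(fe$Ve, 11.44, tolerance = 0.005)
  expect_equal(fe$Vp, 0.79, tolerance = 0.005)
})

test_that("an all-zero curve fits to the Ktrans=0 boundary and stays valid", {
  z <- tibble::tibble(t_s = std_t, conc = 0)
  f <- fit_voxel("tofts", z, std_aif)
  expect_true(f$converged)
  expect_true(f$valid)
  expect_lt(f$Ktrans, 1e-6)
})

test_that("fitting ETM to a Tofts curve drives Vp to zero", {
  ct <- tofts_forward(std_aif, 0.15, 12.61)
  fe <- fit_voxel("etm", ct, std_aif)
  expect_lt(abs(fe$Vp), 0.1)
})

test_that("voxels with too many missing frames are excluded, partial gaps fitted", {
  ct <- tofts_forward(std_aif, 0.15, 12.61)$ct_mM
  bad <- ct; bad[1:30] <- NA
  f <- fit_voxel("tofts", bad, std_aif, t = std_t)
  expect_false(f$valid)
  expect_identical(f$exclusion_reason, "non_invertible_frames")
  few <- ct; few[5:7] <- NA
  f2 <- fit_voxel("tofts", few, std_aif, t = std_t)
  expect_true(f2$valid)
  expect_equal(f2$Ktrans, 0.15, tolerance = 0.01)
})

test_that("returned rss is the minimum over the multistart lattice", {
  set.seed(31)
  noisy <- tofts_forward(std_aif, 0.15, 12.61)$ct_mM +
    rnorm(length(std_t), 0, 0.002)
  f <- fit_voxel("tofts", noisy, std_aif, t = std_t)
  starts <- dcekin:::start_lattice(default_bounds("tofts"), 3)
  rss0 <- apply(starts, 1, function(p0) {
    ct <- dcekin:::.tofts(std_t, std_aif$cp_mM, p0[1], p0[2])
    sum((ct - noisy)^2)
  })
  expect_lte(f$rss, min(rss0) + 1e-12)
})

test_that("the physiological filter applies the documented limits", {
  ok <- physiological_filter(derive_params("tofts", c(Ktrans = 0.2, Ve = 15)))
  expect_true(ok$valid)
  expect_identical(ok$reason, "none")
  bad_ve <- physiological_filter(list(Ve = 101))
  expect_false(bad_ve$valid)
  expect_identical(bad_ve$reason, "non_physiological")
  expect_false(physiological_filter(list(Ve = 60, Vp = 50))$valid)
  expect_false(physiological_filter(list(F = 400))$valid)
  expect_false(physiological_filter(list(Ktrans = 6))$valid)
  expect_false(physiological_filter(list(MTT = 200))$valid)
  zero <- physiological_filter(list(Ktrans = 0, Ve = 0, Vp = 0))
  expect_true(zero$valid)
})

test_that("volume fitting is deterministic, maps exclusions, and errors on empty masks", {
  cfg <- cohort_config(grid = c(4, 3, 1), n_lesion = 4, n_normal = 4,
                       n_artery = 2, noise_frac = 0, model = "tofts",
                       dispersion = 0.3)
  s <- generate_subject(cfg, seed = 12)
  t <- protocol_times(cfg$protocol)
  conc <- array(NA_real_, dim(s$dynamic_series))
  mat <- matrix(NA_real_, prod(dim(s$labels)), length(t))
  for (k in seq_len(nrow(s$truth))) {
    free <- unlist(s$truth[k, c("Ktrans", "Ve")])
    mat[s$truth$voxel[k], ] <- dcekin:::.tofts(t, s$aif_truth$cp_mM,
                                               free["Ktrans"], free["Ve"])
  }
  # corrupt two voxels with NaN frames
  corrupted <- s$truth$voxel[c(2, 5)]
  mat[corrupted, 1:60] <- NaN
  conc[] <- mat
  mask <- s$labels == 1 | s$labels == 2
  pm1 <- fit_volume("tofts", conc, t, s$aif_truth, mask)
  pm2 <- fit_volume("tofts", conc, t, s$aif_truth, mask)
  expect_identical(pm1$maps, pm2$maps)
  excl <- pm1$table[pm1$table$exclusion_reason == "non_invertible_frames", ]
  expect_setequal(excl$voxel, corrupted)
  expect_equal(sum(pm1$table$valid), sum(mask) - 2)
  expect_true(all(is.na(pm1$maps$Ktrans[corrupted])))
  # valid voxels recover their truth
  ok <- pm1$table[pm1$table$valid, ]
  truth_k <- s$truth$Ktrans[match(ok$voxel, s$truth$voxel)]
  expect_lt(max(abs(ok$Ktrans - truth_k) / truth_k), 0.01)
  expect_error(fit_volume("tofts", conc, t, s$aif_truth, array(0, dim(s$labels))),
               "empty mask")
})

test_that("tidy, glance and autoplot work on a cohort fit", {
  sim <- simulate_roi_curves(2, 2, noise_frac = 0, dispersion = 0.3, seed = 2)
  fk <- fit_kinetic(sim$curves, sim$aif, "tofts")
  td <- tidy(fk)
  expect_true(all(c("roi_id", "parameter", "estimate") %in% names(td)))
  expect_setequal(unique(td$parameter), c("Ktrans", "Ve", "Kep"))
  gl <- glance(fk)
  expect_equal(gl$n_curves, 4L)
  expect_equal(gl$n_valid, 4L)
  p <- autoplot(fk)
  expect_s3_class(p, "ggplot")
  # recovered parameters match the drawn truth
  res <- dplyr::inner_join(fk$results, sim$truth, by = "roi_id")
  expect_lt(max(abs(res$Ktrans.x - res$Ktrans.y) / res$Ktrans.y), 0.005)
})
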