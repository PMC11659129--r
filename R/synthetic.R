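# Synthetic-cohort generation: virtual DCE-MRI subjects with known
# ground-truth kinetics, emulating a fast prostate protocol (120 frames at
# 2 s, VFA flips 5/10/15 degrees, TR 2.8 ms).

# Run code with a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Draw kinetic parameters for a tissue class
#'
#' Each free parameter is drawn log-normally with median equal to the
#' published tissue median for that model and class (see
#' [reference_medians()]) and a configurable log-scale dispersion. Draws
#' violating the physiological bounds (see [physiological_filter()]) are
#' rejected and redrawn, so the generator and the downstream exclusion
#' rules agree by construction.
#'
#' @param tissue_class `"lesion"` or `"normal"`.
#' @param generative_model One of `"tofts"`, `"etm"`, `"brix2c"`, `"ath"`,
#'   `"dp"`.
#' @param n Number of parameter sets to draw.
#' @param dispersion Log-scale standard deviation (default 0.5). At 0 the
#'   draw is deterministic at the medians.
#' @param medians Optional replacement median table (same shape as
#'   [reference_medians()]).
#' @return A tibble with `n` rows and one column per free parameter.
#' @examples
#' set.seed(1)
#' sample_tissue_params("lesion", "tofts", n = 3)
#' @export
sample_tissue_params <- function(tissue_class, generative_model, n = 1,
                                 dispersion = 0.5, medians = reference_medians()) {
  tissue_class <- match.arg(tissue_class, c("lesion", "normal"))
  if (!generative_model %in% setdiff(KINETIC_MODELS, "iauc")) {
    stop(sprintf("unknown generative model '%s'; supported: %s",
                 generative_model,
                 paste(setdiff(KINETIC_MODELS, "iauc"), collapse = ", ")),
         call. = FALSE)
  }
  med <- dplyr::filter(medians, .data$model == generative_model)
  pars <- free_param_names(generative_model)
  med <- stats::setNames(med[[tissue_class]], med$parameter)[pars]
  draw <- function(m) {
    out <- matrix(0, m, length(pars), dimnames = list(NULL, pars))
    for (p in pars) {
      out[, p] <- if (dispersion > 0) {
        stats::rlnorm(m, meanlog = log(med[[p]]), sdlog = dispersion)
      } else rep(med[[p]], m)
    }
    out
  }
  ok_rows <- function(mat) {
    apply(mat, 1, function(row) {
      full <- tryCatch(derive_params(generative_model, row), error = function(e) NULL)
      !is.null(full) && physiological_filter(full)$valid
    })
  }
  res <- draw(n)
  bad <- !ok_rows(res)
  guard <- 0
  while (any(bad)) {
    res[bad, ] <- draw(sum(bad))
    bad <- !ok_rows(res)
    guard <- guard + 1
    if (guard > 1000) stop("parameter resampling did not converge", call. = FALSE)
  }
  tibble::as_tibble(res)
}

#' Simulate ROI-level concentration curves through the full signal chain
#'
#' For each ROI: draws free parameters log-normally around the tissue
#' medians, generates the noise-free tissue curve with the chosen forward
#' model, synthesizes the SPGR signal, adds Gaussian noise, and inverts the
#' signal back to concentration exactly as the measurement pipeline does.
#'
#' @param n_lesion,n_normal Number of ROIs per class.
#' @param model Generative kinetic model.
#' @param protocol An [acquisition_protocol()].
#' @param aif AIF tibble; default the population curve on the protocol grid.
#' @param dispersion Log-normal dispersion of the parameter draws.
#' @param noise_frac Gaussian signal noise SD as a fraction of the baseline
#'   signal (default 0.01).
#' @param t10_s Native tissue T1, seconds.
#' @param m0 Equilibrium signal scale.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list with `curves` (long tibble: `roi_id`, `tissue_class`,
#'   `t_s`, `conc`), `truth` (tibble of drawn parameters per ROI), and
#'   `aif`.
#' @export
simulate_roi_curves <- function(n_lesion, n_normal, model = "tofts",
                                protocol = acquisition_protocol(),
                                aif = NULL, dispersion = 0.5,
                                noise_frac = 0.01, t10_s = 1.4, m0 = 1000,
                                seed = 1) {
  t <- protocol_times(protocol)
  if (is.null(aif)) aif <- population_aif(t)
  xy <- as_aif_xy(aif)
  with_seed(seed, {
    classes <- c(rep("lesion", n_lesion), rep("normal", n_normal))
    truth <- purrr::map_dfr(c("lesion", "normal"), function(cl) {
      nn <- sum(classes == cl)
      if (nn == 0) return(NULL)
      dplyr::mutate(
        sample_tissue_params(cl, model, n = nn, dispersion = dispersion),
        tissue_class = cl, .before = 1)
    })
    truth <- dplyr::mutate(truth, roi_id = dplyr::row_number(), .before = 1)
    base_sig <- spgr_signal(1 / t10_s, m0, protocol$dyn_flip_deg, protocol$tr_ms)
    curves <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      free <- unlist(truth[i, free_param_names(model)])
      ct <- forward_model(model, t, xy$cp, free)
      sig <- signal_from_concentration(ct, t10_s, protocol, m0)$signal
      if (noise_frac > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_frac * base_sig)
      cf <- concentration_from_signal(sig, t10_s, m0, protocol)
      tibble::tibble(roi_id = truth$roi_id[i],
                     tissue_class = truth$tissue_class[i],
                     t_s = t, conc = cf$conc)
    })
    list(curves = curves, truth = truth, aif = aif)
  })
}

# Dispatch a forward model kernel on bare vectors given named free params.
forward_model <- function(model, t, ca, free, n_seg = 50) {
  free <- as.list(free)
  switch(model,
    tofts  = .tofts(t, ca, free$Ktrans, free$Ve),
    etm    = .etm(t, ca, free$Ktrans, free$Ve, free$Vp),
    brix2c = .brix2c(t, ca, free$F, free$PS, free$Vp, free$Ve),
    ath    = .ath(t, ca, free$F, free$Tc, free$E, free$Ve),
    dp     = .dp(t, ca, free$F, free$Vp, free$Ve, free$PS, n_seg = n_seg),
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  )
}

#' Configuration for a synthetic subject
#'
#' @param grid Integer vector of 3 volume dimensions.
#' @param n_lesion,n_normal,n_artery Voxel counts per tissue compartment.
#' @param roi_size Voxels per ROI when grouping tissue voxels into ROIs.
#' @param model Generative kinetic model for the tissue voxels.
#' @param dispersion Log-normal dispersion of parameter draws.
#' @param noise_frac Gaussian signal noise SD as a fraction of the baseline
#'   tissue signal; 0 for noise-free data.
#' @param t10_tissue_s,t10_blood_s Native T1 of tissue and blood, seconds.
#' @param m0 Equilibrium signal scale.
#' @param bolus_arrival_s Bolus arrival time of the population AIF, s.
#' @param protocol An [acquisition_protocol()].
#' @return A validated list of class `dce_cohort_config`.
#' @export
cohort_config <- function(grid = c(12, 12, 4), n_lesion = 40, n_normal = 40,
                          n_artery = 8, roi_size = 5, model = "tofts",
                          dispersion = 0.5, noise_frac = 0.01,
                          t10_tissue_s = 1.4, t10_blood_s = 1.7, m0 = 1000,
                          bolus_arrival_s = 10,
                          protocol = acquisition_protocol()) {
  stopifnot(length(grid) == 3, all(grid >= 1))
  n_vox <- prod(grid)
  if (n_lesion + n_normal + n_artery > n_vox) {
    stop(sprintf("config error: %d mask voxels exceed the %d-voxel grid",
                 n_lesion + n_normal + n_artery, n_vox), call. = FALSE)
  }
  if (!model %in% setdiff(KINETIC_MODELS, "iauc")) {
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  }
  stopifnot(inherits(protocol, "dce_protocol"), roi_size >= 1,
            noise_frac >= 0, t10_tissue_s > 0, t10_blood_s > 0, m0 > 0)
  structure(as.list(environment())[c(
    "grid", "n_lesion", "n_normal", "n_artery", "roi_size", "model",
    "dispersion", "noise_frac", "t10_tissue_s", "t10_blood_s", "m0",
    "bolus_arrival_s", "protocol")], class = "dce_cohort_config")
}

#' Generate a synthetic DCE-MRI subject
#'
#' Builds a full virtual acquisition: disjoint lesion/normal/artery masks on
#' one grid, per-voxel ground-truth kinetic parameters drawn around the
#' tissue medians, the 4D dynamic SPGR series, one pre-contrast VFA volume
#' per flip angle (synthesized from the same per-voxel T1/M0), and the true
#' plasma AIF. Artery voxels carry the AIF converted to whole blood via
#' `cb = cp * (1 - hematocrit)`. Additive zero-mean Gaussian noise of the
#' configured level is applied to all signals. Deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `dce_subject`: `dynamic_series` (4D array),
#'   `vfa_series` (list of 3D arrays), `labels` (3D integer array; 0
#'   background, 1 lesion, 2 normal, 3 artery), `truth` (tibble with voxel
#'   index, coordinates, `roi_id`, class, free parameters, `t10_s`),
#'   `aif_truth` (`dce_aif` tibble), `protocol`, `config`, `seed`.
#' @export
generate_subject <- function(config, seed = 1) {
  stopifnot(inherits(config, "dce_cohort_config"))
  p <- config$protocol
  t <- protocol_times(p)
  grid <- config$grid
  n_vox <- prod(grid)
  labels <- array(0L, grid)
  idx_lesion <- seq_len(config$n_lesion)
  idx_normal <- seq_len(config$n_normal) + config$n_lesion
  idx_artery <- seq_len(config$n_artery) + config$n_lesion + config$n_normal
  labels[idx_lesion] <- 1L
  labels[idx_normal] <- 2L
  labels[idx_artery] <- 3L
  aif <- population_aif(t, bolus_arrival_s = config$bolus_arrival_s)
  cb <- aif$cp_mM * (1 - p$hematocrit)   # whole-blood concentration
  with_seed(seed, {
    truth <- purrr::map_dfr(list(c("lesion", 1), c("normal", 2)), function(z) {
      cl <- z[1]
      idx <- which(labels == as.integer(z[2]))
      if (length(idx) == 0) return(NULL)
      pars <- sample_tissue_params(cl, config$model, n = length(idx),
                                   dispersion = config$dispersion)
      dplyr::mutate(pars,
                    voxel = idx, tissue_class = cl,
                    roi_id = paste0(substr(cl, 1, 1), "_",
                                    ceiling(seq_along(idx) / config$roi_size)),
                    t10_s = config$t10_tissue_s, .before = 1)
    })
    nt <- length(t)
    dyn <- array(0, c(grid, nt))
    dyn_mat <- matrix(0, n_vox, nt)
    t10_vox <- rep(config$t10_tissue_s, n_vox)
    t10_vox[idx_artery] <- config$t10_blood_s
    # background voxels: constant baseline tissue signal
    base_tissue <- spgr_signal(1 / config$t10_tissue_s, config$m0,
                               p$dyn_flip_deg, p$tr_ms)
    dyn_mat[] <- base_tissue
    for (k in seq_len(nrow(truth))) {
      free <- unlist(truth[k, free_param_names(config$model)])
      ct <- forward_model(config$model, t, aif$cp_mM, free)
      dyn_mat[truth$voxel[k], ] <-
        signal_from_concentration(ct, config$t10_tissue_s, p, config$m0)$signal
    }
    for (i in idx_artery) {
      dyn_mat[i, ] <- signal_from_concentration(cb, config$t10_blood_s, p,
                                                config$m0)$signal
    }
    vfa <- lapply(p$vfa_flips_deg, function(fl) {
      v <- array(spgr_signal(1 / t10_vox, config$m0, fl, p$tr_ms), grid)
      v
    })
    if (config$noise_frac > 0) {
      sd_noise <- config$noise_frac * base_tissue
      dyn_mat <- dyn_mat + stats::rnorm(length(dyn_mat), 0, sd_noise)
      vfa <- lapply(vfa, function(v) v + stats::rnorm(length(v), 0, sd_noise))
    }
    dyn[] <- dyn_mat
    structure(list(
      dynamic_series = dyn, vfa_series = vfa, labels = labels,
      truth = truth, aif_truth = aif, protocol = p, config = config,
      seed = seed
    ), class = "dce_subject")
  })
}

#' @export
print.dce_subject <- function(x, ...) {
  cat("<dce_subject>\n")
  cat(sprintf("  grid %s | %d dynamics | model %s | seed %d\n",
              paste(dim(x$labels), collapse = "x"),
              dim(x$dynamic_series)[4], x$config$model, x$seed))
  cat(sprintf("  voxels: %d lesion, %d normal, %d artery\n",
              sum(x$labels == 1), sum(x$labels == 2), sum(x$labels == 3)))
  invisible(x)
}
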