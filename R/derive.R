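# Derived-parameter algebra connecting the per-model free parameters to the
# full reported inventory: 6 (DP) + 3 (Tofts) + 4 (ETM) + 6 (two-compartment
# exchange) + 7 (ATH) + 4 (IAUC) = 30 quantities.

KINETIC_MODELS <- c("tofts", "etm", "brix2c", "ath", "dp", "iauc")

free_param_names <- function(model) {
  switch(model,
    tofts  = c("Ktrans", "Ve"),
    etm    = c("Ktrans", "Ve", "Vp"),
    brix2c = c("F", "PS", "Vp", "Ve"),
    ath    = c("F", "Tc", "E", "Ve"),
    dp     = c("F", "Vp", "Ve", "PS"),
    iauc   = c("IAUC60", "IAUC90", "IAUC60No", "IAUC90No"),
    stop(sprintf("unknown model '%s'; supported: %s", model,
                 paste(KINETIC_MODELS, collapse = ", ")), call. = FALSE)
  )
}

#' Expected parameter counts per kinetic model
#'
#' @return A tibble with one row per model and the number of reported
#'   parameters (free + derived) for each: 3 for Tofts, 4 for the extended
#'   Tofts model, 6 for the two-compartment exchange model, 7 for ATH, 6
#'   for DP, and 4 IAUC summaries — 30 in total.
#' @export
param_inventory <- function() {
  tibble::tibble(
    model = c("dp", "tofts", "etm", "brix2c", "ath", "iauc"),
    n_params = c(6L, 3L, 4L, 6L, 7L, 4L)
  )
}

#' Fill in the derived kinetic parameters of a model
#'
#' Given the free parameters of one model, computes the remaining reported
#' quantities:
#' * Tofts/ETM: `Kep = Ktrans / Ve` (1/min).
#' * Two-compartment exchange (`brix2c`): `MTT = Vp / F` (vascular transit,
#'   seconds) and `E = PS / (PS + F)` (percent), the extraction of a
#'   well-mixed compartment.
#' * ATH: `Vp = F * Tc`, `PS = -F * log(1 - E)`, `Kep = E F / Ve` (1/min),
#'   `MTT = Tc`; `E` is reported in percent.
#' * DP: `MTT = Vp / F` (s) and `E = 1 - exp(-PS / F)` (percent), the
#'   plug-flow extraction.
#' * IAUC: the four area summaries pass through unchanged.
#'
#' @param model One of `"tofts"`, `"etm"`, `"brix2c"`, `"ath"`, `"dp"`,
#'   `"iauc"`.
#' @param free Named numeric vector or one-row data frame of the model's
#'   free parameters (units as in [reference_medians()]).
#' @return A one-row tibble: `model` plus one column per reported
#'   parameter.
#' @examples
#' derive_params("tofts", c(Ktrans = 0.15, Ve = 12.61))
#' derive_params("dp", c(F = 20.01, Vp = 2.18, Ve = 9.36, PS = 11.63))
#' @export
derive_params <- function(model, free) {
  model <- match.arg(model, KINETIC_MODELS)
  if (is.data.frame(free)) free <- unlist(free[1, , drop = TRUE])
  need <- free_param_names(model)
  if (!all(need %in% names(free))) {
    stop(sprintf("model '%s' needs free parameters: %s", model,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  p <- as.list(free[need])
  validate_free_params(model, p)
  out <- switch(model,
    tofts = list(
      Ktrans = p$Ktrans, Ve = p$Ve,
      Kep = kep_of(p$Ktrans, p$Ve)
    ),
    etm = list(
      Ktrans = p$Ktrans, Ve = p$Ve, Vp = p$Vp,
      Kep = kep_of(p$Ktrans, p$Ve)
    ),
    brix2c = list(
      F = p$F, PS = p$PS, Vp = p$Vp, Ve = p$Ve,
      MTT = if (p$F > 0) p$Vp / p$F * 60 else NA_real_,
      E = if (p$PS + p$F > 0) 100 * p$PS / (p$PS + p$F) else 0
    ),
    ath = list(
      F = p$F, Tc = p$Tc, E = 100 * p$E, Ve = p$Ve,
      MTT = p$Tc,
      Vp = p$F * p$Tc / 60,
      PS = -p$F * log1p(-p$E),
      Kep = if (p$Ve > 0) p$E * p$F / p$Ve else NA_real_
    ),
    dp = list(
      F = p$F, Vp = p$Vp, Ve = p$Ve, PS = p$PS,
      MTT = if (p$F > 0) p$Vp / p$F * 60 else NA_real_,
      E = if (p$F > 0) 100 * (1 - exp(-p$PS / p$F)) else NA_real_
    ),
    iauc = p
  )
  # ATH reports 7 quantities: F, MTT(=Tc), E, Kep, Vp, Ve, PS — drop the
  # duplicate free Tc from the report but keep MTT
  if (model == "ath") out$Tc <- NULL
  tibble::as_tibble(c(list(model = model), out))
}

kep_of <- function(Ktrans, Ve) {
  if (Ktrans == 0) return(0)
  if (Ve <= 0) stop("Kep undefined for Ve = 0 with Ktrans > 0", call. = FALSE)
  Ktrans / (Ve / 100)
}

validate_free_params <- function(model, p) {
  nn <- function(x, nm) {
    if (!is.finite(x)) stop(sprintf("%s must be finite", nm), call. = FALSE)
  }
  for (nm in names(p)) nn(p[[nm]], nm)
  if (!is.null(p$Ve) && (p$Ve < 0 || p$Ve > 100)) {
    stop("Ve must lie in [0, 100] percent", call. = FALSE)
  }
  if (!is.null(p$Vp) && (p$Vp < 0 || p$Vp > 100)) {
    stop("Vp must lie in [0, 100] percent", call. = FALSE)
  }
  if (!is.null(p$Ve) && !is.null(p$Vp) && p$Ve + p$Vp > 100 + 1e-9) {
    stop("Ve + Vp must not exceed 100 percent", call. = FALSE)
  }
  for (nm in c("F", "PS", "Ktrans", "Tc")) {
    if (!is.null(p[[nm]]) && p[[nm]] < 0) {
      stop(sprintf("%s must be non-negative", nm), call. = FALSE)
    }
  }
  if (!is.null(p$E) && model == "ath" && (p$E < 0 || p$E >= 1)) {
    stop("E must lie in [0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}
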