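#' Reference median kinetic parameters for lesion and normal prostate tissue
#'
#' Published median values of the free parameters of each kinetic model in
#' malignant lesions and normal prostate tissue. These medians calibrate the
#' synthetic-cohort generator: [sample_tissue_params()] draws log-normal
#' parameter values whose median equals the entry for the requested model
#' and tissue class.
#'
#' Units: `F` and `PS` in mL/min/100 mL tissue, `Ktrans` in 1/min, `Ve` and
#' `Vp` in percent, `Tc` (capillary transit time, the ATH vascular phase) in
#' seconds, `E` (ATH extraction fraction) dimensionless in `[0, 1)`.
#'
#' @param model Optional model name to filter by (`"tofts"`, `"etm"`,
#'   `"brix2c"`, `"ath"`, `"dp"`).
#' @param tissue_class Optional tissue class to filter by (`"lesion"`,
#'   `"normal"`).
#' @return A tibble with columns `model`, `parameter`, `lesion`, `normal`.
#' @examples
#' reference_medians("tofts")
#' @export
reference_medians <- function(model = NULL, tissue_class = NULL) {
  tab <- tibble::tribble(
    ~model,   ~parameter, ~lesion, ~normal,
    "tofts",  "Ktrans",    0.15,    0.04,
    "tofts",  "Ve",       12.61,    9.16,
    "etm",    "Ktrans",    0.12,    0.04,
    "etm",    "Ve",       11.44,    9.19,
    "etm",    "Vp",        0.79,    0.04,
    "brix2c", "F",        25.46,    8.55,
    "brix2c", "PS",        4.32,    4.58,
    "brix2c", "Vp",        4.11,    0.51,
    "brix2c", "Ve",        6.60,    7.73,
    "ath",    "F",        32.60,   26.15,
    "ath",    "Tc",        1.28,    0.23,
    "ath",    "E",         0.2709,  0.1109,
    "ath",    "Ve",       10.32,    8.81,
    "dp",     "F",        20.01,   12.10,
    "dp",     "Vp",        2.18,    0.32,
    "dp",     "Ve",        9.36,    8.20,
    "dp",     "PS",       11.63,    4.19
  )
  if (!is.null(model)) {
    mdl <- match.arg(model, unique(tab$model))
    tab <- dplyr::filter(tab, .data$model == mdl)
  }
  if (!is.null(tissue_class)) {
    cls <- match.arg(tissue_class, c("lesion", "normal"))
    tab <- dplyr::select(tab, "model", "parameter", dplyr::all_of(cls))
  }
  tab
}
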