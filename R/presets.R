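# Ground-truth tissue presets for the digital phantom.
#
# Numeric anchors reproduce the study's printed region-of-interest values:
# pre-treatment AUC30 0.067 (extracranial) / 0.058 (intracranial), AUC300
# 0.193 / 0.063, CE-T1 786.1 / 1020.9 ms, T2 128.2 / 111.5 ms, T1 ratios
# 0.429 / 0.497, and post-treatment AUC30 0.008 (extracranial 1 h) / 0.049
# (intracranial 1 h).  Quantities the report does not print (pre-contrast
# T1, ADC, brain-tissue values, post-treatment AUC300) are filled once with
# field-typical values; see the methods vignette for the rationale.

#' Phantom ROI labels
#'
#' Integer label dictionary of the phantom: 0 background, 1 contralateral
#' brain (control tissue), 2 intracranial tumor, 3 extracranial tumor.
#' @export
ROI_LABELS <- c(background = 0L, brain = 1L, intracranial = 2L,
                extracranial = 3L)

#' Ground-truth record for one phantom ROI
#'
#' @param roi_label ROI name (one of `names(ROI_LABELS)` except background).
#' @param t1_ms,t2_ms Pre-contrast relaxation times (ms), `t1 > t2 > 0`.
#' @param ce_t1_ms Post-contrast (steady-state) T1 (ms), `<= t1_ms`.
#' @param adc_mm2_per_s Apparent diffusion coefficient (mm^2/s, > 0).
#' @param auc30,auc300 Target perfusion areas (mmol/L * min).
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @param curve_shape Gamma-variate sharpness passed to
#'   [solve_curve_params()].
#' @return A `ground_truth_record` list with the solved `curve_params` and
#'   closed-form `auc30_true`/`auc300_true`.
#' @export
ground_truth_record <- function(roi_label, t1_ms, t2_ms, ce_t1_ms,
                                adc_mm2_per_s, auc30, auc300, m0 = 1000,
                                curve_shape = 3) {
  if (!(t1_ms > t2_ms && t2_ms > 0))
    stop("need t1_ms > t2_ms > 0")
  if (adc_mm2_per_s <= 0) stop("adc must be positive")
  if (ce_t1_ms > t1_ms) stop("post-contrast T1 cannot exceed pre-contrast T1")
  cp <- solve_curve_params(auc30, auc300, shape = curve_shape)
  rec <- list(
    roi_label = roi_label,
    t1_ms = t1_ms, t2_ms = t2_ms, ce_t1_ms = ce_t1_ms,
    adc_mm2_per_s = adc_mm2_per_s, m0 = m0,
    curve_params = cp,
    auc30_true = gamma_variate_auc(cp$amplitude, cp$shape, cp$scale_s, 30),
    auc300_true = gamma_variate_auc(cp$amplitude, cp$shape, cp$scale_s, 300)
  )
  class(rec) <- "ground_truth_record"
  rec
}

# One scene per timepoint; every scene carries all three tissue ROIs so a
# single phantom holds both tumors plus the control brain, as in the
# intraindividual design.  Contralateral brain is constant across
# timepoints (no significant longitudinal change in the control tissue).
.scene_table <- function() {
  brain <- list(t1 = 1400, t2 = 90, ratio = 1250 / 1400, adc = 0.75e-3,
                auc30 = 0.010, auc300 = 0.020)
  # Pre-contrast tumor T1 anchored so that CE-T1 / T1 equals the printed
  # pre-treatment T1 ratio (extracranial 786.1/0.429, intracranial
  # 1020.9/0.497).
  t1_ex <- 786.1 / 0.429
  t1_in <- 1020.9 / 0.497
  list(
    pre = list(
      brain = brain,
      intracranial = list(t1 = t1_in, t2 = 111.5, ratio = 0.497,
                          adc = 0.90e-3, auc30 = 0.058, auc300 = 0.063),
      extracranial = list(t1 = t1_ex, t2 = 128.2, ratio = 0.429,
                          adc = 1.00e-3, auc30 = 0.067, auc300 = 0.193)
    ),
    `1h` = list(
      brain = brain,
      intracranial = list(t1 = t1_in, t2 = 112.0, ratio = 0.625,
                          adc = 0.90e-3, auc30 = 0.049,
                          auc300 = 0.063 * 0.049 / 0.058),
      extracranial = list(t1 = 1900, t2 = 130.0, ratio = 0.429,
                          adc = 1.05e-3, auc30 = 0.008,
                          auc300 = 0.193 * 0.008 / 0.067)
    ),
    `8h` = list(
      brain = brain,
      intracranial = list(t1 = t1_in, t2 = 112.0, ratio = 0.610,
                          adc = 0.92e-3, auc30 = 0.055,
                          auc300 = 0.063 * 0.055 / 0.058),
      extracranial = list(t1 = 1900, t2 = 140.0, ratio = 0.587,
                          adc = 1.15e-3, auc30 = 0.012,
                          auc300 = 0.193 * 0.012 / 0.067)
    ),
    `24h` = list(
      brain = brain,
      intracranial = list(t1 = t1_in, t2 = 112.5, ratio = 0.615,
                          adc = 0.91e-3, auc30 = 0.056,
                          auc300 = 0.063 * 0.056 / 0.058),
      extracranial = list(t1 = 1900, t2 = 145.0, ratio = 0.620,
                          adc = 1.20e-3, auc30 = 0.020,
                          auc300 = 0.193 * 0.020 / 0.067)
    )
  )
}

.scene_records <- function(timepoint) {
  sc <- .scene_table()[[timepoint]]
  out <- lapply(names(sc), function(roi) {
    v <- sc[[roi]]
    ground_truth_record(roi, t1_ms = v$t1, t2_ms = v$t2,
                        ce_t1_ms = v$ratio * v$t1,
                        adc_mm2_per_s = v$adc,
                        auc30 = v$auc30, auc300 = v$auc300)
  })
  names(out) <- names(sc)
  out
}

#' Phantom preset registry
#'
#' A preset names a timepoint scene (`pre`, `1h`, `8h`, `24h`) plus the
#' tumor ROI of interest; e.g. `"extracranial_pre"` is the pre-treatment
#' scene with the extracranial tumor in focus.  Every preset's scene
#' contains ground truth for all three tissue ROIs.
#'
#' @return Character vector of preset names.
#' @examples
#' preset_names()
#' gt <- preset_ground_truth("extracranial_pre")
#' gt$extracranial$auc30_true   # 0.067
#' @export
preset_names <- function() {
  as.vector(outer(c("extracranial", "intracranial"),
                  c("pre", "1h", "8h", "24h"), paste, sep = "_"))
}

#' @rdname preset_names
#' @param preset_name One of [preset_names()].
#' @return `preset_ground_truth` returns a named list of
#'   [ground_truth_record()]s (brain, intracranial, extracranial) with
#'   attributes `timepoint` and `focus_roi`.
#' @export
preset_ground_truth <- function(preset_name) {
  if (!preset_name %in% preset_names())
    stop("unknown preset '", preset_name, "'; see preset_names()")
  parts <- strsplit(preset_name, "_", fixed = TRUE)[[1]]
  recs <- .scene_records(parts[2])
  attr(recs, "timepoint") <- parts[2]
  attr(recs, "focus_roi") <- parts[1]
  recs
}
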