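# vdamri

Multiparametric MRI and histology quantification of
vascular-disrupting-agent (VDA) response, with a digital phantom for
end-to-end verification.

## The problem

Vascular-disrupting agents such as combretastatin A-4 phosphate collapse
established tumor vasculature and cause central necrosis, but their effect
on intracranial metastases is blunted by the blood–brain barrier.
Preclinical studies assess this with longitudinal multiparametric MRI of
intracranial vs. extracranial tumors — T2 mapping, variable-flip-angle
(VFA) T1 mapping before and after contrast, diffusion-weighted imaging,
and dynamic contrast-enhanced (DCE) perfusion — followed by postmortem
immunohistochemistry.  `vdamri` implements that analysis chain as a
tested, reusable R pipeline for researchers who want the estimators, the
statistics, and a ground-truthed synthetic test bed in one place.

Because animal MRI data of this kind are rarely deposited, the package
ships a digital rat-head phantom that forward-simulates every acquisition
from known tissue parameters, so each stage is verified by parameter
recovery at desk scale.

## Models at the core

* **SPGR signal** (VFA T1 mapping and the DCE readout):
  `S = M0 · sin α · (1 − E1) / (1 − E1 · cos α)`, `E1 = exp(−TR/T1)`.
  T1 is estimated by the classical linearization (regress `S/sin α` on
  `S/tan α`; slope `E1`), with optional 1-D nonlinear refinement.
* **Mono-exponential relaxometry/diffusion**: `S(TE) = S0 · exp(−TE/T2)`
  and `S(b) = S0 · exp(−b · ADC)`, fitted log-linearly with sample-wise
  exclusion of non-positive signals.
* **DCE concentration conversion**: `R1(t) = 1/T10 + r1 · C(t)`, inverted
  through the full SPGR equation with M0 calibrated from the 20
  pre-contrast frames.  Perfusion surrogates are model-free areas under
  the concentration curve: **AUC30** (first 30 s after injection) and
  **AUC300** (first 300 s), plus the **T1 ratio** (post-contrast T1 /
  pre-contrast T1).
* **Phantom kinetics**: tissue curves are gamma variates
  `C(t) = A · t^α · e^{−t/β}` whose closed-form integral (lower incomplete
  gamma) provides the analytic oracle for the trapezoidal AUCs.
* **Histology**: positive-cell rate pooled over three ×200 fields
  (4-connected instance counts), necrosis area fraction over tissue, and
  mean CD31-delineated vessel cross-sectional area.
* **Statistics**: Shapiro–Wilk normality on paired differences, then
  two-sided paired t-tests across timepoints (pre, 1 h, 8 h, 24 h) and
  tumor sites, with a Wilcoxon sensitivity column.

## Worked example

```r
library(vdamri)

ph  <- build_phantom(c(32, 32, 12), "extracranial_pre")
p   <- acq_protocol()
m0  <- phantom_parameter_map(ph, "m0")

# post-contrast T1 from a noiseless 9-angle VFA series
fit <- fit_t1_vfa(simulate_vfa_series(phantom_parameter_map(ph, "ce_t1"), m0, p))
roi_summary(fit$t1, ph$labels, "extracranial")

# DCE: signal -> concentration -> ROI curve -> AUCs
dce   <- simulate_dce_series(ph$labels, ph$ground_truth, p)
bl    <- estimate_baseline(dce)
conc  <- signal_to_concentration(dce, bl$baseline,
                                 phantom_parameter_map(ph, "t1"), p,
                                 mask = ph$labels$labels > 0)
curve <- roi_concentration_curve(conc, ph$labels, "extracranial")
c(auc30 = auc(curve, 30), auc300 = auc(curve, 300, partial = "silent"))

# pooled Ki67 positive rate over three synthetic x200 fields
positive_rate(simulate_histology_fields(1000, 0.122, seed = 5), "Ki67")
```

Output:

```
extracranial CE-T1: 786.1 ms over 210 voxels
AUC30 = 0.0670, AUC300 = 0.1930 mmol/L*min
pooled Ki67 positive rate: 12.2%
```

The fitted CE-T1 equals the preset's ground truth (786.1 ms), the
trapezoidal AUCs match the closed-form integrals of the preset curves to
well under 1%, and the pooled positive rate is exact because positives are
placed by count.

## Command line

```sh
Rscript inst/cli/vdamri.R simulate --out out --preset extracranial_pre --seed 1
Rscript inst/cli/vdamri.R all --out out --seed 1
```

Subcommands: `simulate`, `relaxometry`, `dce`, `stats`, `histo`, `all`.
Outputs are NIfTI maps and series, CSV tables (ROI metrics, concentration
curves, paired comparisons), a checksum manifest, and a markdown report.

## Limitations

The phantom is geometric, not anatomical: no partial-volume effects, no
k-space simulation, no inter-timepoint motion, and simple gamma-variate
kinetics.  See the methods vignette (`vignettes/vdamri-methods.Rmd`) for
the modelling choices, defaults, and what passing recovery tests do and do
not establish about real data.
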