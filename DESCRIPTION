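Package: vdamri
Title: Multiparametric MRI and Histology Quantification of
    Vascular-Disrupting-Agent Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing tumour response to vascular-disrupting
    agents with multiparametric MRI and quantitative histology.  Provides a
    digital rat-head phantom that forward-simulates variable-flip-angle T1,
    multi-echo T2, diffusion-weighted and dynamic contrast-enhanced
    acquisitions (spoiled-gradient-echo signal model, Rician magnitude
    noise) from ground-truth tissue presets; voxel-wise relaxometry fitting
    (T1, T2, ADC); model-free semi-quantitative perfusion metrics (initial
    area under the gadolinium concentration curve over 30 s and 300 s, T1
    ratio); longitudinal region-of-interest statistics with paired
    comparisons; and quantifiers for immunohistochemistry positive-cell
    rate, necrosis area fraction and vessel cross-sectional area.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
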