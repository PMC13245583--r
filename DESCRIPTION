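Package: oxibold
Title: Constrained Quantitative BOLD and ASL Mapping of Brain Oxygen Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for constrained quantitative BOLD
    (qBOLD) brain oximetry combined with arterial spin labeling perfusion
    imaging. Provides a digital phantom and acquisition simulator for
    multi-echo SSFP FID/ECHO data, velocity-selective venous spin labeling,
    and pseudo-continuous ASL; estimation of prior constraint maps (R2, R2',
    delta-chi, delta-B0, venous CBV, CBF); a voxelwise constrained nonlinear
    inversion yielding venous oxygen saturation, deoxygenated blood volume,
    and oxygen extraction fraction maps; CMRO2 quantification by Fick's
    principle; a cohort simulator with age-structured regional physiology;
    and the region-of-interest statistical battery used in aging studies
    (normality-gated group and paired tests, Benjamini-Hochberg false
    discovery rate control, age regressions, laterality indices, volumetrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    RNifti,
    minpack.lm,
    lmtest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
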