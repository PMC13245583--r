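# oxibold

Constrained quantitative BOLD (qBOLD) + arterial spin labeling analysis of
brain oxygen metabolism, as an R package: a self-consistent digital-phantom
simulator for the three acquisitions, estimation of the measured prior maps,
the voxelwise constrained inversion for oxygen extraction fraction (OEF),
CMRO2 quantification by Fick's principle, and the full region-of-interest
statistical battery used in aging studies.

## The science

Deoxyhemoglobin makes venous blood paramagnetic. In the static dephasing
regime, a voxel containing a deoxygenated blood volume fraction DBV loses
multi-echo signal as `exp(-DBV * fc(δω·t))`, where

    δω = (4π/3)·γ·B0·Δχ_do·Hct·(1 − Yv)

is the characteristic frequency set by the venous oxygen saturation Yv, and
`fc` is the standard static-dephasing decay function (quadratic at short
times, unit slope asymptotically). Paired SSFP FID and ECHO components decay
with effective rates R2 + R2′ and R2 − R2′, with
R2′ = DBV·δω + R2′_nh splitting reversible relaxation into heme and
non-heme parts. The *constrained* qBOLD inversion estimates
Θ = {Yv, DBV, R2′_nh, χ_nb} per voxel by penalised least squares:

    argmin_Θ Σ_TE |y(TE) − Ξ(Θ,TE)|² + w|Δχ − Ψ(Θ)|² + p|R2′ − Y(Θ)|²

where the measured priors — R2 and R2′ from magnitude decays, Δχ and ΔB0
from phase processing (field mapping + dipole inversion), CBVv from
velocity-selective venous spin labeling — anchor the otherwise
ill-conditioned problem. OEF = (SaO2 − Yv)/SaO2, and with pCASL-derived CBF,

    CMRO2 = CBF · (Hct·19.93) · 0.98 · OEF      [µmol O2/100 g/min]

No subject data are redistributable for this design, so everything is
validated on a digital phantom generated by the same closed-form models the
fitter uses, plus a cohort simulator with published age structure.

## Worked example

Simulate an aging cohort with the default (published) regional anchors and
run the statistical battery:

```r
library(oxibold)

coh <- simulate_cohort(cohort_config(seed = 7))
rep <- run_stats_battery(coh)
rep
#> <oxibold_stats_report> 15 young vs 19 old, 11 regions, FDR q = 0.05
#>   group tests: 18 of 33 BH-significant
#>   sex chi-square: X2 = 5.399, p = 0.020

subset(rep$group_tests, region == "wb",
       c(family, mean_young, mean_old, test, p, q))
#>   family mean_young mean_old test        p        q
#> 1    oef       34.7     42.1    t 4.73e-05 0.000152
#> 2    cbf       48.3     40.5    t 8.07e-03 0.017752
#> 3  cmro2      141.3    144.5    t 7.80e-01 0.858229
```

Whole-brain OEF is higher and CBF lower in the simulated older group while
CMRO2 does not differ — the compensation pattern the generator encodes and
Fick's principle preserves. The age regression recovers the configured
whole-brain OEF slope of 0.15 %/year with sex and normalized brain volume as
covariates:

```r
tidy(fit_age_model(coh, "oef", "wb"))
#>   term        estimate std_error  ci_low ci_high statistic       p std_beta
#> 1 (Intercept)  27.6      23.6    -20.7    75.9      1.17   0.252    NA
#> 2 age           0.147     0.0466   0.052   0.243    3.16   0.00358  0.570
#> 3 sex           2.80      1.81    -0.903   6.50     1.54   0.133    0.226
#> 4 norm_vol      0.0239    0.276   -0.540   0.588    0.0865 0.932    0.0157
```

The imaging side runs end-to-end on a phantom:

```r
ph  <- make_digital_phantom(dim = c(16, 16, 16))
ser <- simulate_ausfide(ph, noise_sd = 0)
pri <- fit_prior_maps(ser, simulate_vsvsl(ph), simulate_pcasl(ph))
fit <- fit_qbold(ser, pri, hct = ph$hct)
fit
#> <qbold_result> 1904 voxels fitted, 100.0% converged, median 10 iterations
#>   OEF: median 0.376 [0.360, 0.410]
```

`run_pipeline(pipeline_config(...), out_dir)` chains phantom → simulate →
priors → inversion → CMRO2 → ROI summaries → cohort statistics with cached,
resumable artifacts (NIfTI volumes, TSV tables, a frozen YAML config and a
provenance JSON).

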