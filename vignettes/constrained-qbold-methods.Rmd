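---
title: "Constrained qBOLD oxygen-metabolism mapping: models, simulator, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained qBOLD oxygen-metabolism mapping: models, simulator, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxibold)
```

## The problem

Oxygen extraction fraction (OEF) is the fraction of arterially delivered
oxygen that tissue removes from the blood. Combined with cerebral blood flow
(CBF) and hematocrit it yields the cerebral metabolic rate of oxygen through
Fick's principle,

$$\mathrm{CMRO_2} = \mathrm{CBF}\cdot C_a \cdot S_aO_2 \cdot \mathrm{OEF},
\qquad C_a = \mathrm{Hct}\cdot C_{rbc},$$

with $C_{rbc} = 19.93\ \mu$mol O$_2$/mL the oxygen binding capacity of red
cells and $S_aO_2 = 0.98$ assumed. Quantitative BOLD (qBOLD) infers the
venous oxygen saturation $Y_v$ (hence OEF $=(S_aO_2-Y_v)/S_aO_2$) from the
reversible part of the transverse relaxation signature that deoxyhemoglobin
imprints on multi-echo gradient-echo-like signals. `oxibold` implements the
*constrained* variant: independently measured maps — R2, R2$'$, a relative
susceptibility map, a field map, venous blood volume (CBVv) from
velocity-selective venous spin labeling, and CBF from pCASL — enter a
voxelwise penalised least-squares inversion so that the notoriously
ill-conditioned qBOLD problem is stabilised by physics-consistency
constraints rather than by spatial smoothing or machine-learning denoising.

Because no imaging data are redistributable for this design, the package is
organised around a fully self-consistent *digital phantom*: the same
closed-form forward models generate the synthetic acquisitions and drive the
fitting, so every estimator can be validated against known ground truth.

## Signal model

The static dephasing regime describes extravascular signal decay around a
random network of vessels through

$$f_c(x) = \frac13\int_0^1 (2+u)\sqrt{1-u}\,
\frac{1-J_0(1.5xu)}{u^2}\,du,$$

which is quadratic ($0.3x^2$) at short times and asymptotically linear with
unit slope, so that a voxel with deoxygenated blood volume fraction DBV and
characteristic frequency

$$\delta\omega = \tfrac{4\pi}{3}\gamma B_0 \Delta\chi_{do}
\mathrm{Hct}(1-Y_v)$$

loses signal as $\exp(-\mathrm{DBV}\,f_c(\delta\omega t))$. The paired
steady-state components decay with effective rates $R_2 + R_2'$ (FID) and
$R_2 - R_2'$ (ECHO, whose reversible time is $TR - TE$), where
$R_2' = \mathrm{DBV}\,\delta\omega + R_2'_{nh}$ splits the reversible rate
into heme and non-heme (tissue iron) parts. `static_dephasing_fc()` is
evaluated by adaptive quadrature; the simulator and fitter share a cached
interpolation table accurate to about $10^{-6}$, so the forward and inverse
models form an exactly consistent pair.

Two more closed forms are shared between simulator and fitter: the four-pool
voxel susceptibility

$$\Psi = \mathrm{CBV}_a[\chi_{oxy} + \mathrm{Hct}\Delta\chi_{do}(1-S_aO_2)]
+ \mathrm{CBV}_v[\chi_{oxy} + \mathrm{Hct}\Delta\chi_{do}(1-Y_v)]
+ (1-\mathrm{CBV}_a-\mathrm{CBV}_v)\chi_{nb},$$

and the R2$'$ decomposition above. The arterial volume fraction
$\mathrm{CBV}_a$ is fixed (default 0.01), not estimated.

## The constrained inversion

Per voxel the package minimises, over
$\Theta = \{Y_v, \mathrm{DBV}, R_2'_{nh}, \chi_{nb}\}$ (and by default a
softly constrained $R_2$, see below),

$$\sum_{TE}\left|y(TE)-\Xi(\Theta,TE)\right|^2
+ w\left|\Delta\chi-\Psi(\Theta)\right|^2
+ p\left|R_2'-Y(\Theta)\right|^2 (+\ \text{analogous } R_2,\ \mathrm{CBV_v}
\text{ penalties}),$$

with the FID and ECHO amplitudes profiled out by a linear solve at every
iterate (variable projection) and bounds
$Y_v\in[0.30,0.98]$, $\mathrm{DBV}\in[0.001,0.1]$,
$R_2'_{nh}\in[0,20]$ s$^{-1}$, $\chi_{nb}\in[-0.2,0.2]$ ppm. Optimisation is
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`); initialisation inverts
the R2$'$ decomposition with DBV started at the CBVv prior, and an optional
multistart over a $Y_v$ grid keeps the lowest objective (ties broken toward
lower DBV).

### Why R2 is softly constrained rather than fixed

The prior R2/R2$'$ maps come from weighted log-linear mono-exponential fits.
Because $f_c$ is curved at small arguments, those rates carry a small
systematic bias (we exclude the three most-curved echoes per component,
which reduces the R2$'$ bias on a typical cortical voxel from ~10% to ~4%,
but a residual $\gtrsim 0.08$ s$^{-1}$ bias in R2 survives every
trim/weighting scheme we evaluated). The inversion amplifies an R2 error by
roughly 15 OEF percentage points per s$^{-1}$: hard-fixing R2 from the
mono-exponential prior therefore caps noiseless accuracy at 1–3 pp. We
instead treat the measured R2 exactly like the other measured constraints —
as a penalty — and let the fit refine it. On a noiseless 16³ phantom this
restores end-to-end OEF recovery to < 0.2 pp everywhere.
`fit_weights(estimate_r2 = FALSE)` restores the strict four-parameter fit.

### Penalty weights

`"auto"` weights are inverse-variance: the per-voxel noise variance,
estimated from second differences of the echo trains (white noise inflates
squared second differences sixfold, while the smooth decay contributes
little), divided by a prior-uncertainty scale for each constraint
(defaults: 0.01 ppm for $\Delta\chi$, 0.2 s$^{-1}$ for R2$'$ and R2, 0.005
for CBVv). Penalties therefore vanish on noiseless data — where the echoes
identify the parameters on their own — and strengthen with noise, trading
variance against the small bias of the measured priors. The bias–variance
trade is monotone in the weights (a property the test suite checks).

### What noise does to voxelwise OEF

A Monte-Carlo study at SNR 100 (amplitude 100, unit per-channel noise),
with *exact* priors and truth-initialised optimisation, shows a per-voxel
$Y_v$ standard deviation near 0.11: once the priors pin
$R_2'$, DBV and R2, the only data pathway separating $\delta\omega$ from the
non-heme rate is the curvature deficit of $f_c$, a few-percent signal
modulation. Voxelwise OEF maps at this SNR are therefore intrinsically noisy
(~10 pp RMSE); the quantity the aging analysis actually uses — the trimmed
ROI mean — is accurate to a few pp. This limitation is stated here because
no choice of penalty weights can remove it without spatial regularisation,
which is deliberately out of scope.

## Prior-map estimators

* `fit_decay_rates()`: per-voxel weighted log-linear fits of the FID and
  ECHO magnitudes give $R_2+R_2'$ and $R_2-R_2'$; their half-sum and
  half-difference give R2 and R2$'$ (negatives clipped to zero and
  flagged); `trim = 3` drops the most-curved echoes per component.
* `estimate_fieldmap()`: temporal phase unwrapping (successive differences
  wrapped into $(-\pi,\pi]$, accumulated) plus a magnitude²-weighted linear
  fit of phase against echo time; voxels whose fitted phase advance per
  1.5 ms spacing exceeds $\pi$ are flagged as beyond capture.
* `invert_dipole()`: order-2 polynomial background removal inside the mask,
  then Tikhonov-regularised inverse filtering with the unit dipole kernel
  $D(k)=1/3-k_z^2/|k|^2$ ($k=0$ term zeroed); `dipole_field()` is the exact
  forward operator used both by the simulator's phase model and as the test
  oracle. The default regularisation $10^{-2}$ reproduces a sphere phantom
  to < 10% relative RMSE away from a 2-voxel boundary shell when the source
  occupies a minority of the FOV.
* `quantify_cbvv()`: $\mathrm{CBV_v} = (\text{control}-\text{tag}) /
  (2\kappa M_{0b})$ with $\kappa = e^{-TI/T_{1b}}$.
* `quantify_cbf()`: the consensus single-compartment pCASL formula with
  defaults $\lambda = 0.9$ mL/g, $T_{1b} = 1.65$ s, $\alpha = 0.85$,
  $\tau = 1.8$ s, PLD $= 2$ s (label duration, $\lambda$, $T_{1b}$ and
  $\alpha$ are conventions, exposed in the configuration).

## The digital phantom and what it does not emulate

`make_digital_phantom()` builds nested geometric solids — an ellipsoidal
head with a CSF shell, a cortical gray matter shell partitioned into
frontal/parietal/occipital sectors, a white matter core, and bilateral
subcortical boxes (thalamus, striatum, and a medial temporal block
containing hippocampus and amygdala) — so that the ROI hierarchy of the
statistics module is exercised one-to-one. Parameter maps are piecewise
constant per region (young- or old-adult OEF/CBF anchors; plausible 3 T
relaxation rates and susceptibilities with iron-rich deep gray structures
given larger non-heme R2$'$), with optional within-region Gaussian jitter.
Truth DBV equals CBVv: the velocity-selective measurement labels precisely
the deoxygenated venous compartment that DBV models, and the constraint
design rests on that identity. A smooth quadratic background field (ppm) is
added to the susceptibility-induced dipole field so that the phase pipeline
(unwrapping, polynomial background removal, dipole inversion) is exercised
realistically — and the polynomial background is exactly removable by the
order-2 detrend, by construction.

The phantom does *not* emulate anatomy, $k$-space acquisition, motion or
physiological noise, partial-volume mixing at boundaries, flow effects in
the SSFP steady state, or diffusion narrowing. Passing tests therefore
demonstrate self-consistency of the estimator chain and correctness of the
statistics, not robustness to those real-data effects.

## The cohort generator

`simulate_cohort()` draws one row per subject: group sizes 15 (younger,
ages uniform on 23–35) and 19 (older, 50–87), sex with male probability
25/34, hematocrit $0.438\pm0.035$ / $0.434\pm0.053$. Each regional metric
follows

$$\text{metric} = \text{anchor}_{\text{group}} +
\beta_{\text{age}}\,(\text{age}-\text{ref}_{\text{group}}) +
\varepsilon,\qquad \varepsilon\sim N(0,\sigma_{\text{group}}),$$

with group reference ages at the midpoints of the age ranges so that group
means equal the anchors in expectation. Anchors, slopes and SDs default to
published young/old group means and per-year regression coefficients for
the 11 regions; CMRO2 is *never* drawn — it is always computed through
Fick's principle from the subject's own OEF, CBF and hematocrit, so its
group structure is a consequence, not an input. Group anchors take
precedence over the slope when the two disagree (the published group means
do not lie exactly on the published regression line); configuring colinear
anchors recovers an exact global age line, which is how the slope-recovery
tests are built. Volumes come from published group means (whole brain
defined as GM + WM; CSF closes the intracranial volume at
$270\pm35$ / $330\pm50$ mL, values chosen once as realistic for the two age
groups). Hemispheric left/right values are symmetric by default with
configurable asymmetry offsets equal to the expected laterality index.

## The statistical battery

`run_stats_battery()` reproduces the aging-study analysis: within-ROI
plausibility filtering (positive, finite) and inclusive 5th–95th percentile
trimming (type-7 linear-interpolation percentiles, applied within each ROI);
Shapiro–Wilk-gated ($\alpha=0.05$) Student t versus Mann–Whitney U group
comparisons (normal approximation with tie correction, no continuity
correction); paired region-versus-whole-brain tests (paired t or Wilcoxon
signed-rank, zeros dropped) with Cohen's $d_z$; Benjamini–Hochberg step-up
adjustment within each family of 11 regions per metric (this family
reproduces the published corrected q-values 0.121, 0.425 and 0.222 exactly);
OLS regressions `metric ~ age + sex + normalized volume` (male = 1, volume
as %ICV) with standardized coefficients and residual diagnostics; Pearson
age correlations; %ICV volumetrics; laterality indices
$(R-L)/(R+L)$ tested against zero; and the sex-by-group 2×2 chi-square
without continuity correction (the published $P=0.982$ pins that
convention). `bh_adjust()` is implemented directly from the step-up
definition and is cross-checked in the tests against both a brute-force
$O(m^2)$ oracle and an independent library implementation.

## Numerical choices and degenerate inputs

Constant samples make the Shapiro–Wilk test undefined; they gate to the
nonparametric branch, and fully degenerate comparisons (both groups constant
and equal) return $p=1$ with a flag. All-zero voxels are marked invalid, not
errors. Negative apparent R2$'$ and CBVv are clipped to zero with flag maps,
never silently. Negative noisy CBF propagates as invalid CMRO2 and is then
excluded by the plausibility filter. Internal units are seconds, s$^{-1}$,
tesla, ppm and fractions; percentages appear only at reporting boundaries.

## Problem sizes

The shipped tests and the acceptance script use a 16³ phantom for the
end-to-end recovery studies (~2000 fitted voxels, about a minute), a 32³
grid for the dipole round trip, 20 replicates of an n = 200 cohort for
confidence-interval coverage, and 200 reduced-scale replicates for the
false-discovery-rate control study. These sizes were chosen so the full
validation runs in a few minutes on a single core while keeping every
Monte-Carlo margin comfortably away from its decision boundary.

## Known limitations

Voxelwise OEF precision at realistic SNR is constraint-limited (see above).
The SSFP amplitudes are treated as free scales, so no information is drawn
from their ratio. Macroscopic-field magnitude effects (through-slab
dephasing) are not modelled in the magnitude signal; the field enters phase
only. The dipole inversion is plain Tikhonov — streaking-suppressed QSM
variants are out of scope. Partial-volume mixtures, multi-delay ASL kinetics
and longitudinal designs are not modelled.
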