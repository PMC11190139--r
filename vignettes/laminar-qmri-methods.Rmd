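---
title: "Depth-resolved quantitative MRI of the cortex: models and methods"
author: "laminarq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved quantitative MRI of the cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarq)
```

# Scope

`laminarq` implements the quantitative chain used in depth-resolved
(laminar) studies of cortical microstructure at ultra-high field: forward
modelling and inversion of an MP2RAGEME acquisition into T1 and T2* maps,
extraction of 10-depth quantitative profiles inside refined cortical ROIs,
reduction of each profile to three scalar metrics, and a case-control /
within-patient inference harness. Because subject-level clinical MRI data
of this kind cannot usually be shared, the package ships a first-class
synthetic-data generator — cortical-slab phantoms with known laminar ground
truth and cohort simulators with calibrated effects — so that every stage
is testable end to end against known truth.

T1 is used throughout as an inverse proxy for intracortical myelin (more
myelin, shorter T1) and T2* as an inverse proxy for local iron (more iron,
faster dephasing, shorter T2*).

# The MP2RAGEME signal model

The sequence applies an adiabatic inversion followed by two rapid
gradient-echo (GRE) readout blocks at inversion times $TI_1$ and $TI_2$
within a cycle of length $TR_\mathrm{seq}$; the second block samples four
echoes. Defaults are the 7T protocol values: $TI_{1,2} = 670/3675.4$ ms,
$TR_\mathrm{GRE1,2} = 6.2/31$ ms, flip angles $4^\circ/4^\circ$, turbo
factor 150, echo times $3, 11.5, 19, 28.5$ ms, $TR_\mathrm{seq} = 6778$ ms,
0.7 mm isotropic voxels.

The longitudinal magnetization is piecewise linear in $m_z$ under each
event — free recovery $m \mapsto mE + (1-E)$ with $E = e^{-t/T_1}$, a
small-flip excitation $m \mapsto m\cos\alpha$, and the inversion — so one
cycle is an affine map $m \mapsto am + b$ and the periodic steady state is
$m_{ss} = b/(1-a)$, defined whenever $|a| < 1$ (always, for physical
parameters). Signals are read at the center excitation of each block
(`simulateMp2rageSignals()`), and combined into the bias-free uniform
contrast

$$\mathrm{UNI} = \frac{S_1 S_2}{S_1^2 + S_2^2} \in [-0.5, 0.5],$$

which is invariant to proton density and receive gain. The tests verify
the closed-form steady state against an event-driven Bloch simulation that
iterates the cycle explicitly.

Two modelling choices deserve note:

* **Inversion efficiency.** Protocol printouts rarely state it. We model
  the inversion as $m_z \mapsto (1 - 2\,\mathrm{eff})\,m_z$, so that
  $\mathrm{eff} = 1$ is a perfect flip and $\mathrm{eff} = 0$ is the
  identity (no inversion), with default 0.96, a typical adiabatic value.
  Efficiency only shifts the lookup curve, which lookup-based estimation
  absorbs; it is configuration, not a fixed truth.
* **Echo-train placement.** Readout blocks are treated as centered on
  $TI_1$ and $TI_2$, with the multi-echo readout affecting only transverse
  decay. This is the standard treatment; intra-block timing detail has no
  effect on the quantities under test.

## T1 estimation

`buildT1Lookup()` tabulates UNI over a T1 grid (default 500–5000 ms, 1 ms
step — covering all 7T tissue from white matter to CSF) and restricts
inversion to the largest strictly monotone branch containing cortical T1
(1500–2500 ms). `estimateT1Map()` inverts voxelwise by linear
interpolation; UNI values off the branch are flagged missing, never
clamped. On grid nodes the round trip is exact; elsewhere the error is
below the grid step.

## T2* estimation

`estimateT2starMap()` fits $s_k = S_0 e^{-TE_k/T_2^*}$ per voxel. The
log-linear ordinary-least-squares solution is used to initialize a
vectorized Gauss-Newton refinement of the untransformed model; the log
transform alone reweights residuals and is biased under noise. Voxels with
non-positive echoes or non-decaying fits are flagged missing. Noiseless
recovery is exact to solver precision, and the refined fit matches an
independent per-voxel Levenberg-Marquardt solver on noisy data.

# Synthetic phantoms and cohorts

## Slab geometry

`makeCorticalPhantom()` builds a WM | GM | CSF slab along one axis with an
optional sinusoidal undulation of both boundaries. Folded cortical
geometry is deliberately out of scope: folding does not change any
computation under test, while the undulation exercises the distance-based
depth field nontrivially. The ribbon must span at least 4 voxels
(e.g. 2.8 mm at 0.7 mm). WM and CSF receive fixed literature-typical 7T
values (T1 1200/4000 ms, T2* 27/100 ms, overridable).

The laminar baseline is a smooth monotone cubic in normalized depth
(`baselineProfile()`): T1 rises from 1745 ms at the WM/GM boundary to
1995 ms at the pial surface (ribbon mean 1860 ms, the scale of healthy
frontocortical values at 7T); T2* rises 26–30 ms. A simulated disease
effect adds a per-patient shift in one affected ROI (default the lateral
orbitofrontal cortex), either uniform across depth or, optionally, growing
linearly with depth (mean-preserving) to exercise the depth-sensitive AUC
metric.

One caveat the phantom makes visible: on a planar ribbon only a handful of
discrete distance-ratio depths exist (about one per voxel layer), so a
10-bin profile has structurally empty outer bins. The undulated default
spreads voxel depths continuously and fills all bins; the profile contract
(exactly 10 values, at most 2 missing) is enforced either way.

## Cohort simulation and effect calibration

`generateCohort()` draws a 48-patient / 10-control design by default: ages
truncated to the 20–55-year inclusion window, about 70% female, severity
(IDS, 0–84) around 33.5 ± 13.5 in patients versus 4 ± 3 in controls,
childhood-trauma scores, antidepressant (50%) and comorbid-anxiety (44%)
flags among patients, and — by default — one patient with unrecorded
IDS/CTQ (questionnaire non-completion; the latent severity still drives
that subject's simulated shift).

Each subject carries a baseline offset $u_i \sim N(0, \sigma_b^2)$
(default $\sigma_b = 70$ ms, the scale of observed between-subject SDs)
common to all ROIs. Patients additionally receive a true shift in the
affected ROI,

$$s_i = \mu + \sigma_s\left(\rho z_i + \sqrt{1-\rho^2}\,\varepsilon_i\right),$$

with $z_i$ the standardized severity score, so that
$\mathrm{cor}(s, \mathrm{IDS}) = \rho$ exactly (default 0.27) and
$\mathrm{SD}(s) = \sigma_s$ (default 40 ms). The mean $\mu$ is set
analytically to $d \cdot s_\mathrm{pool}$, where $s_\mathrm{pool}$ is the
pooled SD implied by the group variances
($\sigma_b^2 + \sigma_s^2$ vs $\sigma_b^2$), so the population
standardized group difference on mean-like T1 metrics equals the target
$d$ (default 0.6). A 10,000-subject Monte-Carlo check in the test suite
confirms the calibration algebra to ±0.05 on $d$ and ±0.03 on $\rho$.

Note that the *observable* severity correlation of a measured metric is
attenuated relative to $\rho$ by the baseline variance:
$\mathrm{cor}(u + s, \mathrm{IDS}) = \rho\,\sigma_s/\sqrt{\sigma_b^2+\sigma_s^2}
\approx 0.13$ under the defaults. The generator calibrates the *mechanism*
(shift–severity coupling), not the attenuated observable.

Two simulation tiers exist. The voxel tier renders full volumes per
subject and exercises the imaging physics and laminar sampling; the
profile tier (`simulateProfileCohort()`) draws the 10-depth profiles
directly with per-depth Gaussian noise (default 15 ms for T1), and is what
keeps 1000-replicate calibration loops at desk scale. All randomness
descends from a single master seed; reruns are bit-identical.

## What the phantoms do not emulate

Folded geometry and partial-volume mixing beyond voxel-box assignment;
B0/B1 field inhomogeneity; motion; Rician noise by default (a Gaussian
channel model is adequate at the simulated SNR and keeps oracles analytic;
a Rician option exists). Passing tests therefore demonstrate correctness
of the computations, not robustness to every artifact of real
acquisitions.

# Depth fields, ROI refinement and profiles

`computeDepthField()` assigns each GM voxel the normalized depth
$d = D_{WM}/(D_{WM} + D_{CSF})$ from Euclidean distances to the nearest
WM and CSF voxels. This distance-ratio (equidistant) model was chosen over
volume-preserving level-set layering deliberately: it is transparent and
checkable against an exhaustive nearest-neighbour oracle, which the tests
do on undulated phantoms; equivolume layering is an extension point, not a
default. Only boundary voxels of each tissue region are searched — the
nearest member of a region to an outside point always lies on its
boundary — which keeps the exact computation fast.

`refineRoiMask()` mirrors the standard atlas-refinement step: dilate the
ROI by 1–3 voxels (6-connected cross per step; default 2, the midpoint of
the usual range) and intersect with the gray-matter segmentation.

`extractDepthProfile()` partitions depth into 10 equal bins (half-open,
last closed; centers $(i-0.5)/10$) and averages non-missing map values per
bin over the mask. Bins with fewer than `minVoxels` voxels (default 10,
a guard for small synthetic ROIs) are missing; profiles with more than 2
missing bins are rejected. Binned means were preferred over
surface-interpolated sampling: with 10 bins over a ≥4-voxel ribbon they
are the simplest estimator with the same contract (10 values per ROI per
hemisphere). `averageHemispheres()` is the depthwise mean with summed
voxel counts, used when lateralization tests justify pooling.

# Profile metrics

Each profile reduces to three numbers (`profileMetrics()`):

* **mean** — arithmetic mean of the non-missing depth values; the
  depth-blind ROI summary.
* **AUC** — $10\int_0^1 p(x)\,dx$ of the 3rd-order polynomial $p$ fitted
  by OLS to the points at $x_i = (i-0.5)/10$; sensitive to how values
  distribute across depth.
* **offset** — $p(0)$, the fitted value at the WM/GM transitional zone
  (evaluation at depth 0, not an extrapolation into WM).

The factor 10 in the AUC makes it commensurate with a sum over the 10
depth samples, so a flat profile of value $c$ has AUC $10c$ and the
AUC/mean ratio of near-flat laminar profiles is 10 to within a fraction of
a percent — the convention under which reported laminar AUC magnitudes sit
at ten times the profile mean. Whether an AUC is integrated from the
fitted polynomial or trapezoid-summed from raw points is a genuine
convention choice; the fitted-integral reading is primary here and any
affine re-convention only rescales group statistics, which are
scale-invariant. Missing bins are excluded from the fit (minimum 8 of 10
points), never imputed.

# Inference harness

`ancovaGroupTest()` fits `metric ~ group + age + sex` by OLS and reports
the partial F for diagnosis (denominator df $N-4$), the covariate-adjusted
group difference as HC − MDD with its t-based 95% CI, and *two* Cohen's d
variants signed MDD − HC: the pooled-SD d from raw group means, and an
adjusted $d = t\sqrt{1/n_1 + 1/n_2}$ from the ANCOVA t. Published ANCOVA
effect sizes are rarely accompanied by their formula, and the two
definitions differ noticeably in unbalanced designs, so the package
reports both rather than privileging a guess.

`kendallCorrelation()` computes tau-b with tie correction, a p-value from
the tie-adjusted normal approximation, and a seeded subject-level
percentile bootstrap CI (2000 resamples by default). Severity analyses use
tau as primary; Pearson r can be derived by the user if wanted.

`lateralizationTest()` is a paired t-test of left vs right metrics per
(ROI, contrast); when no asymmetry is detected the pipeline consumes
hemisphere-averaged profiles, which also halves the number of tests.

`withinPatientAnalyses()` runs only for (ROI, contrast) pairs with a
significant case-control difference — the gated two-stage workflow —
correlating severity (IDS) and trauma (CTQ) with each metric and
contrasting antidepressant use and comorbid anxiety with age/sex
adjustment, among patients only.

Multiple testing follows the two-stage design itself plus
hemisphere-averaging; no further correction is applied by default
($\alpha = 0.05$, complemented by effect sizes and CIs). This mirrors
common practice in small-sample laminar ROI studies; a Benjamini-Hochberg
pass can be applied downstream on the tidy results table if desired.

# Numerical and calibration choices

* Lookup grid 1 ms; inversion restricted to the monotone branch; linear
  interpolation. T2* fitting: up to 50 Gauss-Newton iterations,
  relative-step tolerance $10^{-12}$, singular normal matrices fall back
  to the log-linear solution for that voxel.
* Degenerate inference inputs are contracts, not crashes: identical metric
  values with balanced covariates give $F = 0, p = 1$; all-tied
  correlation input, single-sex designs and sub-3-subject groups raise
  descriptive errors.
* **Null calibration.** The type-I-error replicates use the *complete*
  null — group shift $d = 0$, severity coupling 0, and shift SD ≈ 0 — under
  which the groups are exchangeable and the F test's level is exact. If
  instead only the mean shift is zeroed while patients keep extra shift
  variance, the groups become heteroscedastic and the pooled-variance test
  is mildly conservative (about 3% analytically at these defaults); that
  is a variance effect, not a size distortion of the null model, so the
  calibration targets the exchangeable null.
* Problem sizes in the shipped tests and acceptance script: Bloch-oracle
  checks at 4 T1 values; noiseless round trips on a 64×64×64 slab;
  1000 profile-tier replicates for the null calibration and 100 for CI
  coverage; 100 tied datasets ($n \le 50$) for the tau oracle. These sizes
  give Monte-Carlo standard errors comfortably inside the asserted bands.

# Known limitations

* The distance-ratio depth is not the equivolume laminar model; on curved
  ribbons the two disagree systematically. Group contrasts are unaffected
  (the mapping is common to all subjects), but absolute per-depth values
  are convention-dependent.
* On thin ribbons the outer depth bins are sparsely populated; the binned
  estimator reports them missing rather than extrapolating, and the offset
  metric then rests on the polynomial fit of interior depths.
* The ANCOVA assumes homoscedastic groups; with a true variance difference
  between groups its CI is conservative (the coverage simulations show
  this directionally).
* The generator calibrates effects at the population level; single-cohort
  empirical effect sizes at $n = 48/10$ scatter widely around the target,
  which is a property of the design, not the generator.
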