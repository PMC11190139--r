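# laminarq

Depth-resolved ("laminar") quantitative MRI of the cortex, end to end, in
R. The package is aimed at researchers who study cortical microstructure —
intracortical myelin proxied by the longitudinal relaxation time T1, local
iron proxied by the apparent transverse relaxation time T2* — in
case-control designs at ultra-high field, and at methodologists who need a
fully synthetic, ground-truth-known testbed for that analysis chain.

It implements:

* **MP2RAGEME signal modelling and map estimation.** The periodic steady
  state of the longitudinal magnetization under inversion + two rapid
  gradient-echo readouts is solved in closed form; each sequence cycle is
  an affine map m ↦ a·m + b of m_z, so the steady state is b/(1 − a).
  T1 is estimated by inverting the bias-free uniform contrast
  UNI = S₁S₂/(S₁² + S₂²) through a lookup table restricted to its monotone
  branch; T2* by per-voxel least squares on the multi-echo decay
  s_k = S₀·exp(−TE_k/T2*), log-linear initialization plus Gauss-Newton
  refinement.
* **Synthetic cortical phantoms and cohorts.** WM | GM | CSF slabs with
  optional boundary undulation, depth-dependent laminar T1/T2* baselines,
  and a calibrated cohort generator (48 patients / 10 controls by
  default) in which the patients' true T1 shift has a target standardized
  group effect (Cohen's d = 0.6) and a target shift-severity correlation
  (ρ = 0.27).
* **Laminar sampling.** Distance-ratio cortical depth fields
  d = D_WM/(D_WM + D_CSF), atlas-style ROI refinement (dilation ×
  gray-matter intersection), and 10-depth profile extraction per
  ROI × hemisphere × contrast.
* **Profile metrics.** Each profile reduces to its mean, the area under a
  3rd-order polynomial fit (AUC = 10·∫₀¹p(x)dx, so a flat profile c has
  AUC 10c), and the offset p(0) at the WM/GM transitional zone.
* **Inference.** ANCOVA `metric ~ group + age + sex` with partial F,
  adjusted group-difference CI (HC − MDD) and two Cohen's d variants;
  Kendall tau-b severity correlations with seeded bootstrap CIs; paired
  lateralization tests; and gated within-patient analyses.

## Worked example

```r
library(laminarq)

## forward-simulate one cortical voxel and combine the two readouts
p <- acquisitionParams()          # 7T protocol defaults
s <- simulateMp2rageSignals(1800, p)
uniContrast(s$s1, s$s2)
#> [1] -0.25277                   # S1 = -0.013613, S2 = 0.050161

## full synthetic case-control study (profile tier, 48 MDD / 10 HC)
res <- runCaseControl(defaultRunConfig())
subset(res$stage1, roi == "lOFC" & contrast == "T1")
#>  metric statistic df1 df2        p effect_pooled effect_adjusted   ci_lo   ci_hi
#>    mean      9.58   1  54 0.003115         1.148           1.076  -138.5  -29.60
#>     auc      9.58   1  54 0.003115         1.148           1.076 -1384.8 -296.03
#>  offset     10.29   1  54 0.002250         1.188           1.115  -145.7  -33.62
```

Reading the output: with the default generator (a +47 ms mean T1 shift in
the lateral orbitofrontal cortex of patients), the ANCOVA on the
hemisphere-averaged lOFC T1 metrics detects the group effect
(F₁,₅₄ ≈ 9.6–10.3, p < 0.01 in this realization); the confidence interval
is the covariate-adjusted HC − MDD difference in ms (negative: patients
higher), and the two effect-size columns are the pooled-SD and
ANCOVA-t-based Cohen's d (signed MDD − HC). Because the lOFC passed the
case-control gate, `res$stage2` holds the within-patient analyses; e.g.
the severity correlations for this cohort:

```r
subset(res$stage2, term == "ids_score")
#>  metric      term statistic     p  ci_lo ci_hi  n
#>    mean ids_score    0.0805 0.425 -0.155 0.313 47
#>     auc ids_score    0.0805 0.425 -0.155 0.313 47
#>  offset ids_score    0.1267 0.209 -0.114 0.361 47
```

(tau under the default mechanism is small once subject-level baseline
variation attenuates the shift-severity coupling; see the methods
vignette). Single realizations scatter widely at n = 48/10 — calibration
claims live in the test suite and acceptance script, which average over
replicates.

A voxel-tier run (`cfg$simulation$tier <- "voxel"`) renders full phantom
volumes per subject and pushes them through map estimation and laminar
extraction; `inst/scripts/laminarq` exposes `simulate`, `run-all` and
`stats` subcommands over YAML configs.

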