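# strokeclock

Estimating how long ago an ischemic stroke began, from MRI alone.

Patients who wake up with stroke symptoms ("wake-up stroke") usually cannot
receive intravenous thrombolysis because the guideline window — 4.5 hours
(270 minutes) from symptom onset — cannot be verified. Quantitative MRI
offers a way out: the T2 relaxation time of ischemic parenchyma rises
approximately linearly with time from onset, while the apparent diffusion
coefficient (ADC) drops within minutes and then stays low, making ADC an
excellent lesion *locator* but a poor *clock*. `strokeclock` implements the
complete computational chain for evaluating MRI stroke-timing classifiers
of this kind, with a synthetic multiparametric cohort generator standing in
for patient data.

## The statistic at the core

For each patient and each map type *m* (ADC, effective DWI, echo-summed
T2w, quantitative T2, FLAIR) the timing biomarker is the **image intensity
ratio**

&nbsp;&nbsp;&nbsp;&nbsp;R_m = mean(m | ischemic VOI) / mean(m | mirrored non-ischemic VOI),

where the ischemic volume of interest (VOI) is segmented on the
quantitative maps (ADC window 0.30–0.55 µm²/ms, ADC more than one
half-width-half-maximum below the non-ischemic median, T2 window 30–200 ms
to exclude CSF, largest 26-connected cluster(s) kept) and the reference VOI
is its reflection about the mid-sagittal plane with the same T2 limits. A
patient is called *within the window* when R_T2 falls at or below a cutoff
chosen by the maximum Youden index J = sensitivity + specificity − 1 (at or
*above* the cutoff for ADC, which falls rather than rises in ischemia).
Classifiers are compared by Pearson/Spearman/Kendall correlation with onset
time, ROC/AUC (Mann–Whitney with exact binomial CIs, paired DeLong tests,
Bonferroni-adjusted), logistic regression ranked by AICc, and — for the
imbalanced FLAIR subcohort — precision-recall-gain curves (AUPRG), F1
scores, and Randolph's free-marginal multirater kappa
κ = (P̄o − 1/k)/(1 − 1/k) for the visual DWI/FLAIR mismatch reading.

Quantitative maps follow the standard models: three-direction ADC
= −ln(S₁S₂S₃/S₀³)/(3b); ≥6-direction mean diffusivity from a log-linear
tensor fit (trace/3); effective DWI = S₀·exp(−1000·ADC·10⁻³); echo-summed
T2w; voxelwise mono-exponential T2 via signal²-weighted log-linear fitting
with an optional Levenberg–Marquardt refinement.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/05_evaluate.R`; each stage writes its artifacts under
`scratch/run/` and summary tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # 35 virtual patients, 16 within / 19 beyond
Rscript analysis/02_quantitative_maps.R
Rscript analysis/03_lesion_voi.R      # lesion volumes 2.3-5.9 mL here
Rscript analysis/04_intensity_ratios.R
Rscript analysis/05_evaluate.R
```

The final stage prints (seed 7, the analysis default):

```
ROC summary (all patients):
  ratio   auc auc_lo auc_hi     p cutoff youden_j accuracy sensitivity specificity
1   adc 0.461  0.403  0.518 0.706   0.65    0.145    0.600       0.250       0.895
2   dwi 0.579  0.521  0.635 0.440   1.31    0.276    0.629       0.750       0.526
3   t2w 0.993  0.976  0.999 0.000   1.08    0.938    0.971       0.938       1.000
4    t2 1.000  0.988  1.000 0.000   1.17    1.000    1.000       1.000       1.000
```

Read: on this synthetic cohort the T2-relaxation ratio separates patients
scanned before vs after 270 minutes essentially perfectly (AUC 1.00,
Youden cutoff ≈ 1.17), the T2-weighted ratio nearly so, while the ADC ratio
performs at chance (AUC 0.46, p = 0.71) — the qualitative contrast the
method is built around: T2-family intensities carry the clock, ADC does
not. The T2 model separating the classes also explains why its logistic fit
is reported as `separated` rather than with finite coefficients. On the
17-patient FLAIR subcohort the same ranking appears in AUPRG and F1, and
the four synthetic mismatch raters agree with free-marginal κ = 0.32 at
P̄o = 0.55.

In code, the same analysis in five lines:

```r
library(strokeclock)
cohort <- make_cohort(n = 35, seed = 1)          # 16 within / 19 beyond, 17 FLAIR
tab    <- analyze_cohort(cohort)                 # maps -> VOI -> ratios per patient
roc_auc(tab$ratio_t2,  tab$label, "below")$auc   # 0.97
roc_auc(tab$ratio_adc, tab$label, "above")$auc   # 0.37 (chance-level ranking)
youden_cutoff(tab$ratio_t2, tab$label, "below")$cutoff
```

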