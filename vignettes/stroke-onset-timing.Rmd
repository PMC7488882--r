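---
title: "Timing stroke onset from multiparametric MRI: models, phantom design and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing stroke onset from multiparametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeclock)
```

## The problem and the model

Intravenous thrombolysis for ischemic stroke is licensed up to 4.5 hours
(270 minutes) after symptom onset. When onset is unwitnessed, an imaging
clock is needed. Two facts about ischemic tissue make quantitative MRI a
candidate: the apparent diffusion coefficient (ADC) collapses within
minutes of ischemia — from roughly 0.77 to roughly 0.5 µm²/ms — and then
stays low for days, while the T2 relaxation time rises slowly and
approximately linearly with time from onset. ADC therefore localizes the
lesion; T2 times it.

`strokeclock` operationalizes this as the *image intensity ratio*: the mean
of a map over the ischemic volume of interest (VOI) divided by its mean
over the mirror-image contralateral reference VOI. Ratios, rather than
hemispheric differences, cancel proton density, coil sensitivity and
sequence scaling, which is what makes values comparable across scanners.
The within-window decision is "ratio at or below a cutoff" for T2, T2w,
DWI and FLAIR (all rise with time) and "at or above" for ADC; directions
are always explicit arguments, never inferred from the data.

## Signal models

All simulation and fitting use the same three forward models, so noiseless
simulation followed by fitting is an exact round trip (the test suite
asserts recovery to a relative 1e-6):

* Multi-echo T2: \(S(TE) = PD \cdot e^{-TE/T_2}\).
* Diffusion: \(S_g = S_0 \, e^{-b\, g^\top D g \times 10^{-3}}\) with ADC
  in µm²/ms and b in s/mm² (the 10⁻³ reconciles the unit conventions);
  isotropic by default, a diagonal-tensor option exists for validating the
  mean-diffusivity fit.
* FLAIR: \(S = PD\,\lvert 1 - 2e^{-TI/T_1} + e^{-TR/T_1}\rvert\,
  e^{-TE/T_2}\). With TI 2500 ms and TR 10000 ms, CSF at T1 ≈ 4000 ms is
  suppressed well below 10% of the parenchymal signal; with TR 9000 ms the
  suppression is weaker, which is why the glasgow-style preset is the
  default protocol.

ADC estimation has two routes matching clinical protocols: the closed form
\(-\ln(S_1S_2S_3/S_0^3)/(3b)\) for three orthogonal directions, and an
ordinary log-linear least-squares tensor fit with mean diffusivity
= trace/3 for ≥ 6 directions. On isotropic input both equal the scalar ADC;
the tensor route exists so that 20-direction protocols can be simulated
end-to-end without an external tool.

The T2 fit is log-linear weighted least squares with weights proportional
to the squared signal — the first-order variance weighting under which the
log-domain fit matches the signal-domain objective. A per-voxel
Levenberg–Marquardt refinement (`method = "nonlinear"`) is available and
agrees with the log-linear route to better than 0.1% on noiseless data; it
is intended for small volumes, as it iterates voxel by voxel. A
mono-exponential is assumed throughout: multi-compartment decays,
stimulated echoes and B1 effects are out of scope.

## The phantom: what it emulates, and what it does not

The generator produces a three-compartment brain (non-ischemic tissue, CSF
ventricles, one unilateral ellipsoidal lesion) on a 64 × 64 × 24 grid at
2 mm isotropic — small enough that a 35-patient cohort simulates and
analyzes in about a minute, large enough that lesions of a few mL and their
mirrored references are well resolved. Defaults: tissue ADC 0.77 /
lesion 0.50 µm²/ms, tissue T2 80 ms, CSF ADC 3.0 µm²/ms and T2 2000 ms; T1
(used only by FLAIR) 1200/1400/4000 ms for tissue/lesion/CSF, plausible
3T values. Noise is Rician (magnitude MR data), with channel sigma
expressed as a fraction of tissue proton density, default 3%; a Gaussian
option exists for debugging. Rician noise biases low-SNR signals upward,
and the tests assert the resulting positive T2-fit bias and its monotone
decline with SNR.

Lesion T2 grows linearly, \(T_2(t) = T_{2,\mathrm{baseline}}
(1 + s\,t)\), with default slope \(s = 6\times10^{-4}\)/min. No
well-established human slope exists to pin this number; the chosen default
yields lesion-to-contralateral T2 ratios of about 1.09–1.34 across
2.4–9.5 h — on the scale of clinically reported ratio cutoffs (≈ 1.07),
with the synthetic Youden cutoff landing near 1.16–1.17. It is a
calibration choice, configurable, and nothing downstream depends on its
exact value beyond the ratio growing with time.

The default cohort emulates a hyperacute clinical sample: 35 patients,
onsets 2.4–9.5 h drawn uniformly within group-specific ranges so that 16
fall within and 19 beyond 270 minutes; 17 patients (5 within / 12 beyond)
additionally receive FLAIR, mirroring the imbalanced subcohort such
studies report. Per-patient biology is varied: lesion position, size and
hemisphere are jittered, and the lesion's T2 response is scaled by a
patient factor ~ N(1, 0.03²), so T2 ratios overlap across the window
boundary instead of separating trivially. The lesion ADC is deliberately
*not* varied with time or patient: the generator's ground truth is that
ADC carries no timing information, which is exactly what the evaluation
must detect. One deliberate design constraint: the whole cohort shares one
acquisition protocol. Because the FLAIR and non-FLAIR subgroups have
different class balances, any protocol-dependent measurement bias (e.g.
ADC estimator noise interacting with the ADC segmentation window) would
otherwise masquerade as timing information in a parameter constructed to
carry none.

What the phantom does not emulate: real anatomy (no template brains, no
partial-volume mixing beyond three compartments), bias fields, distortion,
motion, registration error (volumes are born co-registered and the midline
is exactly the central sagittal plane), perfusion or penumbral physiology,
and any dependence of ADC on time. Passing tests therefore demonstrate the
*correctness of the computational chain* and the *statistical behavior of
the evaluation suite* under the stated generative model — not clinical
performance on patients.

## Lesion identification

A voxel is ischemic iff all of: `adc_low < ADC < adc_high` (defaults
0.30/0.55 µm²/ms — the literature brackets the lower bound at 0.2–0.4 and
the upper at 0.55–0.6, and the acceptance behavior is insensitive within
those brackets on synthetic contrast); ADC more than one
half-width-half-maximum (HWHM) below the median non-ischemic ADC; and
`30 < T2 < 200 ms` (excludes CSF). The HWHM rule is circular — non-ischemic
statistics require a lesion estimate — and is resolved with one bootstrap
pass: the initial non-ischemic set is the brain minus the ADC-window pass,
then all thresholds are applied once. The HWHM itself is measured on a
Gaussian-kernel density (Silverman's bandwidth) as half the width at half
maximum around the main mode, with the half-crossings linearly
interpolated; for a Gaussian ADC distribution this is 1.177σ, which the
tests verify. A constant (degenerate) histogram returns a vanishing HWHM
rather than an error. Whether the non-ischemic statistics should come from
the whole brain or the contralateral hemisphere only is not settled
anywhere we know of; the implementation uses all non-ischemic brain, and
the candidate mask argument makes the alternative a one-liner.

Candidate masks are refined to connected components (26-neighborhood by
default), keeping the largest plus any component at least half its size —
the operational reading of "the largest cluster, or clusters if there is
more than one lesion". The reference VOI is the reflection of the ischemic
VOI about the mid-sagittal plane within each axial slice, with the same T2
limits removing reflected voxels that land in CSF (the automated stand-in
for manual editing). A VOI whose reflection overlaps itself means a
midline-crossing lesion and is a typed error, matching the clinical
exclusion of bilateral stroke; an empty brain-only segmentation raises a
typed `no_lesion` outcome that cohort analysis records as an exclusion
rather than a crash.

## Evaluation methodology and numerical choices

*AUC* is computed as the Mann–Whitney statistic (ties ½). The default CI is
an exact binomial (Clopper–Pearson) interval on the concordant-pair count —
conservative, since the \(mn\) pairs are not independent — with a
DeLong-variance normal interval as the alternative; the test against
AUC = 0.5 and all pairwise classifier comparisons use DeLong placement
variances (covariance-aware for paired scores), Bonferroni-adjusted across
pairs. A classifier compared with itself is defined to give p = 1.

*Youden cutoffs* are found by exhaustive search over midpoints of adjacent
sorted unique scores plus the two boundary cutoffs that classify everyone
into one class. The boundary points matter: without them the maximum J can
fall below 0 even though the trivial operating points always achieve 0 (a
defect the brute-force oracle test caught during development). Ties in J
break toward the cutoff classifying more patients as *beyond* the window —
favoring specificity, hence treatment safety — and the tie-break is
configurable.

*Diagnostic metrics* carry ±1.96·SE proportion intervals clamped to [0,1];
zero-denominator metrics are flagged undefined instead of poisoning the
rest. *F1* uses SE = √(F1(1−F1)/n) over the n classified items; on a
17-item cohort this reproduces the interval widths conventionally reported
with F1 scores of ~0.73 (±0.21), which a multinomial delta-method SE does
not (±0.30).

*Logistic models* are fitted by IRLS (`stats::glm`), reported with
β/SE/t/p, the model χ² against the intercept-only null, and
AICc = −2lnL + 2k + 2k(k+1)/(n−k−1). Perfect separation — common on
synthetic cohorts whose T2 contrast is strong — is detected (fitted
probabilities collapsing onto the labels) and raised as a typed error,
because diverging coefficients are not a fit; cohort-level evaluation
records such models as `separated`.

*Precision-recall-gain* maps precision and recall through
gain(v) = (v−π)/((1−π)v) at prevalence π and traces the curve over
recall-gain ∈ [0,1], entering at recall = π by linear interpolation of the
classification counts; AUPRG is the trapezoidal area, negative
precision-gain segments contributing negatively. A perfect ranking scores
exactly 1 (and, by enumeration at n = 8, no ranking scores more); the
always-positive classifier scores exactly 0; random rankings average 0.
This is the imbalance-robust companion to ROC used for the 5/12 FLAIR
subcohort.

*Free-marginal kappa* is (P̄o − 1/k)/(1 − 1/k) with k = 3 categories
(match / mismatch / no response — abstentions are a genuine rating
behavior, and k = 3 is the only category count consistent with an
agreement/kappa pair like 0.728/0.59). The CI uses the between-item
variance of per-item agreement. Mismatch adjudication is majority vote of
non-abstaining raters with an arbitrator breaking exact ties.

*Label boundary.* A patient at exactly 270 minutes counts as within the
window (`onset <= 270`); a strict-inequality flag exists because the two
phrasings "within 4.5 h" and "< 270 min" differ only on a boundary no real
cohort occupies.

## A statistical note on chance-level classifiers at n = 35

One end-to-end check asserts that the ADC ratio — constructed to carry no
timing signal — performs at chance. At 16 positives and 19 negatives the
AUC of a truly uninformative score is random with standard deviation
√((m+n+1)/(12mn)) ≈ 0.099, so any band of ±0.1 around 0.5 captures a
correct implementation only about two-thirds of the time at a single fixed
seed. The suite keeps the single-cohort assertion at its stated tolerance
(it documents the intended contrast), and the accompanying
larger-replication properties (null AUC at n = 2000; AUPRG averaging 0
over 1000 shuffles) are the statistically stable versions of the same
claim. A user rerunning the end-to-end block at another seed should expect
the ADC AUC anywhere in roughly 0.3–0.7.

## Problem sizes

Unit tests run on 24³-scale grids; the end-to-end cohort uses the default
64 × 64 × 24 grid with n = 35 (about a minute), chosen so the whole suite
stays interactive while lesions remain multi-hundred-voxel objects. The
brute-force oracle checks use exhaustive small instances (score alphabets
of 3 over n = 6, all 56 label placements at n = 8, 500 random Youden
instances) where enumeration is exact.

## Known limitations

Registration, brain extraction and bias-field correction are upstream of
this package and assumed done (synthetic volumes are born clean); the
midline is the grid's central sagittal plane, so real data would need a
midline estimation step. The mismatch raters are a simple logistic
visibility model — adequate for exercising the agreement arithmetic, not a
model of radiologists. No DICOM ingestion; NIfTI-1 only. The mirrored
reference assumes gross left–right symmetry of the non-ischemic
hemisphere, which real pathology (prior infarcts, leukoaraiosis) violates.
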