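---
title: "Quantifying the r'-wave and scoring the Brugada type-2 pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the r'-wave and scoring the Brugada type-2 pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwavealg)
```

## The problem

Brugada syndrome is diagnosed from a type-1 ECG pattern, either spontaneous
or unmasked by a sodium channel blocker provocation test (SCBPT, e.g.
intravenous flecainide). The provocation test requires hospitalization and
carries arrhythmic risk, so a pre-test estimate of the probability of a
positive result is clinically valuable. In suspected cases the baseline ECG
often shows an incomplete right-bundle-branch-like r'-wave (a "saddleback" /
type-2 pattern) in leads V1 and V2, and the shape of that r'-wave carries
information: a wider, blunter terminal deflection predicts conversion to the
type-1 pattern under drug challenge.

This package implements the measurement and scoring machinery for that
prediction: geometric quantification of the r'-wave from digitized traces,
a four-criterion composite score (the r'-wave algorithm), and the
diagnostic-accuracy statistics needed to evaluate predictors against the
provocation-test outcome.

## The triangle model of the r'-wave

All geometry lives in the *paper-mm frame*: 25 mm/s paper speed and
10 mm/mV gain, so 1 mm is 40 ms horizontally and 0.1 mV vertically. Angles
only make sense in a fixed aspect ratio; this is the one in which the
published cut-offs were derived, and `ecg_calibration()` makes it explicit
and overridable.

Extending the upslope and the downslope of the r'-wave as straight lines
forms a triangle whose apex is their intersection. With `theta_up` the
angle of the upslope from vertical, `alpha` the angle of the downslope from
vertical, and `h` the apex height above the isoelectric line (in mm), the
five criteria are:

* beta-angle: `beta = theta_up + alpha` (degrees);
* alpha-angle: `alpha` itself;
* DBT-5mm: base duration of the triangle cut 5 mm below the apex,
  `40 * 5 * (tan(theta_up) + tan(alpha))` ms;
* DBT-iso: base duration at the isoelectric line,
  `40 * h * (tan(theta_up) + tan(alpha))` ms;
* base/height ratio: DBT-iso in mm divided by `h`, which collapses to
  `tan(theta_up) + tan(alpha)`.

These identities are exact and hold to numerical precision for every
geometry object the package emits; the test suite enforces them at 1e-9.

An r'-wave is *measurable* when its amplitude above baseline and its
descending limb both exceed 0.1 mV, strictly. Unmeasurable waves produce no
criterion values.

## Extraction pipeline and its numerical choices

`extract_rprime()` runs per channel: beat detection by a smoothed-derivative
energy detector (200 ms refractory period), per-beat baseline as the median
of a 40 ms PR-segment window ending 40 ms before QRS onset (robust to P/T
contamination), r'-candidate location, limb fitting, and triangle geometry.

Decisions that were genuinely open and how they were settled:

* **r' candidate.** The r' is the *terminal* positive deflection: the last
  local maximum between the R peak and the QRS offset, gated at 0.05 mV
  above baseline. J-point elevation without a discrete peak is treated as
  no r'. Candidates are screened on a 10 ms moving-average trace with a
  0.05 mV *prominence* filter: of two neighbouring peaks whose valley comes
  within 0.05 mV of the lower one, the lower is discarded. Without the
  prominence filter, noise bumps riding on the descending limb regularly
  masquerade as the terminal peak.
* **Limb fitting.** The published measurements were manual tangent lines;
  how they were drawn is not recoverable. Each limb is fitted by least
  squares to the samples in the 20–80% vertical band between the apex and
  the adjacent (prominence-screened) local minimum. The band excludes apex
  rounding and foot curvature; its bounds are configurable. Two numerical
  details matter. First, voltage is regressed on time, not the reverse:
  time is exact while voltage carries the noise, and regressing time on
  voltage attenuates the slope (an errors-in-variables bias of about 1.5
  degrees at 0.02 mV noise). Second, band membership is decided on the
  smoothed trajectory, because selecting samples by their noisy values
  truncates the noise distribution at the band edges and biases the fitted
  slope shallow (about +2 degrees at 0.02 mV noise before the fix).
* **Apex.** The triangle apex is the intersection of the two fitted lines,
  which may sit slightly above the sampled maximum; `h` is measured from
  this intersection. Limbs with fewer than 3 samples in the band fail the
  fit and mark the beat unmeasurable; an apex at or below the isoelectric
  line is likewise unmeasurable.
* **Sampling floor.** Records below 250 Hz are rejected: a typical limb
  spans only a few tens of ms, and slope estimation needs several samples
  inside the fit band.

`aggregate_patient()` mirrors the published protocol: criteria are averaged
over measurable beats within each lead placement (V1 or V2 at the II°,
III° or IV° intercostal space, each placement distinct), and the patient's
"major" value of each criterion is the maximum of the per-placement means,
taken independently per criterion.

## The r'-wave algorithm

`score_patient()` awards one point per criterion at the published cut-offs
(inclusive): beta >= 40°, alpha >= 24°, DBT-5mm >= 120 ms, DBT-iso >= 80 ms.
The 0–4 sum predicts a positive provocation test at score >= 2. The score is
an unweighted count; weights are configurable for sensitivity analysis but
the published algorithm does not use them. A patient with no measurable
r'-wave at any placement scores 0 and is predicted negative — the absence
of a measurable r' is evidence against the pattern. Because the published
denominators are not stated, evaluation supports both a `measurable_only`
mode (unmeasurable patients excluded from single-criterion ROC) and an
`all_patients` mode (unmeasurable ranked below every measured value).
`measurable_only` is the default: the published single-criterion AUCs match
the summary statistics of the measurable subpopulation, not of the full
cohort.

## Diagnostic-accuracy statistics

`roc_auc()` computes the empirical (Mann–Whitney, tie-aware) AUC with the
DeLong placement-value variance and a Wald 95% CI clipped to [0, 1];
`delong_compare()` tests paired AUC differences with the DeLong covariance
and a two-sided normal p-value. `youden_cut()` scans midpoint thresholds and
breaks ties toward the lowest threshold (maximizing sensitivity).
`mcnemar()` uses the exact two-sided binomial test below 25 discordant
pairs and the continuity-corrected chi-squared above. `icc_agreement()` is
the two-way, absolute-agreement, single-measurement ICC (ICC(A,1)) with the
standard F-based interval; the published agreement analysis names no model,
and ICC(A,1) is the conservative conventional choice for "do two observers
produce the same number". None of these applies multiplicity corrections,
matching the reporting style of the source analyses.

## What the synthetic data emulates — and what it does not

`gen_waveform()` builds beats whose r'-wave is an exact triangle with
requested angles and height riding on a stylized qRS complex, plus optional
white noise (default 0.01 mV, 500 Hz). It exists to give the extractor a
known ground truth; it does not model P/T waves, baseline wander,
respiration, or muscle artifact. Passing recovery tests on it shows the
geometry engine is correct, not that detection is robust to every clinical
artifact.

`gen_cohort()` draws a latent triple (theta_up, alpha, h) per patient from
class-conditional truncated normals (theta_up in 1–45°, alpha in 1–70°, h
in 0.5–8 mm — physical plausibility bounds) and derives all five criteria
through the exact identities, which induces the strong inter-criterion
correlation a composite score must contend with. Calibration targets are
the published per-class mean ± SD of the measurable subpopulations
(`cohort_preset("table3")` for the test cohort, `"table5"` for the
validation cohort): alpha is matched directly; theta_up = beta − alpha is
assumed independent of alpha so its variance is the difference of the
printed variances (floored at (3°)² where the printed beta SD does not
exceed the alpha SD, as in the test-cohort positive class); h is set so the
derived DBT-iso mean matches, with its spread from a delta-method CV
decomposition. Measured features add independent per-criterion observer
noise carrying fraction 1 − ICC of the printed variance, with ICC = 0.92,
the midpoint of the published intra/inter-observer agreement — the printed
tables are consensus human measurements, and a generator without observer
noise would make the five criteria unrealistically redundant.
Measurability per intercostal level is Bernoulli with the published class
frequencies.

Known limitation: normal latents cannot reproduce the skewness the printed
numbers imply. The published negative-class alpha mean (24.6°) sits *above*
the 24° cut-off, yet the published specificity of that criterion is 71%,
which requires a right-skewed distribution with median well below the mean;
similarly the negative-class DBT-5mm mean sits essentially at its 120 ms
cut. Under symmetric latents, measurable negative-class patients meet
individual criteria at markedly higher rates than the published accuracy
figures imply, which compresses the advantage of the composite score over
the best single criterion. Replicate experiments on these synthetic cohorts
therefore reproduce the published sensitivity/specificity of the score to
within about 0.1, but not the published margin by which the composite AUC
dominates every single criterion.

## Problem sizes used in validation

The packaged checks use: 1,000 replicates per binormal AUC replication;
a 150-combination noiseless recovery grid (6 upslope angles × 5 downslope
angles × 5 heights, sampled at 2000 Hz so the steepest limbs keep at least
3 samples in the fit band); 1,000 random small instances for the
brute-force oracle comparisons; 2,000 null simulations at 50 per class for
the DeLong size check; and 200 seeded validation-cohort replicates
(47 positive / 150 negative) for the composite-score experiments. All
randomness is behind explicit seeds.
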