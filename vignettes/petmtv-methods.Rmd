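---
title: "petmtv: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petmtv: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `petmtv`, the
parameters a user may want to change, the numerical conventions that make
results reproducible, and the limits of what the synthetic ground truth can
establish.

## 1. Reference quantification of FDG-avid foci

The package treats an SUV volume as a 3-D array on an anisotropic grid
(default 3.18 × 3.18 × 5.0 mm, so one voxel is 0.050562 ml). Quantification
proceeds in five steps.

**Detection threshold.** FDG-avid foci are preselected by a patient-specific
threshold computed from a mediastinal blood-pool region:
`T = 2·mean + 2·SD` of the SUV over the region. The SD is the *population*
SD (divisor N): blood-pool regions contain hundreds of voxels, so the
distinction from the sample SD is negligible, but fixing one convention
keeps thresholds bit-reproducible. Voxels strictly above `T` are candidate
tissue.

**Focus extraction.** Foci are connected components of the supra-threshold
voxel set. Default connectivity is the permissive 26-neighbourhood
(`connectivity = 6` is available); hot-spot PET work conventionally treats
diagonal contact as connected. Components whose volume
(voxel count × voxel volume) is below `min_volume_ml = 0.5` are neglected —
the filter is applied to the *detection-mask* volume, before any
re-segmentation or classification, since sub-0.5-ml blobs at this grid
resolution (≤ 9 voxels) are dominated by noise and partial-volume effects.

**SUVpeak.** The mean SUV in a 1.0-ml sphere, the PERCIST convention.
Sphere membership is decided by voxel-centre distance in mm; the centre is
searched over the focus voxels only (so the peak reflects the focus, not a
hotter neighbour), but the sphere may extend into surrounding tissue for
foci smaller than 1 ml — SUVpeak of a small faint focus is deliberately
diluted by its surroundings, which is what makes the measurability
criterion selective. Sphere voxels falling outside the grid are excluded
from the mean.

**Measurability.** A focus is PERCIST-measurable iff
`SUVpeak > 2·mean + 2·SD` of a liver region, with *strict* inequality — the
boundary case is not measurable.

**MTV.** The metabolic tumor volume is segmented by relative thresholding
at 50% of the focus's SUVmax: starting from the focus's maximum voxel, the
mask grows by connectivity through voxels with `SUV ≥ 0.5·SUVmax`. Seeding
at the maximum and growing by connectivity means adjacent structures that
exceed the half-max level but are not connected to this focus stay
excluded; "local SUVmax" is a per-focus notion. MTV is the mask's voxel
count times the voxel volume.

Degenerate inputs are contracts, not surprises: an empty region mask is an
error; a volume with no supra-threshold voxel yields an empty focus list
(not an error); a focus is never empty by construction.

## 2. The synthetic phantom

`generate_phantom()` renders, onto a noisy soft-tissue background
(default SUV 0.8, Gaussian noise SD 0.15 truncated at 0 — SUV cannot be
negative), two box compartments (mediastinal blood pool: mean 1.8, SD 0.2;
liver: mean 2.2, SD 0.25 — typical clinical magnitudes) and a set of
lesions. Lesions are voxelized spheres: exactly
`ceiling(volume / voxel volume)` voxels nearest the intended centre, so the
achieved volume is the requested volume rounded up to whole voxels and is
recorded in the truth table. Lesion voxels are set exactly to the lesion's
SUVmax (noise applies outside lesions), so the pre-blur maximum equals the
requested SUVmax — this is what makes voxel-exact MTV recovery a testable
contract rather than an approximation. An optional isotropic Gaussian blur
(FWHM in mm; 6 mm is a realistic reconstruction resolution for this grid)
emulates partial-volume blurring.

Placement is rejection sampling with a bounded retry budget: lesions keep a
guard band from each other (so connected components remain separable) and
from the compartments (so half-max region growth cannot leak into liver or
blood pool); liver-organ lesions are placed inside the liver compartment
and their SUVmax is raised, if necessary, to 2.5× the liver mean so their
half-max contour stays above the surrounding liver uptake. Physiological
(unsuspicious) foci use the same rendering machinery and differ only in
their classification label.

When lesions are sampled rather than listed, counts are Poisson (defaults:
mean 11 suspicious and 10 physiological foci per patient, matching a
whole-body read of a metastasized cohort), volumes log-normal
(`meanlog = log 2.5`, `sdlog = 1`), SUVmax log-normal truncated at 4, and
organs drawn over bone / lymph node / liver / lung / soft tissue /
breast-pectoral.

**What the phantom does not emulate:** scatter, randoms, reconstruction
(OSEM) artefacts, respiratory motion, heterogeneous lesion texture, or CT.
Passing tests on phantoms therefore establish the *algorithmic* correctness
of thresholding, component extraction and segmentation — not clinical
segmentation accuracy on real images, where partial-volume effects and
heterogeneity dominate.

## 3. The simulated detector

`simulate_detector()` stands in for an automated (neural-network) read.
Its per-focus probability of flagging a suspicious focus is logistic in
log2 volume and SUVmax
(`plogis(intercept + b_vol·log2(MTV) + b_suv·SUVmax)`, slopes ≥ 0), so
sensitivity degrades for small, faint lesions — the qualitative signature
of automated PET readers, which surfaces downstream as missed foci being
smaller and fainter than detected ones. Physiological foci are falsely
flagged at a constant rate, and anatomical labels are corrupted at
per-level confusion rates (defaults 0.02 / 0.12 / 0.20 for body part /
region / subregion, i.e. label accuracy is best at the coarsest level).
Defaults (`intercept -1.9`, `b_vol 1.0`, `b_suv 0.35`) put sensitivity near
0.95 for a 3.6-ml, SUV 8 focus and near 0.5 for a 1.3-ml, SUV 4.7 focus.
The detector reads the reference detection set; it does not introduce foci
of its own (a constant false-positive rate on physiological foci plays
that role at the classification level).

## 4. Evaluation against the reference read

`match_foci()` pairs candidate and reference foci by `(patient, focus)` id
when the candidate read was produced on the same detection set, or by
maximal voxel overlap when masks are supplied (equal overlap breaks toward
the reference focus with higher SUVmax — the hotter focus is the one a
reader would have meant). Status follows the classification pair: TP both
suspicious, TN both unsuspicious, FN reference-suspicious but candidate
unsuspicious *or absent* (a reference focus the automated read never saw is
a miss), FP candidate-suspicious but reference-unsuspicious or absent.

Metrics come in two scopes. *Per focus* pools all foci. *Per patient*
computes the metric within each patient and averages over patients for
which it is defined; a patient with an empty denominator (e.g. no
suspicious focus, for sensitivity) is excluded from the mean — exclusion is
the only option that does not invent a value — and the number of
contributing patients is reported.

Confidence intervals are percentile bootstrap with patient-level
resampling: foci of one patient are correlated (a patient with many large
lesions is systematically easier), so patients, not foci, are the
resampling unit. Default B = 1000, level 95%. Replicates where the metric
is undefined are dropped and counted. The percentile interval (not BCa) is
the minimal construction that is seed-reproducible and assumption-free.

Label accuracy is the fraction of matched foci whose candidate label equals
the reference label at the requested level. Subregion accuracy is computed
only over foci whose *reference* provides a subregion (absent is not
wrong); the most-detailed level compares at the finest reference-provided
level per focus — subregion when present, region otherwise.

## 5. The survival layer

All MTV covariates enter models as `log2(x + 1)`: tumor burden is
right-skewed over orders of magnitude, the +1 ml offset maps 0 (no disease
in an organ system) to 0, and base 2 makes a coefficient the log hazard
ratio *per doubling* of burden.

**Cox fits** maximize the partial likelihood with Efron tie handling
(month-granularity follow-up ties often; Efron is the less biased
convention; Breslow is available) via `survival::coxph`, with Wald SEs from
the inverse observed information, convergence tolerance 1e-9. Monotone
likelihood (perfect separation) and singular information are reported as
errors naming the covariate.

**Forward-LR selection** mirrors the SPSS procedure of that name with its
standard settings: at each step the candidate with the smallest score-test
p-value enters if p < 0.05 (the score test for adding one covariate is
evaluated at the current MLE extended by zero, which reduces to the 1-df
adjusted score statistic); after each entry, included covariates are
re-tested by likelihood ratio and removed while p > 0.10 (never the one
just entered, which prevents entry/removal cycles). The full trace of
tested entries and removals is returned.

**Concordance.** The Gönen–Heller concordance probability estimate is a
function of the fitted risk scores only — each unordered pair contributes
`1/(1 + exp(-|η_i - η_j|))` — and therefore needs no censoring adjustment.
Tied risk scores contribute 1/2, so a null model returns exactly 0.5 (with
a degeneracy flag). The unsmoothed estimator is the default; no kernel
smoothing is applied.

**Model comparison** uses a paired patient-level bootstrap Gauss test: each
replicate resamples patients, refits both models, and records the
difference of their concordances; `z = mean(Δ)/SD(Δ)` is referred to the
standard normal. Replicates that fail to converge are dropped (more than
20% dropped is an error); an identically-zero difference (a model compared
with itself) returns p = 1. One property matters for interpretation: at
the degenerate boundary where *neither* model carries signal, the
concordance is a function of |β̂| and the test becomes strongly
conservative — its size is well below nominal there. Away from that
boundary (models with genuine, comparable discrimination — the regime where
such comparisons are scientifically meaningful) the test holds close to its
nominal size; the test suite checks both behaviours.

**Kaplan–Meier and cutoffs.** The product-limit estimator reports the
median as the earliest time at which survival reaches 0.5 or below
(undefined if never). The log-rank test is the standard
observed-minus-expected statistic. Quartile groups use type-7
(linear-interpolation) quantiles with ties assigned to the lower group —
quartile boundaries are convention-dependent, so the convention is fixed
and documented; collapsed groups (fewer distinct values than groups) are
flagged. `optimal_logrank_cutoff()` scans every midpoint between
consecutive distinct values (including the 0-vs-positive split natural for
zero-inflated organ burden), subject to an arm-size floor of 10% of
patients (degenerate splits otherwise win by chance), and returns the
cutoff maximizing the log-rank χ². Its p-value is reported as *naive*: a
maximally selected statistic is selection-inflated, and the test suite
demonstrates that inflation rather than hiding it.

**Agreement statistics** for paired MTV measurements: Wilcoxon signed-rank
on the raw paired differences (zero differences dropped; exact for ≤ 25
non-zero pairs, normal approximation with tie correction above), squared
Pearson correlation on the `log2(x+1)` scale, and Bland–Altman bias with
`bias ± 1.96·SD` limits of agreement on the raw ml scale.

## 6. The synthetic cohort

`generate_cohort()` draws per-organ MTV from zero-inflated log-normal laws
(organ-wise burden starts at 0 ml for every organ system: not every patient
has disease everywhere), sums them into whole-body MTV, and draws event
times from the proportional-hazards model
`h(t) = h0 · exp(Σ β_k · log2(MTV_k + 1))` with administrative censoring at
a horizon (default 84 months). The default baseline hazard of 0.002/month
yields roughly 60% events over the horizon and median survival of tens of
months — the profile of a metastasized breast-cancer cohort. An
all-censored draw warns rather than fails. Times are continuous by
default; the Efron default in the fitting layer covers externally supplied
month-granularity data.

## 7. Problem sizes and numerical tolerances in the test suite

The suite verifies each operation against an independent brute-force oracle
at sizes where brute force is exact and fast, and each estimator against
its generating parameters at sizes chosen so that sampling error has known
scale: connected components and half-max growth against recursive flood
fill on grids up to 20³; SUVpeak against an exhaustive centre scan;
Gönen–Heller against an O(n²) double loop (n ≤ 20, tolerance 1e-12);
`cox_fit` against a grid-searched hand-written partial likelihood on
4-subject fixtures (tolerance 1e-4, fixtures with unbounded MLEs excluded);
MTV recovery on 20-lesion phantoms spanning 0.5–200 ml (exact without
blur, one surface-layer of voxels with 6-mm blur); detector recovery on
2000 foci over 50 patients with B = 1000 bootstrap and 100-repeat coverage
checks; Cox coefficient recovery at n = 2000 and Wald-CI coverage over 200
cohorts of n = 200; and 1000-replicate null simulations for the size of the
log-rank, signed-rank, Mann–Whitney and concordance-comparison tests.

## 8. Known limitations

- The reference read on phantoms is itself produced by the thresholding
  pipeline; truth lesions the pipeline misses are added back at their true
  volume (flagged `added`), emulating manual addition, but no intra- or
  inter-reader variability is modelled.
- The candidate read shares the reference detection set; detector-specific
  segmentation differences enter only through missed foci, not through
  boundary disagreement on found foci.
- Box compartments and homogeneous spherical lesions are geometric
  idealizations; no claim is made about anatomically realistic shapes.
- The optimized-cutoff p-value is intentionally uncorrected; users who need
  calibrated inference for a selected cutoff must validate it on
  independent data.
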