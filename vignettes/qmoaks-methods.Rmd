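---
title: "Methods: quantitative MOAKS-style cartilage scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative MOAKS-style cartilage scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and data model

`qmoaks` operates downstream of image segmentation: its inputs are tables
of cartilage thickness (mm, orthogonal to the bone surface) at
anatomically corresponded landmarks, an atlas assigning each landmark to
one of the 10 tibiofemoral subregions (central/posterior femur and
anterior/central/posterior tibia, medial and lateral), and ordinal 0–3
semi-quantitative cartilage scores. The anterior femur is excluded by
construction because it belongs partly to the patellofemoral compartment.
No geometry is stored: correspondence is purely by shared landmark id,
assumed established upstream (e.g. by statistical shape/appearance
models). Region sizes may be unequal — tibial subregions are defined as
plateau tertiles but carry very different amounts of cartilage cover — so
no equal-size validation is applied.

## The normative model and its central ambiguity

The normative thickness at each landmark is the arithmetic mean over a
non-OA control cohort. Thinning is declared where thickness falls
strictly below 95% of normative, denudation strictly below 5%. The
construct is sometimes described instead in terms of "percentiles" of the
normative value; since the normative value at a point is a single average,
a percentile of it is ill-posed, and the fraction-of-mean reading is the
package default (`normative_config(mode = "fraction_of_mean")`). A
genuine cross-subject percentile mode
(`mode = "percentile_of_controls"`) is provided: it stores the empirical
per-landmark 5th/95th control quantiles (type-7 linear interpolation) and
uses them directly as thresholds. Neither mode is asserted to be "the"
original construction; they coincide in neither thresholds nor
classifications in general, and with degenerate (zero-variance) controls
the percentile mode collapses both thresholds onto the mean — violating
the requirement that the denudation threshold lie strictly below the loss
threshold — so the constructor rejects that case rather than producing a
vacuous model.

Landmarks whose normative mean falls below `min_normative_mm` (default
0.1 mm) carry essentially no cartilage cover; a 5%-of-normative threshold
there would be vacuous, so such landmarks are excluded from both
numerator and denominator of all area percentages. Regional mean
thickness (ThCtAB) deliberately ignores this mask by default — it is the
plain quantitative thickness construct over the whole subregional bone
area — with a masked variant available for sensitivity analysis.

## Scoring conventions

* **Strict thresholds.** "Less than" is implemented as `<`: a landmark
  exactly at a threshold is not thinned. Whether the original construct
  counted boundary landmarks is unstated; strict inequality is adopted
  and documented.
* **Banding.** The published band labels overlap ("1: 0–10%, 2:
  10–75%"). Resolved as left-open/right-closed with 0 reserved for
  exactly 0%: band 0 iff pct = 0, band 1 iff 0 < pct ≤ 10, band 2 iff
  10 < pct ≤ 75, band 3 iff pct > 75. Rationale: "none" must be
  distinguishable from any positive loss, and a measured 10.0% should
  not already count as the wider category.
* **Area weights.** Landmarks default to uniform unit weight (dense
  correspondences ≈ equal area shares); per-landmark weights are
  honoured everywhere and all percentages are invariant to uniform
  weight rescaling.
* **Precision.** Percentages are carried at full precision; rounding to
  printed precision (integer percent, ρ to 2 dp) happens only at report
  time, half-up.

## Within-grade change

At follow-up visits the special codes +0.5 / −0.5 record definite
worsening/improvement that does not cross a whole-grade boundary. Change
resolution maps a whole-grade follow-up to `follow − baseline` and a
±0.5 code to ±0.5 directly. For the 0→24-month interval with records at
both 12 and 24 months, the default (`within_grade = "direct"`) uses the
24-month record against baseline; the alternative `"chained"` mode
accumulates visit-to-visit changes so two consecutive half-steps sum to
1. How the original analysis reconciled such sequences is unstated;
both modes are provided and the default is the simpler one. Within-grade
improvements are kept as negative deltas by default
(`drop_improvement = TRUE` to exclude them).

## Statistics

* **Spearman ρ** is computed as the Pearson correlation of midranks —
  the standard tie correction, essential for 4-level ordinal data — from
  pair vectors or directly from crosstab counts (algebraically
  identical). A margin with zero variance makes ρ undefined; this is
  signalled with a distinct `qm_degenerate` warning and `NA`, never
  silently coerced to 0 (degenerate regions print as "n/a").
* **Confidence intervals for ρ** use the Fisher z transform,
  `tanh(atanh(ρ) ± 1.96/√(n−3))`. The method behind the published
  intervals is unstated; Fisher z reproduces the printed cMF interval
  (0.51, 0.66) at n = 297 exactly, which is why it is the default.
* **SRM** uses the sample (n−1) standard deviation — the standard
  convention, documented because it is unstated in the source analyses.
  Complete-case analysis per measure per region; dropped knees are
  counted on the change object.
* **Bootstrap CIs** are percentile intervals over `n_boot = 1000`
  resamples of knees with replacement (2.5/97.5 empirical quantiles,
  type 7). Percentile rather than BCa because it is the simplest method
  consistent with "random samples with replacement"; resamples with zero
  SD are skipped and counted. All resampling is seeded and
  deterministic.

## The synthetic cohort generator

The generator exists so every downstream stage is testable with known
ground truth; it emulates the *statistical structure* the analysis
assumes, not knee anatomy.

* **Normative field**: each subregion's landmarks live on a u×v grid
  (default 8×5, i.e. 400 landmarks — dense enough for percentages in
  2.5% steps at desk scale) carrying a smooth sinusoidal surface
  `base_mean ± spatial_amplitude` (defaults 2.2 ± 0.3 mm, the typical
  femorotibial cartilage thickness scale).
* **Subjects**: thickness = field × mean-one lognormal subject factor
  (`subject_scale_sd = 0.10`) + i.i.d. Gaussian measurement noise
  (`noise_sd = 0.05` mm, the order of reported test–retest precision of
  landmark thickness measurement), clamped at 0. The mean-one
  parameterisation (`exp(N(−σ²/2, σ))`) makes the truth field the exact
  population mean, so the control average is an unbiased normative
  estimator and parameter-recovery checks are well-posed.
* **Lesions**: each progressor knee receives a focal radial depression
  on one region's grid — fraction `depth · (1 + cos(πd/r))/2` of local
  normative thickness removed at grid distance `d` (cosine taper; a flat
  profile is available for constructing exact-fraction scenarios).
  Radius and centre depth advance linearly per elapsed year, supporting
  deeper-only, wider-only and mixed growth. Defaults (radius 1.8 grid
  units, depth 0.35, +0.4 units/yr, +0.25/yr, placed mainly in the
  central medial compartments) describe a medially progressing cohort.
  Lesions never cross region boundaries, which keeps truth fractions
  exact per subregion.
* **Ground truth** is produced by scoring the noise-free maps against a
  normative model built from the truth field — the *same* thresholds
  contract as the scoring module — so a noise-free run reproduces the
  truth identically. The geometric lesion footprint is recorded
  separately (`footprint_pct`): under deeper-only growth the footprint
  is exactly constant while the threshold-based thinned area can only
  grow (pointwise thinning is monotone), and the truth tables expose
  both views.
* **Reader**: true bands pass through a 4×4 row-stochastic confusion
  matrix; `overcall_bias` shifts mass one band up, emulating systematic
  overcalling of affected area; `within_grade_sensitivity` is the
  probability that a sub-band worsening is recorded as +0.5.
* **Determinism**: every output is a pure function of (parameters,
  seed). Per-knee substreams are derived by stable integer hashing of
  the knee index, so enlarging a cohort never reshuffles earlier knees.
  Controls and progressors drawn from one population should share a
  single field (pass `field =` to both generators).

What the generator does **not** model: anatomically realistic bone
shapes, spatially correlated measurement noise, covariate structure
(age/sex/height — deliberately unmodelled, as the normative construct
itself is unstratified), multi-lesion interaction beyond independent
depth compounding, and reader drift over visits. A green test therefore
establishes correctness of the scoring/statistics machinery under the
stated model, not clinical validity of the construct.

## Degenerate inputs and numerical choices

Zero-variance margins (ρ), zero-SD change vectors (SRM) and all-excluded
regions are signalled as errors or distinct `qm_degenerate` warnings with
`NA` results. Empirical quantiles are type 7 throughout. Thickness CSVs
declare 6-decimal precision and round-trip exactly at it. All validation
is fail-fast with offending ids named.

## Known limitations

* The fraction-of-mean vs percentile-of-controls ambiguity cannot be
  resolved from the published description; results from the two modes
  differ, and users comparing against published values should use the
  default.
* Published responsiveness values derive from a specific
  image-segmentation pipeline on a real progression cohort; the package
  reproduces the published concordance statistics exactly from printed
  counts, but SRM magnitudes on synthetic cohorts are model properties,
  not re-estimates of the published ones — only the qualitative ordering
  (thickness SRM > area-percentage SRM > banded-score SRM under
  deeper-than-wider progression) is checked.
* Aggregation of subregional scores into compartment scores (and the
  area-weighting question it raises) is out of scope.
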