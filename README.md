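# qmoaks

Quantitative, landmark-based scoring of knee cartilage thinning and
denudation on the tibiofemoral MOAKS subregions, for researchers comparing
semi-quantitative radiologist grading with automated cartilage morphometry
in osteoarthritis (OA) imaging studies and DMOAD trial design.

## The problem and the construct

MRI cartilage morphology in OA can be graded semi-quantitatively — the
MOAKS cartilage score records, per subregion, the area affected by any
thickness loss (ThMCM) and by full-thickness loss/denudation (dMCM) on an
ordinal 0–3 scale (0: none, 1: 0–10%, 2: 10–75%, 3: >75% of the subregion
surface) — or quantitatively, from segmentation-derived thickness measured
orthogonal to the bone surface at densely corresponded landmarks. The two
constructs are hard to compare directly.

`qmoaks` implements a quantitative analogue of the MOAKS cartilage score
(Q-MOAKS). Given per-landmark thickness maps on a 10-subregion
tibiofemoral atlas (cMF, cLF, pMF, pLF; aMT, cMT, pMT, aLT, cLT, pLT):

1. **Normative model** — at each landmark *l*, the normative thickness
   `m_l` is the mean over a non-OA control cohort. A landmark with
   thickness `t` is *thinned* when `t < 0.95 m_l` and *denuded* when
   `t < 0.05 m_l` (strict inequalities; an empirical-percentile mode is
   available as an alternative).
2. **Area percentages and scores** — per subregion,
   `ThQCM% = 100 · area(thinned ∪ denuded) / area(subregion)` and
   `dQCM% = 100 · area(denuded) / area(subregion)` (area-weighted over
   included landmarks), banded into ordinal ThQCM / dQCM scores with the
   same 0–3 convention as MOAKS. Mean regional thickness ThCtAB is the
   plain (weighted) mean over all subregion landmarks.
3. **Concordance** — 4×4 cross-tabulations, row-wise concordance
   proportions, and tie-corrected Spearman ρ (Pearson correlation of
   midranks) with Fisher-z confidence intervals.
4. **Responsiveness** — standardised response means,
   `SRM = mean(Δ)/sd(Δ)` over 1- and 2-year change, with
   percentile-bootstrap CIs (1000 resamples), honouring MOAKS within-grade
   change codes (+0.5 / −0.5).
5. **Synthetic cohorts** — a generative model (smooth normative field ×
   mean-one lognormal subject factor + Gaussian noise; focal cosine-taper
   lesions that deepen and/or widen per year; an optional simulated reader
   with overcall bias) provides fully ground-truthed data for validation.

## Worked example

Reproduce the published central-medial-femur concordance from the bundled
cross-tabulation counts, then score a synthetic progression cohort:

```r
library(qmoaks)

tabs <- published_crosstabs()
rho <- spearman_midrank(tabs$cMF_ThMCM)
ci  <- spearman_ci(rho, sum(tabs$cMF_ThMCM))
#> cMF ThMCM/ThQCM: rho = 0.59 (95% CI 0.51, 0.66), n = 297
#> MOAKS 2 knees also Q-MOAKS 2: 56% (89/159)

atlas <- make_grid_atlas()                 # 10 regions x 40 landmarks
fp    <- field_params()                    # 2.2 mm +/- 0.3 mm field
field <- make_mean_field(atlas, fp, seed = 1)
ctrl  <- generate_controls(100, atlas, fp, seed = 1, field = field)
model <- build_normative(ctrl$thickness)
prog  <- generate_progression_cohort(50, atlas, fp, lesion_params(),
                                     seed = 2, field = field)
scores <- score_cohort(prog$thickness, model)
head(scores[scores$region == "cMF", ], 3)
#>     knee_id visit_month region thqcm_pct dqcm_pct thqcm_score dqcm_score thctab_mm
#> 1  knee0001           0    cMF       0.0        0           0          0      2.19
#> 11 knee0001          12    cMF       0.0        0           0          0      2.20
#> 21 knee0001          24    cMF       2.5        0           1          0      2.19
```

The first knee's cMF develops a small thinned area by 24 months (2.5% of
the subregion below 95% of normative, so ThQCM = 1) with no denudation.
Two-year responsiveness of mean thickness in that region:

```r
ch  <- paired_change(scores = scores, measure = "ThCtAB",
                     region = "cMF", interval = c(0, 24))
est <- srm(ch)
ci  <- bootstrap_srm_ci(ch, n_boot = 1000, seed = 1)
#> cMF ThCtAB 0->24 months: SRM = -0.58 (95% CI -0.77, -0.39), n = 50
```

The negative sign reflects cartilage loss; score and percentage SRMs are
positive by the same convention.

`run_pipeline(config, out_dir)` orchestrates the full analysis
(simulate → normative build → score → concordance → responsiveness) from a
single JSON config and writes crosstab / correlation / SRM / boxplot
tables plus a seeded run manifest. A command-line front end with the same
stages lives at `inst/cli/qmoaks.R`.

## Documentation

See the methods vignette (`vignettes/qmoaks-methods.Rmd`) for the model,
its assumptions, parameter choices, and limitations.
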