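---
title: "Methods: compartmental age trends of RNA production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental age trends of RNA production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontotrend)
```

## The model and its assumptions

The package analyses an age-resolved, multi-tissue bulk expression matrix
under a two-compartment view of the genome. Housekeeping genes (HG) — the
conserved machinery every cell needs — are identified from a curated list
(HRT-Atlas style plus functional categories); all remaining genes form the
integrative compartment (IntG). The scientific quantity of interest is each
compartment's total RNA production as a function of age, summarized per age
point, and the contrast between the two compartments' trends.

Three modelling commitments shape everything downstream:

1. **Trends live at the per-age-mean resolution.** All regression is
   ordinary least squares on the per-age aggregated means — one equally
   weighted point per age, ten points on the default 1–27 month grid. With
   5–6 genetically heterogeneous animals per tissue × age cell, the
   replicate level is too noisy to model directly, and the published group
   statistics are defined at exactly this resolution: the per-age-mean
   construction reproduces every printed slope, t, r and F of the original
   analysis, which is how the implementation is validated.
2. **Linearity, fixed breakpoint.** Only linear and segmented-linear trends
   are fitted. The segmented analysis uses a breakpoint fixed a priori at
   9 months (the physiological peak of development in *Mus musculus*), with
   closed segments: the breakpoint age belongs to both the 1–9 fit (4
   points) and the 9–27 fit (7 points). No breakpoint estimation,
   polynomials or splines — with 10 noisy points those would be
   overparameterized.
3. **The matrix is already normalized.** Values are taken as normalized
   expression ("RNA production") in arbitrary units; the pipeline applies
   no further normalization (an optional CPM helper exists for raw counts).
   All group-level conclusions are therefore only meaningful relative to a
   common normalization, which is why the HG/IntG *ratio* — invariant under
   any common rescaling — is the headline indicator.

## Aggregation and the confidence interval

Per age, each gene's production is the mean of its values over all valid
(tissue, animal) samples at that age, pooling tissues and sexes; the series
value is the mean of those per-gene means over the set's genes ("gene-first"
aggregation). The alternative — pooling all gene × sample values directly —
is available via `pool = "samples"` but is dominated by the most productive
genes' replicate noise.

The 95% CI is mean ± 1.96 · sd/√n, with the sd taken **across the per-gene
means** (sample sd, n − 1): a standard error across thousands of genes, which
matches the tight published intervals relative to the large between-gene
spread. This is a CI for the compartment mean under gene-level resampling,
not an animal-level CI. With a single gene the interval degenerates to the
mean.

## The CV filter

Between-animal variance is occasionally extreme, so time-point analysis
excludes, per (gene, tissue, age) cell, cells with coefficient of variation
sd/mean ≥ 1 across the replicate animals (sample sd; zero-mean cells are
also excluded). The filter is computed within the cell because that is where
the replicate animals live; a genome-wide per-gene variant is available via
`scope = "gene"`. Exclusion is complete-case within age — no imputation.
Raising the threshold never invalidates additional cells (monotonicity,
property-tested).

A consequence worth knowing: selecting cells with low *sample* CV slightly
truncates upward outliers of a skewed noise distribution, so filtered group
means sit a percent or two below unfiltered ones. The Monte-Carlo recovery
harness quantifies this on synthetic data; the shrinkage is well inside the
sampling noise of the slope estimates at the default settings.

## Trend fits and the slope-equality F test

`fit_trend()` reports slope, intercept, slope se = √(RSS/(n−2)/Sxx), t with
two-sided p on n−2 df, and the Pearson correlation of the same points with
its own p. Degenerate inputs are flagged rather than raised: a constant
series returns slope 0, r = 0, p = 1 (`degenerate = "constant"`); a
zero-residual fit returns p = 0 with `degenerate = "perfect_fit"` (the
"zero" test is relative, RSS ≤ 1e−20 · Syy, so exactly-linear synthetic
series are caught regardless of scale).

`compare_slopes()` implements the slope-homogeneity test with pooled
residual variance s² = (RSS₁+RSS₂)/(n₁+n₂−4) and
F = (b₁−b₂)²/(s²(1/Sxx₁+1/Sxx₂)) on (1, n₁+n₂−4) df — algebraically the
squared t of the group × age interaction in a separate-intercept,
separate-slope model, which is how the tests cross-check it. When both fits
are residual-free the pooled variance vanishes; the comparison is then
flagged degenerate with F = ∞, p = 0 (or F = 0, p = 1 for identical slopes)
instead of erroring, because noiseless synthetic fixtures hit this case
routinely.

**Degrees of freedom are printed with every F.** On the default grid the
segment comparisons have df (1, 4) for 1–9 (4 + 4 points) and (1, 10) for
9–27 (7 + 7 points). Published segment F values sometimes circulate with
interval labels inconsistent with their p-values; since p determines df2 and
df2 determines the interval, reporting df makes every F self-verifying, and
the acceptance tests pin the df-consistent assignment (F ≈ 0.86 on 1–9,
F ≈ 2.56 on 9–27 for the shipped reference means).

## The ratio trajectory and stages

`ratio_series()` is the raw elementwise quotient of the per-age HG and IntG
means — not normalized to its own average. The raw reading is the one under
which the published interval slopes (+0.003 over 1–9 months, −0.011 over
9–18 months) emerge from the shipped means, and it keeps the scale
interpretable (≈3.7 at the first age). Interval slopes reuse `fit_trend()`
on the ratio points of a closed interval; the 9–18 month window is exposed
as an explicit interval because it straddles a stage boundary. Stages (I:
1–6, II: 6–15, III: 15–21, IV: 21–27 months) are closed on both sides —
boundary ages fall on the grid and belong to both adjacent stages, giving
point counts 3, 4, 3, 3; two-point stages report a difference quotient with
a `low_n` flag rather than a regression.

## Gene blocks

Blocks (the DNA-repair set, the HOXA Block I, the developmental Block II)
are resolved against the catalogue with whitespace repair ("GDF 10" →
"GDF10") and explicit reporting of unresolved names. Trajectories are the
same gene-first aggregation; `block_decline_report()` emits the fitted
start level and both segment slopes explicitly because "A − B per month"
phrasings are ambiguous between (start level, decline) and an interval —
emitting both numbers lets either reading be checked. The shipped
56-gene repair list is a curated default of canonical mouse repair genes;
the original analysis' repair block was published only by citation, so
results on the default list are a reference analysis of a comparable block,
not a reproduction.

## The synthetic-data generator

`simulate_dataset()` emulates the study design it stands in for: 17 tissues,
the 10-age grid, 5 or 6 animals per cell (3M+3F or 3M+2F), and two
compartments with piecewise-linear mean paths around the 9-month breakpoint.
Defaults are the study's magnitudes: HG starting near 496 units with an
early slope of −3.04/month, IntG near 135 with −0.92/month, late slopes
attenuated to the published late/early ratios (0.429 and 0.255), and an HG
fraction of 5101/35630. Scale defaults to 2,000 genes — enough for stable
group means while keeping simulation studies fast; the full 35,630-gene
scale is a config choice, not a default.

Each value is baseline_g × tissue_factor_t × trend_g(age) × noise. Noise is
multiplicative log-normal (the pipeline consumes normalized expression, not
counts, so negative-binomial machinery would model the wrong stage), with
the unit-mean parameterization sdlog² = log(1 + CV²). Baselines (log-normal,
sdlog 1) are normalized to mean 1 within each group and tissue factors to
mean 1 across tissues, so that at zero noise the aggregated group series
equals the configured mean path *exactly* — the noiseless limit
(`replicate_cv = 0`, `tissue_effect_sd = 0`) recovers configured slopes to
1e−9 and anchors the whole pipeline's correctness. A configurable fraction
of genes receives replicate CV ≥ 1 so the CV filter has a target.

What the generator does **not** emulate: tissue-specific trend biology, sex
effects, gene–gene correlation, count-level sampling, and batch structure.
Passing tests on synthetic data therefore demonstrate the estimators'
statistical correctness under the design's noise structure, not robustness
to real-data artefacts.

**A bias worth documenting:** the sample CV of 5–6 log-normal replicates is
strongly biased below the population CV (at population CV 1.5 only ≈38% of
cells show sample CV ≥ 1, and even at population CV 10 only ≈85%). So a
"high-variance" gene at population CV 1.5 loses many — not all — of its
cells to the filter. The property tests assert the achievable contrast
(high-variance genes lose cells at a far higher rate than calibrated genes,
which essentially never do) rather than near-total removal, which no
log-normal noise level can deliver at n = 6.

## Calibration of the slope-equality test

`calibration_run()` estimates the test's rejection rate by full-pipeline
simulation. The type-I configuration makes the two compartments
exchangeable — equal levels, equal slopes, *linear* trends
(`late_slope_factor = 1`) and gene-level noise only
(`tissue_effect_sd = 0`) — for two reasons established while designing the
harness:

- with a bent (piecewise) common trend, the linear fits carry systematic
  lack-of-fit that inflates the pooled residual variance, and the test is
  conservative for reasons unrelated to its construction;
- tissue-level shocks are *shared* by both compartments' series (the groups
  are measured on the same samples), positively correlating the two series;
  common shocks cancel from the slope difference while still inflating s²,
  again making the test conservative. The two-regression F test assumes
  independent series, and calibration should test the statistic under its
  own assumptions.

Under the exchangeable null the empirical type-I rate at nominal 5% sits
inside the exact binomial 99% band over 1000 replicates (the acceptance
suite runs exactly this). The corollary for real data, where both
compartments share samples and tissue shocks, is that the F test is, if
anything, conservative there — observed significances are not inflated by
the shared-sample design.

Calibration problem sizes (300 genes, 3 tissues, 1000 replicates; slope
recovery at 2,000 genes, 17 tissues, 20 replicates) were chosen as the
smallest designs at which the Monte-Carlo error of the estimated rates is
comfortably below the decision bands.

## Numerical and design choices

- Sample sd (n − 1) throughout (CV and CI): replicate counts are 5–6.
- Coverage ties (equal total production at the prefix boundary) break by
  descending production then lexicographic gene name — determinism over
  elegance.
- Gene matching is exact after whitespace trimming, case-sensitive by
  default (mouse symbol case is meaningful); case-insensitive mode and a
  numbered-variant expansion (`Hoxa` → `Hoxa1`, `Hoxa13`) are opt-in. The
  cross-group duplicate rule — a symbol spelled into both the housekeeping
  list and the remainder under the active normalization — is a standalone
  predicate (`flag_cross_group()`); it is empty by construction under exact
  matching and an explicit `flagged` vector can override it.
- The variant-expansion rule behind curated housekeeping lists is not a
  well-defined function of symbols alone, so list-derived counts (e.g. a
  5,101-gene HG compartment out of 35,630) are reproducible only with the
  original resolved list; the pipeline recomputes all such counts from
  whatever list it is given.
- `run_pipeline()` treats the config as the single source of truth and
  stamps reports with the seed and a config hash; reruns are byte-identical.

## Known limitations

- Ten age points bound what any trend analysis can resolve; segment fits on
  4 points have 2 residual df and their non-significance is weak evidence.
- The gene-first mean weights every gene equally; a production-weighted
  variant would answer a different (also reasonable) question.
- The CI is a between-gene standard error, not an animal-level uncertainty;
  with correlated genes it understates total uncertainty.
- The slope-equality test inherits the independence caveat above when the
  two series share samples; its p-values are then conservative rather than
  exact.
- Block analyses on the shipped default repair list characterize that list,
  not the original study's unpublished one.
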