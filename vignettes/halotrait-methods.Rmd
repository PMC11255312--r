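---
title: "Methods: gradient response groups, trait normalization, and biomarker selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient response groups, trait normalization, and biomarker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`halotrait` analyses how prokaryotic taxa and their functional gene content
respond to a soil salinity gradient measured as electrical conductivity
(EC, dS m⁻¹). Its inputs are annotation-level tables (taxon abundances,
per-taxon gene abundances keyed by KEGG orthology and CAZyme family ids,
taxon metadata with genome sizes); no sequence-level processing is in scope.

## Response classification

The response of a taxon is modelled as a straight line, abundance on EC,
fitted by ordinary least squares; the two-sided p-value of the slope (t
statistic, n − 2 df) decides significance at α = 0.05. Taxa with total
abundance below 100 across all samples are removed first. No
multiple-testing correction is applied by default because the screening rule
is deliberately per-taxon; a Benjamini–Hochberg option exists
(`classify_taxa(p_adjust = "BH")`) for users who prefer controlled FDR over
fidelity to the screening design. "Abundance" is treated as an opaque
non-negative quantity: whether it is raw mapped-read counts or
coverage-normalized does not change anything downstream except the scale of
slopes (all decisions are scale-equivariant, which the test suite checks).

Within each domain × direction stratum the top-N taxa by total abundance
form the response groups (defaults N = 200 bacteria, 50 archaea per group).
Ties in total abundance are broken lexicographically by taxon id so results
are reproducible; strata smaller than the quota are kept whole with a
warning.

## Breakpoint (segmented) fits

Group-summed abundance against EC is fitted with the continuous two-segment
model y = β₀ + β₁x + β₂·max(0, x − ψ). The breakpoint ψ is estimated by
profiling the residual sum of squares over a 201-point uniform grid spanning
the interior of the observed x (between the 2nd smallest and 2nd largest
distinct values, so each segment keeps at least two support points), then
refining the grid minimizer by golden-section search between its neighbours.
This profile search is global and derivative-free, unlike the iterative
linearization used by classic segmented-regression software, and agrees with
an exhaustive 10⁵-point grid to 10⁻³ on random instances (tested).
Continuity at ψ is enforced: the breakpoint is a change in trend, not a
jump.

Model selection against the nested straight line uses
F = ((RSS_lin − RSS_seg)/2)/(RSS_seg/(n − 4)) referred to F(2, n − 4), or
optionally BIC. Because ψ is estimated from the same data, the F test is
**anti-conservative**: at α = 0.05 the measured selection rate on pure-line
data with Gaussian noise is ≈ 9%, and under heteroskedastic
negative-binomial noise it rises to ≈ 17%. A fitted RSS below 10⁻¹⁰ of the
total sum of squares is treated as an exact fit so that noiseless inputs do
not produce 0/0 F statistics.

## Trait normalization (NACG)

Scaffold-based gene abundance is proportional to the abundance of the taxon
carrying the gene, so per-taxon functional content is expressed as the
normalized abundance of category genes: the summed abundance of a
category's member genes within a taxon divided by that taxon's abundance.
Two scopes are provided because the definition is silent about sample
handling: *pooled* (sum numerator and denominator over samples first —
default for group comparisons) and *per-sample* (the ratio within each
sample — used for along-gradient trends). Samples where the taxon is absent
are excluded from pooled sums and yield missing per-sample values; a taxon
with zero total abundance yields a missing value with a warning, never an
error. Genes mapping to several pathways count once in each pathway
(standard KEGG practice), but never twice within one category. The
carbon-acquisition investment fraction — (C-fixation + CAZyme gene
abundance) / all catalogued gene abundance — is a ratio of gene sums and
therefore invariant to the taxon's own abundance.

## Mechanism sets

A mechanism (3 salt-resistance, 7 C-fixation, 6 CAZyme classes) is called
present in a taxon when at least `min_genes` (default 1) of its member genes
have positive pooled abundance; no abundance floor is applied because the
data are already thresholded upstream by the annotation pipeline, and the
strictness knob is exposed. UpSet summaries assign every taxon to exactly
one subset — its exact present set, including the empty set, which is
reported explicitly — so subset counts always sum to the group size.

## Contrasts, biomarkers, clustering

Group contrasts use the unpaired two-sided Mann–Whitney U test: exact by
enumeration of all label assignments when the pooled sample is ≤ 12 without
ties, otherwise a normal approximation with midrank tie correction and
continuity correction. The differential-pathway rule is the conjunction
(MWU p < 0.05) AND (|difference of per-taxon group means| > 0.001), reading
"significant absolute abundance difference of > 0.001" as literally as
possible; both knobs are exposed, and the threshold applies to group means
of per-taxon values (the alternative — group totals — is a config choice
away via the exported matrices). Partial correlation controlling EC uses
the first-order recursion and is verified against the residual-correlation
formulation. Hierarchical clustering of selected pathways is agglomerative
with Euclidean distance and average linkage, with exact ties resolved by
input order so that output is deterministic.

## Random-forest biomarker ranking

Within each response group the sample × level-3-pathway NACG matrix predicts
EC with a regression random forest (default 1000 trees, mtry = p/3, node
size 5), refitted over 100 iterations whose seeds derive from the master
seed by counter; pathways are ranked by mean impurity-decrease importance.
The forest learner is implemented in this package (compiled code): the
environment this package targets has no R random-forest package available,
so delegating to one was not an option. The implementation is a standard
CART regression forest — bootstrap resampling, random feature subsets per
node, variance-reduction splits. Impurity importance is positively biased
for irrelevant features (they are occasionally used deep in trees); this
bias is small relative to genuine signals and does not disturb rankings,
which is what the procedure consumes. The number of biomarker pathways is
chosen by 10-fold cross-validation with the one-standard-error rule on CV
mean squared error (a `rule = "min"` alternative exists). Note that
mutually redundant predictors — e.g. several pathways all linear in EC —
make CV error flatten after the first few, so the 1-SE rule deliberately
selects fewer pathways than were planted.

# The synthetic stated world

`synth_config()` defaults emulate the gradient the analysis is designed
for: 37 samples with EC drawn uniformly on 0.14–13.65 dS m⁻¹ (an explicit
EC vector can be supplied); bacteria responding linearly (60 positive, 60
negative, 60 null) and archaea responding with thresholded responses (50
positive with ψ = 4.2 dS m⁻¹, 50 negative with ψ = 3.4 dS m⁻¹, 10 null).
Observed abundance is negative-binomial around the class mean; the gene
layer multiplies planted per-gene copy numbers by the *observed* taxon
abundance (so noiseless gene data recover copy numbers exactly) with
mean-one lognormal noise (sdlog 0.2). Genome sizes are lognormal by group
with medians mirroring the contrast under study (pos-arch 3.74 Mb vs
neg-arch 1.60 Mb; pos-bac 3.0 Mb vs neg-bac 4.5 Mb; reference distributions
centred at 2.49 Mb for Euryarchaeota and 1.36 Mb for Thaumarchaeota).
Mechanism completeness is planted as deterministic head-counts
(e.g. 76% of pos-arch vs 20% of neg-arch carry all three salt-resistance
mechanisms; 68%/22%/34.5%/81.5% for the seven C-fixation pathways;
70%/12%/43%/69.5% for the six CAZyme classes), so noiseless recovery is
exact rather than merely unbiased. Each taxon's carbon-acquisition copy
fraction is rescaled to its group's planted investment value (13.49%,
12.43%, 24.37%, 12.65%), which makes per-gene copy numbers fractional — a
deliberate choice: copy numbers here are gene dosage per unit taxon
abundance, not integral gene counts.

Two defaults were calibrated, once, against design properties the package
is required to satisfy rather than against data: (i) slope/intercept ranges
keep every class mean non-negative across the whole EC range, because a
negative mean floored at zero creates a second kink that makes the planted
single-breakpoint model misspecified (the floor remains as a guard); and
(ii) the negative-binomial size parameter defaults to 100 (per-sample
residual CV ≈ 10–12% for abundant taxa), because breakpoint localization to
±0.5 dS m⁻¹ at n = 37 is statistically impossible at strong overdispersion
— the variance of a negative-binomial scales with μ², and the 3.4 dS m⁻¹
breakpoint sits where abundance (hence noise) is highest. Real soil
metagenomes are often noisier than this; the generator emulates the tightly
structured trends that make a breakpoint analysis sensible at all, and both
knobs are configurable.

What a green test does **not** establish: the generator plants independent
taxa (no phylogenetic or compositional correlation), a clean piecewise
response family, and noise levels favourable to detection. Passing recovery
tests demonstrates correctness of the estimators on their intended data
model, not power on arbitrary field data.

# Numerical choices

- Degenerate per-taxon regressions (constant response) return slope 0,
  p = 1, rather than NaN, so batch screening never crashes.
- Admissible breakpoints are restricted to the interior of the design; grid
  endpoints are nudged inward by 10⁻⁶ of the range to avoid a collinear
  hinge column.
- Mann–Whitney switches from exact enumeration to the corrected normal
  approximation at pooled size 12 or at the first tie.
- Row z-scores use the n − 1 standard deviation; constant rows map to zeros.
- All randomness flows from explicit seeds; iteration seeds derive from the
  master seed by counter, and pipeline outputs are byte-identical across
  runs at the same seed.
- Ranking ties (total abundance, importance) break lexicographically.

# Known limitations

- The two-segment model fits exactly one breakpoint; responses with
  saturation on both sides (or floor-induced second kinks) are fitted with
  whatever single kink minimizes RSS.
- The post-hoc-breakpoint F test is anti-conservative (measured above);
  treat "segmented" calls near the threshold with caution or use BIC.
- Impurity-based importance is biased toward high-variance features; only
  rankings, not absolute importances, should be interpreted.
- The default catalog ships placeholder KO memberships for mechanisms; real
  analyses should supply a curated catalog (`read_catalog()`).
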