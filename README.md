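# halotrait

Eco-evolutionary trait analysis of soil microbial communities along salinity
gradients.

## The problem

Soil salinization restructures microbial communities, and bacteria and
archaea appear to adapt in opposite directions: salt-tolerant bacteria tend
to *streamline* — shrinking genomes and shedding metabolic genes to save
energy (the Black Queen / streamlining strategy) — while salt-tolerant
archaea tend to *expand* — enlarging genomes and accumulating
carbon-acquisition machinery to broaden resource usage (a Red Queen-style
strategy). Testing this from shotgun-metagenomic annotations requires a
chain of analyses that `halotrait` packages as reusable, tested components:

1. **Response-group construction** — per-taxon OLS of abundance on
   electrical conductivity (EC, dS m⁻¹, the salinity proxy), after removing
   taxa with total abundance < 100 across samples; taxa with slope p < 0.05
   are split by sign and domain, and the top-N by total abundance form the
   four groups *pos-bac*, *neg-bac*, *pos-arch*, *neg-arch*.
2. **Breakpoint detection** — continuous two-segment least squares
   `y = β₀ + β₁x + β₂·max(0, x − ψ)` with a profiled-RSS grid search plus
   golden-section refinement for ψ, and an F-test (or BIC) against the
   nested straight line.
3. **Trait normalization** — scaffold-derived gene abundance scales with the
   abundance of the taxon carrying the genes, so per-taxon functional
   content is normalized as

   `NACG_i = Σⱼ ACG_ij / AT_i`

   (normalized abundance of category genes: summed member-gene abundance of
   a category in taxon *i* divided by the abundance of taxon *i*), applied
   to overall KEGG orthologs (KOs), BRITE level-1/3 pathways, salt-resistance
   KOs, C-fixation KOs, and CAZyme families.
4. **Mechanism completeness** — presence/absence of the 3 salt-resistance
   mechanisms (Na⁺ extrusion, K⁺ uptake, osmotic-solute accumulation), the 7
   inorganic C-fixation pathways, and the 6 CAZyme classes, summarized as
   exact-subset (UpSet) counts and completeness distributions.
5. **Contrasts and biomarkers** — Mann–Whitney U group contrasts (exact by
   enumeration for small untied samples), genome-size comparisons between
   groups / within a shared phylum / against reference phylum distributions,
   partial correlation controlling EC, the "p < 0.05 AND |Δmean| > 0.001"
   differential-pathway rule with average-linkage clustering, and
   random-forest ranking of level-3 pathways against salinity (1000 trees,
   importance averaged over 100 iterations, 10-fold CV biomarker-count
   selection).

A synthetic-data module generates gradient datasets with planted ground
truth (response classes, breakpoints at 3.4/4.2 dS m⁻¹, gene copy numbers,
mechanism sets, genome-size groups), so every stage is testable without any
sequencing data.

## Worked example

```r
library(halotrait)

gen <- generate_dataset(synth_config(seed = 1))
ds  <- gen$dataset
ds
#> ht_dataset: 290 taxa x 37 samples; 768934 gene-abundance records; EC range 0.3209-13.54 dS/m

assignments <- classify_taxa(ds, min_total = 100, alpha = 0.05)
groups <- select_response_groups(assignments, n_bac = 50, n_arch = 50)
table(groups$group)
#> neg-arch  neg-bac     none pos-arch  pos-bac
#>       50       50       90       50       50

# breakpoint in the summed abundance of salt-tolerant archaea
ids <- groups$taxon_id[groups$group == "pos-arch"]
fit <- fit_segmented(ds$samples$ec, colSums(ds$abundance[ids, ]))
fit
#> segmented fit: psi = 4.24, left slope = 17.32, slope change = 589.8, RSS 6.22e+04 (linear 5.869e+06), n = 37
select_model(fit)$chosen_model
#> [1] "segmented"
```

The planted breakpoint for positive-responding archaea is 4.2 dS m⁻¹; the
fitted ψ = 4.24 recovers it, and the F-test prefers the segmented model.

```r
genome_size_contrasts(groups, ds$taxa, ds$refs)[, c("label", "median_a", "median_b", "p_value")]
#>                                      label median_a median_b      p_value
#> 1                       pos-bac vs neg-bac 3.183086 4.313525 1.345799e-08
#> 2                     pos-arch vs neg-arch 3.951290 1.678475 4.418612e-16
#> 3 pos-bac vs neg-bac within Proteobacteria 3.208520 4.228492 3.313062e-05
#> 4            pos-arch vs all Euryarchaeota 3.951290 2.420823 4.889555e-13
#> 5           neg-arch vs all Thaumarchaeota 1.678475 1.337241 1.076958e-07
```

Salt-tolerant bacteria have *smaller* genomes than salt-sensitive ones
(3.18 vs 4.31 Mb; the same inside the shared phylum), while salt-tolerant
archaea have *larger* genomes (3.95 vs 1.68 Mb) — the planted
streamlining-vs-expansion contrast.

```r
# per-taxon trait normalization and C-acquisition investment
nacg(ds, ids[1], "salt_resistance")$nacg
#> [1] 28.25867
c_acquisition_fraction(ds, ids[1])$fraction
#> [1] 0.2457043

# completeness of the three salt-resistance mechanisms among tolerant archaea
profs <- mechanism_profiles(ds, ids, "salt_resistance")
completeness_distribution(profs)$complete_fraction
#> [1] 0.74
```

The generator plants all three salt-resistance mechanisms in 76% of
positive-responding archaea; the assembled group recovers 0.74 because group
membership is re-derived from the noisy abundances rather than read off the
ground truth.

## Command line

```sh
Rscript inst/cli/halotrait.R simulate --config inst/extdata/config.yaml --out outdir/dataset
Rscript inst/cli/halotrait.R run      --config inst/extdata/config.yaml --out outdir
```

`run` executes every stage and writes all output tables (TSV/JSON) to the
output directory; `simulate`, `classify`, `segfit`, `traits`, `mechanisms`,
`contrasts` and `rf-select` run stages individually. `--seed` overrides the
config seed; outputs are byte-identical across runs at the same seed.

## Documentation

Function-level documentation lives in the roxygen comments in `R/`; the
methods vignette (`vignettes/halotrait-methods.Rmd`) describes the model
assumptions, the synthetic stated world, numerical choices, and known
limitations.
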