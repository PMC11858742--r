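# palaeodark

Museum collections hold large numbers of fossil occurrences that never
reach the published literature or community databases — so-called *dark
data*. Whether those unpublished records change our picture of a clade's
diversity, geographic spread and temporal history is an empirical question,
and answering it requires running the same battery of macroevolutionary
analyses on several versions of one occurrence compilation and comparing
the results.

`palaeodark` is an R package for exactly that workflow. It is organised
around a four-way partition of an occurrence table:

| dataset | contents |
|---------|----------|
| **A** | museum-only ("dark") occurrences |
| **B** | occurrences in the published record |
| **C** | the database-entered subset of B |
| **D** | the combined dataset, `D = A ∪ B`, `A ∩ B = ∅`, `C ⊆ B` |

and provides, per dataset and per geological time bin:

* ingestion, validation, per-collection deduplication and majority-rule
  time binning of occurrence CSVs (including a reader for Paleobiology
  Database exports);
* metadata composition (lithology, grain size, taxonomic rank,
  specimen-level taphonomic grade) with chi-squared, Kruskal–Wallis
  (ε² = H/(n−1) effect size) and Wilcoxon tests, and the
  domestic-vs-foreign repository breakdown by country;
* grid-cell occupancy; spherical convex-hull geographic range size with
  per-taxon `overlap% = 100·Area(S)/Area(D)` and
  `added% = 100·(Area(D) − Area(D∖S))/Area(D)`; latitudinal range widths,
  overlaps and midpoint shifts;
* bin-bound temporal ranges (FAD/LAD), range overlap and time added, and
  the distribution of occurrences within their taxon's range;
* raw richness and coverage-based rarefaction of incidence data
  (interpolation by exact hypergeometric expectation, Chao2
  extrapolation, quorum standardisation by inverting the coverage curve),
  Good's *u*, and Spearman/Benjamini–Hochberg series comparisons;
* the standardized relative affinity (SRA) of families for carbonate vs
  siliciclastic substrates — a seeded Monte-Carlo z-score of
  `RA = k/n − π` against a `Binomial(n, π)` null;
* GLS regression of diversity on covariate series with AR(1) errors
  (exact ML, `df = coefficients + 2`, AICc) and exhaustive
  subset selection (`dredge_gls()`), with broom-style `tidy()`/`glance()`
  methods;
* a seeded synthetic occurrence generator whose taxa have closed-form true
  range areas (spherical caps), true durations and true substrate
  affinities, so every estimator above can be validated against known
  truth.

All user-facing functions take and return tibbles and compose with the
pipe; `run_pipeline()` / `simulate_and_run()` execute the full stage
sequence and write one tidy CSV per stage plus a JSON manifest.

## Worked example

Simulate a compilation under the default study conditions (976 dark / 1247
published occurrences with channel-specific lithology, taphonomy, spatial
and temporal biases), then measure what the dark channel contributes:

```r
library(palaeodark)
library(dplyr)

taxa <- generate_taxa(n_taxa = 60, seed = 42)
sim <- sample_occurrences(taxa, default_channels(), seed = 43)

occ <- sim$occurrences |>
  deduplicate_occurrences() |>
  assign_bins(palaeozoic_bins("stage"))
part <- partition_datasets(occ)
part
#> <dataset_partition>
#>   A (dark):      829 occurrences
#>   B (published): 1062 occurrences
#>   C (pbdb):      558 occurrences
#>   D (combined):  1891 occurrences
```

Deduplication merged same-taxon same-collection rows (2223 raw draws →
1891 occurrences) while conserving specimen counts; the partition algebra
`|D| = |A| + |B|`, `C ⊆ B` holds exactly.

```r
range_overlap_added(part, rank = "genus") |>
  summarise_ranges("added_pct")
#> # A tibble: 3 × 4
#>   subset        n  mean median
#> 1 dark        136  65.6   73.6
#> 2 pbdb        136  41.5   22.9
#> 3 published   136  68.9   99.8
```

Across 136 genus-by-stage ranges, removing the dark data would lose 65.6%
of hull area on average at this (sparse) sampling density — museum-only
records dominate the spatial signal of many taxon-bins, because the
published channel is configured to reach only 65% of each true range.

```r
occurrence_positions(part, "genus") |>
  group_by(subset) |>
  summarise(mean_position = mean(position))
#> # A tibble: 3 × 2
#>   subset    mean_position
#> 1 dark              0.373
#> 2 pbdb              0.521
#> 3 published         0.528
```

Dark occurrences sit "bottom-weighted" toward the old end of their taxon's
range (mean relative position 0.37 vs 0.53 for published data), exactly as
configured in the generator.

```r
glance(gls_ar1(filter(raw_diversity(part), dataset == "total")$richness))
#> # A tibble: 1 × 6
#>      df logLik  AICc     rho sigma  nobs
#> 1     3  -113.  233. -0.0920  3.17    44
```

An intercept-only GLS-AR(1) fit of the total diversity series carries
df = 3 (intercept, autocorrelation, residual scale) — the baseline against
which `dredge_gls()` ranks every covariate subset by AICc.

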