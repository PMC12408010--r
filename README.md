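# spatialmx

Spatial single-cell statistics for multiplexed tissue imaging, built for
the kind of question an obesity study of the human pancreas asks: how do
pro-inflammatory macrophages, resident T cells, and inflamed epithelium
arrange themselves around each other, and how does that arrangement track
donor BMI?

The package takes segmented single-cell tables (one row per cell: donor,
x/y centroid in µm, tissue compartment, cell type, marker intensities) plus
a donor covariate table, and provides:

* **Marker classification against a negative control** — Box-Cox
  normalization of a marker (e.g. CD11c on macrophages) pooled with a
  biological negative control (neuroendocrine cells); cells above the zero
  threshold on the normalized scale are called `high`, below `low`.
* **Proximity graphs** — exact radius-based neighbour graphs per donor
  (default 20 µm), per-donor proximity fractions, and compartmental
  densities.
* **Interaction scores** — for each cell-type pair, the standardized
  residual `(O − E)/√E` of the observed neighbour-pair count against its
  closed-form expectation under label permutation
  (`E = 2 M n_a n_b / (n(n−1))` for distinct types), with permutation
  p-values (1000 iterations, labels reshuffled on the fixed graph),
  Benjamini–Hochberg FDR within donor, and cohort aggregation.
* **Cellular neighbourhoods** — composition windows over each cell's 10
  nearest cells, mini-batch k-means clustering, log2 enrichment, and
  per-donor neighbourhood frequencies.
* **LISA-style regions** — multi-radius (10/20/50 µm) centred local
  composition features, PCA, k-means region assignment (k = 7), region
  enrichment and frequencies.
* **Cohort statistics** — simple and covariate-screened multivariable
  regression of donor metrics on BMI (covariates retained at full-model
  p < 0.3; TMA batch correction via the retained batch term), Pearson
  correlation, and the Chao1 diversity estimator.
* **A synthetic tissue generator** — compartmentalized pancreas-like
  fields with planted ground truth (bimodal markers, BMI-dependent subset
  fractions, cross-type spatial attraction, batch artefacts), so every
  stage is testable without protected human data.

Everything is tidyverse-native: functions take data frames first, return
tibbles, chain with the pipe, and fitted objects support `tidy()`,
`glance()`, `augment()`, and `autoplot()`.

## Worked example

```r
library(spatialmx)
library(dplyr)

co <- generate_cohort(tissue_config(n_donors = 6), seed = 1)
cells <- classify_marker(co$cells, "CD11c", "macrophage", "neuroendocrine")
attr(cells, "classification_models") |>
  select(donor_id, lambda, control_positive_fraction) |> head(3)
#> # A tibble: 3 × 3
#>   donor_id  lambda control_positive_fraction
#>   <chr>      <dbl>                     <dbl>
#> 1 D001     -0.115                          0
#> 2 D002      0.0372                         0
#> 3 D003      0.351                          0
```

Every donor's neuroendocrine control sits entirely below the zero
threshold (`control_positive_fraction` 0), so the CD11c-high/low macrophage
call is anchored by a clean negative.

```r
res <- interaction_analysis(cells, radius = 20, n_perm = 1000, seed = 2,
                            class_column = "CD11c_class")
aggregate_interactions(res) |> arrange(desc(n_significant)) |> head(5)
#> # A tibble: 5 × 5
#>   type_a         type_b         mean_score n_donors n_significant
#>   <chr>          <chr>               <dbl>    <int>         <int>
#> 1 acinar_cell    ductal_cell         -8.86        6             6
#> 2 acinar_cell    neuroendocrine      -4.09        6             6
#> 3 ductal_cell    ductal_cell         18.8         6             6
#> 4 neuroendocrine neuroendocrine      17.5         6             6
#> 5 acinar_cell    acinar_cell          2.61        6             4
```

The scores read as spatial biology: ductal and neuroendocrine cells
self-attract strongly (they are confined to ducts and islets), and both
avoid acinar tissue — each significant at FDR < 0.05 in all six donors.

```r
metric <- cells |>
  filter(!is.na(CD11c_class)) |>
  group_by(donor_id) |>
  summarise(value = mean(CD11c_class == "high")) |>
  left_join(co$donors, by = "donor_id")
tidy(simple_linreg(metric, "value"))
#> # A tibble: 2 × 5
#>   term        estimate std.error statistic p.value
#>   <chr>          <dbl>     <dbl>     <dbl>   <dbl>
#> 1 (Intercept)   0.213    0.0856       2.49 0.0675
#> 2 bmi           0.0137   0.00257      5.33 0.00595
```

The generator plants a CD11c-high fraction rising 0.01 per BMI unit; the
recovered slope here is 0.0137 with 95% CI [0.0066, 0.0208] — covering the
planted truth on this 6-donor cohort.

The full chain (classify → graph → proximity → neighbourhoods →
interactions → LISA → regression, with CSV outputs and a reproducibility
manifest) runs via `run_pipeline(pipeline_config(...))`.

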