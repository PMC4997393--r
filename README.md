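# bopmap

Tools for building and auditing a branded food composition database (FCDB)
from "Back of Pack" (BOP) nutrition labels.

## The problem

National food composition tables carry full nutrient panels — macronutrients
plus a micronutrient panel of ~120 fields — but only for a few thousand
mostly generic foods. Branded products, by contrast, exist by the tens of
thousands but their labels declare only eight nutrients per 100 g: energy
(kcal), protein, fat, saturated fat, carbohydrate, total sugars, AOAC fibre
(all g) and sodium (mg). Dietary assessment at the brand level therefore
needs a *mapping exercise*: each branded item keeps its own label
macronutrients and borrows micronutrients from one or more nutritionally
similar generic reference foods. `bopmap` implements that pipeline —
cleaning the raw label extract, ranking mapping candidates, blending
reference panels, auditing the result — together with a synthetic catalog
generator so every stage is testable without proprietary data.

## The core statistic

A branded item *b* is compared with a generic candidate *g* by a summed
percentage difference over the four ranking macronutrients
K = {energy, fat, protein, carbohydrate}:

    d(b, g) = (4 / |C|) * Σ_{k ∈ C} | 100 · (g_k − b_k) / max(b_k, ε) |

where C ⊆ K are the nutrients present in both panels, ε = 0.1 floors the
denominator (diet drinks declare 0–1 kcal), and each term is capped at 500
percentage points. With a full panel this is exactly the plain sum of four
percentage differences; the (4/|C|) rescaling keeps partially labelled items
on the same scale. Candidates are ranked ascending in d, ties broken by
code. For composite foods (e.g. breaded fish) the engine enumerates every
pairing from two food-group-limited candidate lists across splits
0%, 10%, …, 100%, de-duplicating the degenerate endpoints into
single-generic candidates.

The chosen mapping's micronutrients are the allocation-weighted blend
Σᵢ (pᵢ/100) · panelᵢ; the eight label macronutrients are never overwritten
(items mapped on description alone, which had no label panel, get both).

Around the mapping engine sit:

* **cleaning** — non-food/seasonal screens, multi-pack collapsing, global
  plausibility cut-offs (energy ≤ 900 kcal/100 g, fibre ≤ 54 g/100 g,
  salt ≤ 39 g/100 g, …), decimal-shift and salt/sodium-swap suggestion;
* **tolerance** — EU food-labelling tolerance bands (e.g. fat declared
  < 10 g/100 g: ±1.5 g; 10–40 g: ±20%; > 40 g: ±8 g) and negligible-amount
  declarations ("<0.5 g", "0 g");
* **QC audit** — energy-agreement screening of mapped items, per-food-group
  min–max range checks built from the reference catalog, and a
  keep / update / remove resolution workflow with conservation accounting;
* **portions** — portion-size merging by source priority and portion-image
  key assignment;
* **simulation** — seeded generation of generic and branded catalogs with
  injected decimal shifts, salt/sodium swaps, missing panels, multi-packs
  and diet variants, each recorded in a truth table.

## Worked example

```r
library(bopmap)
library(dplyr)

cfg <- sim_config(seed = 42, n_branded = 200, noise_sd_pct = 5,
                  error_rates = list(decimal_shift = 0.05, diet_variant = 0.05))
generics <- generate_generics(cfg)
branded  <- generate_branded(cfg, generics)

cleaned  <- clean_catalog(branded)
maps     <- rank_catalog(cleaned$kept, generics, top_k = 5)
enriched <- apply_mappings(cleaned$kept, filter(maps, rank == 1), generics)
rep      <- agreement_report(enriched$catalog, filter(maps, rank == 1), generics)
rep$groups
#> # A tibble: 5 × 4
#>   food_group  count pct_of_total mean_pct_diff_energy
#>   <chr>       <int>        <dbl>                <dbl>
#> 1 soft drinks    48           24                22.1
#> 2 bakery         42           21                44.9
#> 3 vegetables     42           21                -3.25
#> 4 dairy          40           20                11.1
#> 5 meat           28           14                36.1
rep$pct_within_10
#> [1] 90.5
```

Each group row gives the number of mapped items, their share of the
catalog, and the mean signed percentage difference between the blended
generic energy and the label energy. The large positive group means are
driven by the injected diet variants — items whose label energy is a few
percent of their non-diet parent's — exactly the pattern an
energy-agreement audit is meant to surface:

```r
ranges <- build_group_ranges(generics)
flags  <- range_outlier_check(enriched$catalog, ranges)$flags
nrow(flags)
#> [1] 72          # range flags, mostly the injected decimal shifts

tolerance_bounds("fat_g", 5)
#>  low high
#>  3.5  6.5
within_tolerance("protein_g", 60, 67)
#> # A tibble: 1 × 4
#>   ok    margin   low  high
#>   <lgl>  <dbl> <dbl> <dbl>
#> 1 TRUE       0    52    68
```

A thin command-line front end over these functions ships in
`inst/cli/bopmap.R` (`Rscript bopmap.R simulate|clean|map|tolerance|qc …`).

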