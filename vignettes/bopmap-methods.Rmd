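---
title: "Mapping branded label data to reference foods: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping branded label data to reference foods: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bopmap)
library(dplyr)
```

# The pipeline

A branded food composition database starts from a commercial extract of
"Back of Pack" (BOP) label data: one record per product carrying only the
eight legally framed nutrients per 100 g. `bopmap` turns such an extract
into an analysable database in five stages, each a module of this package:

1. **clean** the extract — remove non-food and seasonal items, collapse
   multi-packs, flag values beyond global plausibility cut-offs, and
   suggest (never apply) corrections for the two dominant data-entry
   errors, decimal shifts and salt/sodium swaps;
2. **map** each branded item to one or more generic reference foods by
   nutrient similarity, so its missing micronutrients can be populated;
3. **audit tolerances** — check declared values against the EU labelling
   tolerance bands;
4. **QC** the mapped database — energy-agreement screening, per-group
   range checks, and a resolution workflow;
5. **derive portions** — merge serving-weight sources and assign
   portion-image keys.

A sixth module generates synthetic generic and branded catalogs with known
ground truth, because the commercial extracts this pipeline is designed for
are proprietary.

Throughout, a catalog is a tibble with one row per item and one column per
nutrient key, and a missing value is `NA` — never 0. A blank label cell
means "not declared"; conflating it with zero would corrupt both the
ranking distance (a zero energy denominator) and the negligible-amount
logic (an explicit 0 g is a legitimate declaration).

# The ranking distance

The mapping engine scores a generic candidate $g$ against a branded item
$b$ over the four ranking macronutrients
$K = \{\text{energy}, \text{fat}, \text{protein}, \text{carbohydrate}\}$:

$$
d(b, g) \;=\; \frac{|K|}{|C|}\sum_{k \in C}
\left|\,100 \cdot \frac{g_k - b_k}{\max(b_k, \varepsilon)}\right|_{\wedge c},
\qquad C = \{k \in K : b_k, g_k \text{ present}\},
$$

with $\varepsilon = 0.1$ (denominator floor, in each nutrient's unit) and a
per-nutrient cap $c = 500$ percentage points. Three conventions here were
genuinely open and are fixed as follows:

* **Denominator = the branded (label) value.** The question the ranking
  answers is "how far is this reference food from the label?", so the label
  is the base. The sign convention $(g-b)/b$ makes a diet drink mapped to a
  sugary generic come out *positive* — matching the direction in which such
  disagreements are conventionally reported.
* **Floor and cap.** Diet products declare 0–1 kcal; without
  $\varepsilon$ the distance is infinite, and without the cap one
  pathological nutrient swamps the other three. The uncapped magnitude is
  still recorded where it matters (the energy-agreement audit reports
  differences above 1000% distinguishably).
* **Partial panels.** The mean over comparable nutrients multiplied by
  $|K| = 4$ equals the plain four-term sum for fully labelled items, while
  keeping items with a partial label on a comparable scale rather than
  silently favouring them.

Ties in $d$ are broken by generic code, lexicographically — in production
use a nutritionist breaks ties by judgement; a batch pipeline needs a
deterministic rule, and the code is the only stable attribute.

## Blend enumeration

For composite foods the engine takes two candidate lists limited by food
group and sweeps every pair across splits $p \in \{0, 10, \dots, 100\}$
percent (the 10-point step is configurable; it divides 100 by
construction). The endpoint splits $p = 0$ and $p = 100$ degenerate to
single-generic candidates; they are reduced to a canonical single-item key
and de-duplicated *before* ranking, so a generic appearing in both lists is
scored once. For lists of sizes $n_A$ and $n_B$ this costs
$n_A \, n_B \, (100/s + 1)$ evaluations pre-deduplication — 11 for a 1×1
pairing, 66 for 2×3 at $s = 10$ — counts the test suite checks against an
independent brute-force enumeration.

## What mapping changes, and what it never changes

Applying a mapping fills the branded item's micronutrients with the
allocation-weighted blend $\sum_i (p_i/100)\,\text{panel}_i$, where a
nutrient missing in *any* constituent is missing in the blend (a partial
weighted sum would systematically understate it). The eight label
macronutrients are authoritative and are never overwritten. The one
exception is items mapped on description alone (`description_only`): these
had no usable label panel, so both macros and micros come from the generic.
Description matching uses a token-set similarity — the maximum normalised
indel similarity between the shared-token string and each full sorted token
string — with a proposal threshold of 0.6; the measure is order-insensitive
and rewards a shared distinctive token ("lager") even when one description
carries extra qualifiers ("4% abv").

Hand-coded recipes (ready meals decomposed from their ingredient list)
accept allocations summing to $100 \pm 0.5$ and renormalise to exactly 100;
the distance against the implied blend is recorded for audit.

# Cleaning conventions

* **Global cut-offs** (per 100 g): energy 900 kcal, carbohydrate 99.9 g,
  protein 89 g, sugars 100 g, fat 99.9 g, saturated fat 86 g, fibre 54 g,
  salt 39 g. These are *maximum plausible* values — pure oils, table sugar,
  protein powders, dried herbs and seasoning mixes sit at them — so the
  comparison is strict: a value exactly at the cut-off is acceptable, one
  above it is flagged. Salt is screened from the salt column when present,
  otherwise derived from sodium.
* **Salt–sodium conversion**: salt (g) = sodium (g) × 2.5, the EU labelling
  convention. A swap is suggested when the declared salt equals sodium/1000
  within 0.001 g while differing from the expected 2.5× value by more than
  20%.
* **Suggestions are never auto-applied.** Decimal-shift and swap detectors
  emit suggestions; only the QC resolution step mutates values, because in
  this workflow every correction is a human decision. This also gives the
  cleaning pass its idempotence property: it partitions and annotates, so
  running it twice equals running it once.
* **Multi-pack twins** are matched on brand plus a normalised description
  (lower-cased, punctuation stripped, pack-size tokens
  `\d+\s*(pack|x|multipack)` removed). A multi-pack without a single-item
  twin is kept and gains a "per item" portion of pack weight divided by
  count.

# Labelling tolerance bands

The tolerance module encodes the EU FIC bands per nutrient, with boundary
membership fixed as: "<10 g" means $[0, 10)$, "10–40 g" means $[10, 40]$,
">40 g" means $(40, \infty)$; the "at least" thresholds (4 g saturates,
0.5 g sodium, 1.25 g salt) are inclusive on the percentage rule. Sodium is
handled on a gram basis. Two properties worth stating:

* the declared value always lies inside its own interval;
* the bounds are **not** monotone in the declared value everywhere — the
  printed bands make the fat lower bound step down at 10 g (9.99 − 1.5 >
  10 − 2) and the sodium and salt upper bounds step down at their
  thresholds (20% of 0.5 g is narrower than ±0.15 g). The package preserves
  these discontinuities rather than smoothing them; the tests assert them
  explicitly.

Negligible amounts: sugars, fat, carbohydrate and protein at or below
0.5 g/100 g declare "<0.5 g"; saturates at or below 0.1 g "<0.1 g"; salt at
or below 0.0125 g "<0.01 g" (the regulation prints the threshold and the
label at different precision; both are kept as printed); an exact zero
declares "0 g". The vitamin-C-in-liquids allowance is exposed as an
optional upper-tolerance multiplier, off by default.

# Quality control

The post-mapping audit runs three independently callable rounds:

1. **Energy agreement**: flag mapped items whose blended generic energy
   differs from the label energy by more than 100% (of the label value).
   The 100% threshold is a pragmatic triage level; most hits are legitimate
   diet products mapped to non-diet generics, which is why flags carry the
   signed magnitude rather than a binary verdict.
2. **Group ranges**: for each food group, the min–max of every nutrient
   over the resolved reference foods becomes a cut-off pair; branded values
   strictly outside flag, values exactly on a bound do not. Group
   resolution accepts an explicit reference-group list and/or a keyword on
   reference descriptions (a "frozen foods" group with no reference
   equivalent resolves via the keyword "frozen"). Items whose group cannot
   be resolved are reported as unchecked, never silently passed. By
   construction the reference catalog is self-consistent: checking it
   against its own ranges yields zero flags — a property the tests pin.
3. **Resolution**: each flag resolves as *keep* (corroborated), *update*
   (reformulated; the value is corrected) or *remove* (no data; the item is
   hidden, closing all of its open flags). The audit log conserves items —
   active + hidden = input — and updates touch exactly the flagged
   (item, nutrient) pairs.

For blended mappings the agreement statistics use the allocation-weighted
generic energy (not the first allocation), the only choice consistent with
how the blend populates nutrients.

# The synthetic generator

`generate_generics()` draws, per food group, an archetype: total macro mass
per 100 g, a protein/fat/carbohydrate composition, saturate and sugar
fractions, and a sodium scale. Individual foods jitter the archetype, and
energy follows from the Atwater factors (4/9/4 kcal per g), so every
profile respects the global cut-offs by construction (100 g of pure fat is
the 900 kcal extreme). Ten micronutrients are drawn per group on a log
scale. `generate_branded()` derives each branded item from one parent (or a
two-generic blend with a split on the 10% grid) with **log-normal
multiplicative noise** on the four ranking macros — label values are
positive and their errors scale with magnitude. Injected pathologies
(decimal shifts, salt/sodium swaps, missing panels, multi-packs, diet
variants with sugars zeroed and energy cut to a few percent) are recorded
in a truth table.

Determinism: all draws flow from the config seed, with generics generated
at `seed` and branded items at `seed + 1` so the two catalogs are
independently reproducible; the ambient RNG state is restored afterwards.

What the generator does *not* emulate: real British product vocabulary and
brand market structure, correlated multi-nutrient label errors, nutrient
panels that disagree with their own energy declaration, and reference
catalogs with internal inconsistencies. Passing recovery tests on these
catalogs therefore demonstrates the algorithmic machinery — not that a
particular recovery rate would be achieved on a commercial extract, whose
error structure is messier.

# Study sizes and numerical choices

The package's own evaluation uses 5 food groups × 30 generics and 500
branded items at 5% label noise — large enough for stable rates, small
enough that the full suite runs in about a minute. Under those conditions
the true parent ranks first for ≥ 90% of items and within the top five for
≥ 99%; with the noise at zero, recovery is exact and every group's mean
energy difference is 0, a closure property that would expose any asymmetry
or rescaling bug in the distance.

Other numerical conventions: reports serialize numbers at four decimal
places and round-trip comparisons use an absolute tolerance of 1e-6; blend
linearity holds to 1e-9; equality comparisons against group-range bounds
and cut-offs are exact (values are flagged only strictly beyond them).

# Known limitations

* Description matching is token-based; it has no notion of synonyms
  ("coke" vs "coca-cola") or misspellings — synonym curation is a data
  task, out of scope here.
* Group-range QC inherits the reference catalog's coverage: a branded
  group with no resolvable reference foods is an error at range-building
  time by design, forcing an explicit mapping decision.
* The tolerance module covers the eight label nutrients plus
  vitamin/mineral classes; it is not a full labelling-regulation
  implementation (no trans fats, polyols, or kJ declarations).
* Recipe decomposition is validated, not inferred: parsing ingredient
  lists into allocations is a human (or NLP) task upstream of this
  package.
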