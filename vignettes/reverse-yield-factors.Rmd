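---
title: "Reverse-yield factors: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-yield factors: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryf)
```

## The problem

Residue exposure is regulated at the raw-primary-commodity (RPC) level —
maximum residue limits attach to wheat, not to udon noodles — while food
consumption is recorded for processed and composite foods. The
reverse-yield factor (RF) of an ingredient in a food is the grams of the
ingredient needed to produce one gram of the food. Chaining RFs through
every processing tier converts composite-food consumption into RPC
amounts. `ryf` derives RFs from nothing more than a per-100 g
food-composition table plus a recipe configuration that says, for each
composite food, which category of processing produced it and from which
candidate ingredients. That categorization is expert input, not
inference: deciding that an item is a rice-bran pickle of cucumber is a
dietitian's judgement, and the package treats it as authoritative
configuration.

## Closed-form models and their assumptions

**Dried and salted foods.** Let `a` be the source's water content (%),
`b` the product's, and `s` the added salt (g per 100 g of product, NaCl
equivalent, taken directly from the salt-equivalent column rather than
derived from sodium). Conservation of non-water, non-salt solids gives

    RF = (100 − s − b) / (100 − a),

with `s = 0` for plain drying. The assumptions are that drying and
salting move only water and salt, and that the water content of the salt
itself is negligible. `RF < 1` simply records net water uptake (brining);
it is a valid result, not an error. Infeasible inputs — `a ≥ 100`, or
`s + b > 100` — are hard errors because they indicate a data problem,
not a boundary case.

**Pickles.** The vegetable's RF uses the salted-food balance. The medium
is quantified through a marker nutrient assumed to originate entirely
from the medium: thiamine for rice-bran paste (3.12 mg/100 g in the
paste), acetic acid for vinegar (4.2 g/100 g), protein for soy sauce
(7.7 g/100 g) and miso (12.5 g/100 g). Added sugar comes from a sucrose
mass balance: product sucrose minus what the vegetable (and, for soy
sauce, the medium's own 0.1 g/100 g) contributed, divided by sugar's
99.3 g/100 g sucrose content. The sugar equations admit two typeset
readings; the one implemented — subtract the other ingredients' sucrose
contributions, then divide by sugar's sucrose content — is the only one
dimensionally consistent with the thiamine, acetate and protein
equations, and is the package's documented interpretation. A negative
implied sugar amount within `1e-9` is clamped to zero with a message
(floating-point noise); anything larger is an error, because silently
clipping it would mask a misconfigured recipe.

**Fermented foods.** Alcoholic fermentation theoretically converts one
glucose into two ethanol plus two CO2, but roughly a fifth of the glucose
feeds yeast growth, leaving a practical yield of 0.42 kg ethanol per kg
glucose — hence 1/0.42 = 2.38 g glucose per gram of ethanol, and the
integer coefficient 238 = round(100 × 2.38) in

    RF = (238·ethanol/c + 100·residual_carb/c) / 100,

where `c` is the raw material's available carbohydrate (g/100 g). The
first term is the raw material that became ethanol, the second the raw
material whose carbohydrate survived. Acetic-acid fermentation oxidizes
ethanol to acetic acid; the theoretical yield is 60/46 = 1.304 kg acid
per kg ethanol, but because *Acetobacter* consumes part of the ethanol
the working assumption is 1 kg acid per 1 kg ethanol, making the acetic
equation formally identical with acetic acid in ethanol's place. The
theoretical factor is available through the `acetic_per_ethanol`
argument for sensitivity analysis. The purely stoichiometric helpers
`glucose_equiv_ethanol()` ((45/23)·a) and `glucose_equiv_acetate()`
(1.5·b) expose the molar arithmetic separately from the yield-adjusted
engine.

One documented discrepancy: the standard worked example for sake quotes
an ethanol content of 12.3 g/100 g in its text but computes with 12.8,
obtaining 39.67 g of polished rice per 100 g. The package reproduces the
printed calculation (12.8 → 39.67) and leaves the inconsistency to the
source rather than resolving it.

Lactic-acid-fermented items have no single marker equation; they are
routed by recipe structure. A one-ingredient lactic item (a soured
pickle) goes through the salted-food balance; a two-ingredient item (a
fermented milk beverage) is solved as a 2×2 mixed system with available
carbohydrate and calcium as the conserved markers. Items lacking those
values classify as `INGREDIENTS_UNKNOWN`.

**Mixed foods.** With `k` ingredients and `k` marker nutrients assumed
conserved through processing, the balance `Σ_i (R_ji/100)·W_i = P_j`
determines the ingredient weights `W` (grams per 100 g of composite);
`RF_i = W_i/100`. The matrix display convention is rows = markers,
columns = ingredients, and the `/100` scaling is fixed by requiring
consistency with `RF = W/100` and with the flour/salt noodle example,
whose closed-form solution (`W_flour = 100·56.8/75.1`,
`W_salt = 100·2.5/99.5`) the solver reproduces to 1e-12. When the
configuration lists known content ratios, they are used directly and no
system is solved.

## Numerical choices

- **Gauss–Jordan elimination is implemented in the package** (it is the
  point of the mixed-food engine, not plumbing), as reduced row-echelon
  reduction over the augmented matrix with **partial pivoting** added for
  stability on near-collinear nutrient profiles. Rows are scaled to unit
  maximum before pivot comparison so `pivot_tol` (default `1e-10`) is
  meaningful across nutrient magnitudes (mg vs g columns).
- A pivot below tolerance yields a **structured singularity report**
  naming the columns (ingredients) that could not be separated; the
  dispatcher converts this into a `TOO_MANY_INGREDIENTS` failure, since
  dependent markers cannot distinguish the ingredients.
- Every returned solution carries its max-norm residual; solutions are
  accepted only with residual ≤ 1e-8.
- **Negative solution components** beyond −1e-9 mark the entry set
  `infeasible` (the recipe's ingredient set cannot reproduce the
  composite's nutrients); components within [−1e-9, 0) clamp to zero.
- **Surplus candidate markers** are pruned to the square subset
  minimizing the exact condition number of the marker matrix, by
  exhaustive search over subsets (recipes here have k ≤ 6, so the search
  is trivial); overdetermined systems are never least-squares-fitted,
  because the model class is exact square balances.
- Markers with missing values are dropped before selection. On an
  exactly-square configuration a missing value means missing
  information (`INGREDIENTS_UNKNOWN`); on a surplus configuration whose
  usable markers still fall short of the ingredient count the food is
  unseparable (`TOO_MANY_INGREDIENTS`). When several reasons apply the
  precedence is `INGREDIENTS_UNKNOWN` > `TOO_MANY_INGREDIENTS` >
  `COMPLICATED_PROCESSING`, matching the dominant class among real
  non-computable items.
- Composition tables keep missing values explicit (`NA`, never zero);
  "Tr" (trace) cells read as zero by default (`trace_as_zero`), the
  conventional reading of trace amounts, with the switch documented for
  users who prefer strict missingness.
- Mass closure is validated per row: water + protein + available
  carbohydrate + ethanol ≤ 100 g + 0.5 g slack per 100 g of food.

## Tier chaining

Tier 1 is the first disaggregation step of a composite; depth counts
edges. An edge's tier is its composite's full disaggregation depth in
the recipe graph. Cumulative RFs multiply along root-to-leaf paths
(`disaggregate()`), the default `max_depth` of 6 reflecting the deepest
chains observed in practice (configurable). When one RPC is reached
along several paths its contributions are summed in the flat
`rpc_summary()` view, because exposure assessment needs total RPC mass.
A failed sub-recipe truncates only its own branch; the summary then
reports `complete = "no"` and counts incomplete branches. The ingredient
graph must be acyclic; a cycle is reported with the full path.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` forward-simulates processing from pseudo-random RPC
profiles by exact mass balance: water removal, salt addition (dry NaCl,
then water adjustment), glucose-to-ethanol fermentation with explicit
CO2/biomass mass loss, ethanol-to-acetic-acid oxidation at 1:1 mass, and
linear blending with optional added water. Two choices make parameter
recovery exact rather than approximate:

- the simulator produces ethanol at exactly 100/238 g per g of glucose,
  absorbing the same rounding the RF equation's integer coefficient
  absorbs — otherwise the recovery test would only ever hold to the
  rounding error of 238 vs 100/0.42;
- pickles are simulated under the model's own assumptions: the product's
  water and salt follow the vegetable balance, and each marker nutrient
  carries only its designated source's contribution.

Acetic-fermented corpus foods oxidize their ethanol fully, because the
acetic RF equation has no residual-ethanol term. Generated RPCs carry no
salt, ethanol or acetic acid, as raw commodities do.

This is deliberate: the generator tests that the engines invert the
stated models exactly. It does **not** emulate real data's deviations
from those models — nutrient retention losses during cooking, thiamine
already present in vegetables, variable vinegar strengths, correlated
nutrient profiles, or measurement rounding in published tables. Passing
recovery therefore demonstrates correctness of the implementation, not
accuracy of the models on real foods. A noise mode is intentionally
absent from the default corpus; robustness to model violations shows up
instead as `infeasible` statuses, which the corpus exercises through its
deliberately broken foods (unknown ingredients, missing markers, more
ingredients than usable markers, singular systems, complicated
processing).

Default study conditions: 220 composite foods per corpus, ~30 % of items
RPCs, category proportions weighted toward mixed foods (as real
composition tables are), chains to tier 6, all randomness from one
integer seed; the same seed reproduces the corpus byte-for-byte. The
test suite uses corpora of 30–220 foods; these sizes exercise every
category and tier while keeping each property cheap to evaluate many
times.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `thiamine_rice_bran` | 3.12 | mg/100 g | thiamine content of rice-bran paste |
| `acetate_vinegar` | 4.2 | g/100 g | acetic acid content of vinegar |
| `sucrose_sugar` | 99.3 | g/100 g | sucrose content of table sugar |
| `protein_soy_sauce` | 7.7 | g/100 g | protein content of soy sauce |
| `protein_miso` | 12.5 | g/100 g | protein content of miso |
| `sucrose_soy_sauce` | 0.1 | g/100 g | sucrose carried by soy sauce |
| `ethanol_yield` | 0.42 | kg/kg | practical ethanol yield from glucose |
| `ferment_constant` | 238 | — | round(100/0.42); fermentation coefficient |
| `acetic_per_ethanol_assumed` | 1.0 | kg/kg | working acid:ethanol mass ratio |
| `pivot_tol` | 1e-10 | — | singularity threshold after row scaling |
| `max_depth` | 6 | tiers | deepest observed processing chain |
| `trace_as_zero` | TRUE | — | reading of "Tr" cells |

All medium constants are configuration (`process_constants()`), so a
revised composition table changes data, not code; internal consistency
(`glucose_per_ethanol ≈ 1/ethanol_yield` within 0.005,
`ferment_constant = round(100 · glucose_per_ethanol)`) is asserted at
construction.

## Known limitations

- Marker nutrients are assumed conserved; cooking losses (e.g. thiamine
  degradation) bias the corresponding RFs and are not modelled.
- The pickle equations attribute each marker wholly to one source;
  vegetables genuinely rich in protein or thiamine violate this.
- Mixed-food RFs are only as good as the configured ingredient lists and
  the linear-conservation assumption; the solver reports infeasibility
  but cannot repair a wrong recipe.
- Acetic-fermented foods must be linked directly to their
  carbohydrate-bearing raw material: the equation traces acid through
  ethanol to glucose, so an intermediate alcoholic product is not a
  valid ingredient for it. Deeper provenance is expressed through the
  recipe graph instead.
- Retention/loss of nutrients during mixed-food cooking, uncertainty
  propagation on RFs, and category inference from food names are out of
  scope.
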