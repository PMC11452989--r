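---
title: "Nutrient-density scoring of foods and one-day diets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient-density scoring of foods and one-day diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(nutridense)
```

## The problem

Nutrient-dense foods deliver substantial amounts of beneficial nutrients
for relatively few calories. Communicating that idea to consumers is the
purpose of nutrient-profiling indices and of food-guide graphics such as
the Chinese food guide pagoda (2022), which recommends daily gram
quantities per food group at a 2000 kcal energy level. `nutridense`
implements the quantitative machinery behind a pagoda-based
nutrient-density educational tool: the NRF9.2 index for foods and whole
one-day diets, adequacy evaluation (NAR/MAR), macronutrient
energy-supply profiling, within-group quartile points, pagoda-compliant
diet construction, and a deterministic SVG rendering of the
block-coloured pagoda with an energy label.

## The NRF9.2 model

The Nutrient-Rich Food index family scores a food per 100 kcal of
edible portion. NRF9.2 uses nine beneficial nutrients (protein, dietary
fiber, vitamins A, C and E, calcium, iron, magnesium, potassium) and two
limiting nutrients (saturated fat, sodium):

$$
NR_9 = \sum_{i=1}^{9} \frac{N_i}{NRV_i}\times 100,\qquad
LIM_2 = \sum_{j=1}^{2} \frac{L_j}{MNRV_j}\times 100,\qquad
NRF9.2 = NR_9 - LIM_2,
$$

with $N_i$, $L_j$ the nutrient amounts per 100 kcal (amount per 100 g
divided by energy density, times 100) and $NRV_i$, $MNRV_j$ daily
reference values on a 2000 kcal basis (`load_reference_set()`; saturated
fat 22.2 g and sodium 1450 mg derive from the acceptable
macronutrient-distribution range at that energy level).

Two numerical choices deserve note:

* **Normalisation is applied exactly once.** Some renderings of the
  formula carry an extra factor of 100 on the difference
  $(NR_9 - LIM_2)$ on top of the percent scaling already inside the
  sums. That double-counts the scale, so the package keeps the index in
  percent-of-reference units per 100 kcal: a food whose every beneficial
  nutrient sits at 5% of its NRV per 100 kcal scores $NR_9 = 45$, and
  the hand-checkable oil example (900 kcal/100 g, 14 g saturated
  fat/100 g) gives $LIM_2 \approx 7.0$. The unit tests lock this scale
  against such hand-arithmetic oracles.
* **Capping is off by default.** The sum-based algorithm does not
  truncate the per-nutrient ratios, so a fortified food can exceed 100%
  of an NRV per 100 kcal. `capped = TRUE` truncates each beneficial
  ratio at 1 before summing, for comparability with capped NRF
  variants.

A whole diet is scored by treating it as one composite food: total
daily nutrient intakes normalised per 100 kcal of total diet energy.
The score is therefore invariant under uniform scaling of all entry
grams, and a one-entry diet scores exactly like its food. Zero-energy
foods (and diets) have no per-100-kcal representation and raise an
error rather than returning an arbitrary value.

## Quartile points and the pagoda colouring

Within each food group, scored foods are split at the 25th/50th/75th
percentiles of their NRF9.2 scores and assigned 1 (lowest nutritional
quality) to 4 points. The published description fixes only "four groups
based on interquartile range", so the binning rule is a design choice,
made once and test-locked: linear-interpolation sample quantiles
(`stats::quantile(type = 7)`) with left-open bins — score $\le Q_1$
gives 1 point, $(Q_1, Q_2]$ gives 2, $(Q_2, Q_3]$ gives 3, above $Q_3$
gives 4. Binning by value means tied foods always share a bin, and a
group of identical scores collapses to 1 point for everyone. Groups
with fewer than four foods are rejected: their quartiles would be
artefacts. An independent brute-force oracle (explicit sorting and
hand-rolled interpolation) checks the implementation on small groups in
the test suite.

The render model maps a layer's point value to the fraction of each
block that keeps the layer's original colour — 1 point: one quarter, 2:
one half, 3: three quarters, 4: the full block — with the remainder
drawn in a lighter hue. When a layer contains several foods, the
layer's point value is the energy-weighted mean of its foods' points,
rounded to the nearest integer; energy weighting (rather than gram or
per-food weighting) follows the tool's premise of nutrition per
calorie. The same weighting drives `diet_point_score()`, the diet-level
1–4 summary. How the original tool combined multiple foods per layer,
and how its published diet-level labels were weighted, is not
documented, so these are package choices, stated here and held fixed.

## Adequacy: NAR, MAR and the energy-supply profile

The nutrient adequacy ratio is daily intake over the daily reference
intake; the mean adequacy ratio averages the NARs of a fixed
15-nutrient panel, each truncated at 1. Computation keeps full
precision; 2-decimal rounding happens only at display. Shortfall counts
("NAR < 1") use the raw, untruncated ratios with a strict inequality.

Two adequacy reference presets are shipped because the published
reference tables disagree on niacin: the standalone DRI panel lists
14 mg NE, while the RNI row printed beside the worked-example diets
uses 12 mg NE — and the worked-example MAR values only reproduce with
12. `adequacy_table3` (niacin 14) is the default for new analyses;
`adequacy_table6_rni` (niacin 12) is the default wherever the package
reproduces the worked examples. The iron reference is 15 mg in both; a
sex-split "13/15" variant appears alongside the worked examples and is
retained as metadata only, since iron adequacy caps at 1 in all three
diets under either value.

Macronutrient energy supply uses the Atwater factors 4/9/4 kcal per
gram of protein/fat/carbohydrate (never stated alongside the worked
examples, but consistent with them to rounding) and the recommended
bands 10–15% protein, 20–30% fat, 50–65% carbohydrate.
`energy_profile()` also accepts already-computed per-macronutrient kcal,
for checking published tables whose kcal entries embed their own
rounding.

## The worked-example diets

Three one-day diets — high, medium and low nutrient density, built from
the pagoda quantities at 2000 kcal — illustrate the tool:
energy 1686/2002/2362 kcal, fat energy share rising from 28% to 43%,
MAR falling 0.97 → 0.91 → 0.87 with 5/6/9 nutrients short of their
reference. The recipes behind these diets are not published; only their
per-day totals are. Each diet is therefore shipped (`demo_diet()`) as a
single `"composite"` pseudo-food whose per-100 g content equals the
daily totals, consumed at 100 g — every per-day quantity derived from
it is exact, while per-food structure is intentionally absent. The
published tables carry small internal inconsistencies (e.g. fat
52.84 g × 9 = 475.56 kcal against a printed 475.2; a total of 2362 kcal
in one table against 2363 in the running text); the fixtures carry the
printed kcal values, and the reproduction checks in
`run_demo_tables()` target the values that are arithmetically
self-consistent (totals, fat shares, MARs, shortfall sets). The
diet-level point labels attached to the published diets (3.6/2.6/1.6)
are not reproduced: their weighting scheme is undocumented and the
per-food lists needed to recompute them do not exist in print.

## The energy label

The label at the pagoda's foot compares diet energy with the preset
2000 kcal. "Within the preset level" is undefined in the source
description, so the band is a configuration knob defaulting to ±0.5% —
chosen so that the 2002 kcal worked example, presented as the on-target
diet, reads as within. Above the band the label fills gray, below it
white, in both cases by the relative deviation $|E - 2000|/2000$ capped
at 1 (the proportional fill rule is likewise unstated in the source and
is a documented package choice); within the band it fills dark
completely.

## The synthetic food generator

`generate_synthetic_foods()` supplies validated foods for tests and
demonstrations. Per food group it draws energy density and nutrient
amounts uniformly from fixed ranges chosen once to echo the broad
patterns of Chinese food-composition data: oils are nearly pure fat
with zero fiber and ~900 kcal/100 g, vegetables are low-energy and rich
in potassium, fiber and vitamin C, milk carries calcium and riboflavin,
soybeans are dense in protein, fiber and potassium, salt is nearly pure
sodium. Generation is deterministic for a fixed seed and never mutates
the caller's RNG state.

What the generator does *not* emulate: correlations between nutrients
within a food, regional consumption frequencies, seasonal or cooking
variation, and the skewed (rather than uniform) distributions of real
tables. Tests that pass on synthetic foods therefore demonstrate the
correctness of the scoring arithmetic and its invariants — not that any
particular real food ranks in any particular quartile. Real analyses
should feed `read_food_table()` with measured composition data.

## Problem sizes and determinism

All shipped computations are small: the worked-example evaluation is a
15-nutrient panel over three diets, property checks run on tens to ~100
generated foods, and quartile oracles use groups of 4–12. SVG output is
byte-deterministic (fixed element order, ids and number formatting), so
rendered files can be diffed and cached.

## Known limitations

* Only the 2000 kcal pagoda level is supported; other energy levels are
  an extension point, not implemented.
* Edible-portion basis throughout; cooking losses and nutrient
  retention are out of scope (tubers are fresh weight, converted at
  75 g fresh ≡ 15 g cereals when substituted into the cereal quota).
* Other NRF family members (NRF6.3, NRF11.3, per-serving or mean-based
  variants) are out of scope, as are probability-of-adequacy methods
  for adequacy.
* The quartile points depend on the food list supplied; the package
  ships no normative list of regional consumption data.
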