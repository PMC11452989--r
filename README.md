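# nutridense

Nutrient-density scoring of foods and one-day diets with the NRF9.2
index, for dietitians and nutritional epidemiologists working with
Chinese dietary guidance.

Consumers are advised to pick *nutrient-dense* foods — those that
deliver the most beneficial nutrients per calorie. `nutridense`
implements the quantitative core of a nutrient-density educational tool
built on the Chinese food guide pagoda (2022):

* **NRF9.2 scoring** of foods and whole one-day diets, per 100 kcal:

  NR9 = Σᵢ₌₁..₉ (Nᵢ / NRVᵢ) × 100,  LIM2 = Σⱼ₌₁..₂ (Lⱼ / MNRVⱼ) × 100,
  NRF9.2 = NR9 − LIM2

  over 9 beneficial nutrients (protein, dietary fiber, vitamins A/C/E,
  Ca, Fe, Mg, K) and 2 limiting nutrients (saturated fat 22.2 g,
  sodium 1450 mg), with all amounts per 100 kcal of edible portion and
  reference values on a 2000 kcal/day basis.
* **Adequacy evaluation**: nutrient adequacy ratios
  (NAR = intake / daily reference) over a fixed 15-nutrient panel and
  their truncated mean, the mean adequacy ratio (MAR ∈ [0, 1]).
* **Energy-supply profiling**: protein/fat/carbohydrate energy shares
  via Atwater factors 4/9/4 kcal/g, checked against the recommended
  bands 10–15% / 20–30% / 50–65%.
* **Quartile points**: within-food-group ranking of NRF9.2 scores into
  quartiles, 1 point (lowest nutritional quality) to 4 (highest).
* **Pagoda construction and rendering**: one-day diets with exactly the
  pagoda's recommended gram quantities, and a deterministic SVG of the
  pagoda whose blocks keep 1/4–4/4 of their colour according to the
  points, with an energy label that fills dark/gray/white as the diet
  sits on, above or below the 2000 kcal preset.

## Worked example

```r
library(nutridense)

# a pagoda-compliant day from synthetic foods (one per layer)
foods <- generate_synthetic_foods(
  setNames(rep(1, 11), c("cereals", "vegetables", "fruits",
                         "meat_poultry", "eggs", "aquatic", "milk",
                         "soybeans", "nuts", "cooking_oil", "salt")),
  seed = 42)
sel  <- setNames(foods, vapply(foods, `[[`, "", "food_group"))
diet <- build_diet_from_pagoda(sel, label = "my pagoda day")
score_diet(diet)
#> <nrf_score> my pagoda day: NRF9.2/100 kcal = 69.93 (NR9 81.85 - LIM2 11.92)
```

The diet supplies 81.85% of the nine beneficial-nutrient references and
11.92% of the two limiting-nutrient maxima per 100 kcal; their
difference, 69.93, is the diet's NRF9.2 per 100 kcal (higher = more
nutrient-dense).

```r
# rank cereals into quartile points
pool <- generate_synthetic_foods(c(cereals = 8), seed = 7)
pts  <- assign_quartile_points(lapply(pool, score_food), rep("cereals", 8))
head(pts[, c("food_id", "nrf92", "points")], 4)
#>                 food_id    nrf92 points
#> cereals_001 cereals_001 19.21524      1
#> cereals_002 cereals_002 26.98431      2
#> cereals_003 cereals_003 32.10902      4
#> cereals_004 cereals_004 29.06739      3

# adequacy of the shipped high-nutrient-density worked-example diet
rep_ <- adequacy_report(demo_diet("high"),
                        load_reference_set("adequacy_table6_rni"))
sprintf("MAR = %.2f, %d nutrients below reference", rep_$mar, rep_$n_below_one)
#> "MAR = 0.97, 5 nutrients below reference"

energy_label_state(total_energy(demo_diet("low")), 2000)
#> <energy_label_state> above: 2362 kcal vs preset 2000 kcal (fill 0.181, gray)
```

The MAR of 0.97 says the high-density diet meets, on average, 97% of
the 15-nutrient reference panel (each nutrient credited at most 100%);
the five shortfalls are vitamin B1, vitamin E, niacin, calcium and
fiber. The low-density diet overshoots the 2000 kcal preset by 18.1%,
so its energy label fills gray to that fraction.

Rendering and the shell interface:

```r
m <- render_model(diet, pts_for_diet, preset_kcal = 2000)
write_svg(m, "pagoda.svg")          # byte-deterministic SVG
```

```sh
Rscript inst/cli/nutridense.R demo            # reproduce the worked examples
Rscript inst/cli/nutridense.R adequacy --demo medium --refs adequacy_table6_rni --json
Rscript inst/cli/nutridense.R score-diet --foods foods.json --diet diet.csv --json
```

Exit codes: 0 success, 1 usage error, 2 validation error,
3 reproduction mismatch in `demo`.

## Reference data

`load_reference_set()` ships the DRI presets (`nrf92_beneficial`,
`nrf92_limits`, and two 15-nutrient adequacy panels that differ only in
the niacin reference — see the vignette for why both exist);
`load_pagoda_layers()` ships the 13-row pagoda block structure at
2000 kcal. `demo_diet("high" | "medium" | "low")` returns the three
worked-example one-day diets as per-day-total composites.

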