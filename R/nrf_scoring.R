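#' @title NRF9.2 nutrient-density scoring
#' @description
#' The NRF9.2 (Nutrient-Rich Food) index ranks a food or a whole diet by
#' nutrient density per 100 kcal:
#'
#' \deqn{NR9 = \sum_{i=1}^{9} \frac{N_i}{NRV_i} \times 100, \qquad
#'       LIM2 = \sum_{i=1}^{2} \frac{L_i}{MNRV_i} \times 100, \qquad
#'       NRF9.2 = NR9 - LIM2}
#'
#' where \eqn{N_i} and \eqn{L_i} are the amounts of beneficial nutrient
#' \eqn{i} (protein, dietary fiber, vitamins A/C/E, Ca, Fe, Mg, K) and
#' limiting nutrient \eqn{i} (saturated fat, sodium) per 100 kcal of
#' edible portion, and \eqn{NRV_i}/\eqn{MNRV_i} are the corresponding
#' daily reference values on a 2000 kcal basis
#' (see [load_reference_set()]). Units are percent of daily reference per
#' 100 kcal; the normalisation by reference values is applied exactly
#' once. Scores are undefined for zero-energy foods.
#'
#' By default the per-nutrient ratios are not truncated; `capped = TRUE`
#' truncates each beneficial ratio at 100% of its NRV before summing, for
#' comparability with capped NRF variants.
#' @name nrf_scoring
NULL

#' Nutrient amount per 100 kcal of a food
#'
#' @param food A [food_composition()].
#' @param nutrient Nutrient id.
#' @return Amount per 100 kcal: `per-100 g amount / energy density x 100`.
#'   Errors for a zero-energy food (a per-100-kcal amount is undefined).
#' @export
#' @examples
#' f <- food_composition("x", "x", "cereals", 200, c(protein = 10))
#' nutrient_per_100kcal(f, "protein") # 5
nutrient_per_100kcal <- function(food, nutrient) {
  if (food$energy_kcal_100g <= 0) {
    stop("Food ", food$food_id, " has zero energy density; ",
         "per-100-kcal amounts (and NRF scores) are undefined",
         call. = FALSE)
  }
  food_nutrient(food, nutrient) / food$energy_kcal_100g * 100
}

#' @describeIn nrf_scoring Beneficial-nutrient sum NR9 (percent of NRV
#'   per 100 kcal). `refs` must be the 9-entry beneficial set.
#' @param food A [food_composition()].
#' @param refs A `nutrient_reference_set`; defaults to the shipped preset.
#' @param capped Truncate each beneficial nutrient ratio at 100% of NRV
#'   before summing (default `FALSE`; the sum-based algorithm is
#'   uncapped).
#' @export
compute_nr9 <- function(food, refs = load_reference_set("nrf92_beneficial"),
                        capped = FALSE) {
  stopifnot(inherits(refs, "nutrient_reference_set"))
  if (refs$kind != "beneficial-reference") {
    stop("compute_nr9 needs a beneficial-reference set (9 entries)",
         call. = FALSE)
  }
  ratios <- vapply(names(refs$values), function(n) {
    nutrient_per_100kcal(food, n) / refs$values[[n]]
  }, numeric(1))
  if (capped) ratios <- pmin(ratios, 1)
  sum(ratios) * 100
}

#' @describeIn nrf_scoring Limiting-nutrient sum LIM2 (percent of MNRV
#'   per 100 kcal) over saturated fat and sodium.
#' @export
compute_lim2 <- function(food, refs = load_reference_set("nrf92_limits")) {
  stopifnot(inherits(refs, "nutrient_reference_set"))
  if (refs$kind != "maximum-reference") {
    stop("compute_lim2 needs a maximum-reference set (2 entries)",
         call. = FALSE)
  }
  ratios <- vapply(names(refs$values), function(n) {
    nutrient_per_100kcal(food, n) / refs$values[[n]]
  }, numeric(1))
  sum(ratios) * 100
}

new_nrf_score <- function(subject_id, nr9, lim2) {
  structure(
    list(subject_id = subject_id, nr9 = nr9, lim2 = lim2,
         nrf92 = nr9 - lim2),
    class = "nrf_score"
  )
}

#' @export
print.nrf_score <- function(x, ...) {
  cat(sprintf("<nrf_score> %s: NRF9.2/100 kcal = %.2f (NR9 %.2f - LIM2 %.2f)\n",
              x$subject_id, x$nrf92, x$nr9, x$lim2))
  invisible(x)
}

#' Score a single food
#'
#' @inheritParams compute_nr9
#' @param limit_refs The 2-entry limiting set.
#' @return An `nrf_score` object with fields `nr9`, `lim2`,
#'   `nrf92 = nr9 - lim2` and `subject_id`.
#' @export
#' @examples
#' oil <- food_composition("oil", "Oil", "cooking_oil", 900,
#'                         c(fat = 100, saturated_fat = 14))
#' score_food(oil)
score_food <- function(food,
                       refs = load_reference_set("nrf92_beneficial"),
                       limit_refs = load_reference_set("nrf92_limits"),
                       capped = FALSE) {
  new_nrf_score(food$food_id,
                compute_nr9(food, refs, capped = capped),
                compute_lim2(food, limit_refs))
}

#' Score a whole one-day diet
#'
#' The diet is treated as one composite food: total daily nutrient
#' intakes are normalised per 100 kcal of total diet energy, then
#' NR9 - LIM2 is applied as for a food. The score is therefore invariant
#' under uniform scaling of all entry grams, and a one-entry diet scores
#' identically to [score_food()] on that food.
#'
#' @param diet A [day_diet()].
#' @inheritParams score_food
#' @return An `nrf_score`.
#' @export
score_diet <- function(diet,
                       refs = load_reference_set("nrf92_beneficial"),
                       limit_refs = load_reference_set("nrf92_limits"),
                       capped = FALSE) {
  stopifnot(inherits(diet, "day_diet"))
  energy <- total_energy(diet)
  if (energy <= 0) {
    stop("Diet has zero total energy; NRF9.2 per 100 kcal is undefined",
         call. = FALSE)
  }
  all_nuts <- unique(unlist(lapply(diet$entries,
                                   function(e) names(e$food$nutrients))))
  totals <- vapply(all_nuts, function(n) total_nutrient_intake(diet, n),
                   numeric(1))
  composite <- food_composition(
    food_id = if (nzchar(diet$label)) diet$label else "diet",
    name = "diet composite", food_group = "composite",
    energy_kcal_100g = energy,
    nutrients = totals
  )
  score_food(composite, refs, limit_refs, capped = capped)
}
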