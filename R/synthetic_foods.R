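#' Generate synthetic foods with plausible per-group nutrient profiles
#'
#' Draws food composition records whose energy density and nutrient
#' amounts fall inside documented per-group ranges typical of Chinese
#' food-composition data: cooking oils are fat-dominant with zero fiber,
#' vegetables are low-energy and rich in potassium, fiber and vitamin C,
#' milk carries calcium and riboflavin, and so on. Used for tests and
#' demonstrations where a real composition table is not required; the
#' generator reproduces relative patterns between groups, not any
#' particular food, brand or regional consumption distribution.
#'
#' Sampling is uniform within each range (log-uniform would skew small;
#' plausibility, not realism, is the goal). Deterministic for a fixed
#' seed. Every generated food passes [food_composition()] validation and
#' has strictly positive energy density, so NRF scores are always finite.
#'
#' @param group_spec Named integer vector or list, pagoda food group to
#'   number of foods to generate (counts >= 1).
#' @param seed Integer seed.
#' @return A named list of [food_composition()] objects.
#' @export
#' @examples
#' foods <- generate_synthetic_foods(c(cereals = 4, cooking_oil = 2), seed = 1)
#' foods[[1]]
generate_synthetic_foods <- function(group_spec, seed) {
  counts <- unlist(group_spec)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("group_spec must map food groups to counts", call. = FALSE)
  }
  bad <- setdiff(names(counts), pagoda_groups())
  if (length(bad)) {
    stop("Unknown food group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 1)) stop("Counts must be >= 1", call. = FALSE)
  ranges <- .group_nutrient_ranges()
  foods <- list()
  # private RNG stream: leaves the caller's .Random.seed untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (grp in names(counts)) {
    rng <- ranges[[grp]]
    for (k in seq_len(counts[[grp]])) {
      id <- sprintf("%s_%03d", grp, k)
      ed <- stats::runif(1, rng$energy[1], rng$energy[2])
      nuts <- vapply(rng$nutrients, function(lim) {
        stats::runif(1, lim[1], lim[2])
      }, numeric(1))
      foods[[id]] <- food_composition(
        id, sprintf("Synthetic %s #%d", gsub("_", " ", grp), k), grp,
        round(ed, 2), round(nuts, 4)
      )
    }
  }
  foods
}

# per-100 g ranges (registry units); one fixed choice per group
.group_nutrient_ranges <- function() {
  r <- function(lo, hi) c(lo, hi)
  list(
    cereals = list(energy = r(330, 380), nutrients = list(
      protein = r(7, 14), fat = r(1, 4), carbohydrate = r(65, 78),
      fiber = r(1, 10), saturated_fat = r(0.2, 1), sodium = r(1, 10),
      vitamin_b1 = r(0.1, 0.5), niacin = r(1, 5), iron = r(1, 5),
      magnesium = r(30, 150), potassium = r(100, 350),
      phosphorus = r(100, 350), zinc = r(1, 3), calcium = r(5, 40),
      vitamin_e = r(0.3, 2)
    )),
    tubers = list(energy = r(60, 110), nutrients = list(
      protein = r(1, 3), fat = r(0.1, 0.5), carbohydrate = r(14, 26),
      fiber = r(0.8, 3.5), sodium = r(2, 30), vitamin_c = r(10, 30),
      potassium = r(200, 500), magnesium = r(15, 40),
      phosphorus = r(30, 70), calcium = r(5, 30), iron = r(0.3, 1.2)
    )),
    vegetables = list(energy = r(15, 60), nutrients = list(
      protein = r(1, 4), fat = r(0.1, 0.6), carbohydrate = r(2, 10),
      fiber = r(1, 4), sodium = r(5, 100), vitamin_a = r(10, 300),
      vitamin_c = r(10, 100), vitamin_e = r(0.2, 2),
      potassium = r(100, 400), magnesium = r(10, 60),
      calcium = r(20, 150), iron = r(0.5, 3), phosphorus = r(20, 80)
    )),
    dark_vegetables = list(energy = r(20, 60), nutrients = list(
      protein = r(1.5, 5), fat = r(0.2, 0.8), carbohydrate = r(2, 9),
      fiber = r(1.5, 4.5), sodium = r(10, 120), vitamin_a = r(200, 600),
      vitamin_c = r(20, 120), vitamin_e = r(0.5, 2.5),
      potassium = r(150, 500), magnesium = r(20, 80),
      calcium = r(50, 200), iron = r(1, 4), phosphorus = r(30, 90)
    )),
    fruits = list(energy = r(30, 90), nutrients = list(
      protein = r(0.3, 1.5), fat = r(0.1, 0.5), carbohydrate = r(7, 22),
      fiber = r(0.8, 4), sodium = r(0.5, 5), vitamin_a = r(2, 100),
      vitamin_c = r(5, 80), potassium = r(80, 300),
      magnesium = r(5, 25), calcium = r(4, 30), iron = r(0.2, 1)
    )),
    meat_poultry = list(energy = r(110, 400), nutrients = list(
      protein = r(13, 22), fat = r(3, 35), saturated_fat = r(1, 13),
      sodium = r(40, 90), iron = r(1, 4), zinc = r(1.5, 5),
      vitamin_b1 = r(0.03, 0.6), vitamin_b2 = r(0.1, 0.3),
      niacin = r(3, 9), phosphorus = r(120, 220),
      potassium = r(150, 350), selenium = r(5, 20)
    )),
    eggs = list(energy = r(130, 170), nutrients = list(
      protein = r(11, 14), fat = r(8, 12), saturated_fat = r(2.5, 4),
      sodium = r(100, 170), vitamin_a = r(150, 310),
      vitamin_b2 = r(0.2, 0.4), iron = r(1.5, 3), zinc = r(0.8, 1.5),
      phosphorus = r(130, 230), selenium = r(10, 30),
      calcium = r(40, 70)
    )),
    aquatic = list(energy = r(80, 180), nutrients = list(
      protein = r(15, 22), fat = r(1, 10), saturated_fat = r(0.3, 2.5),
      sodium = r(40, 160), calcium = r(20, 120), iron = r(0.5, 2),
      zinc = r(0.8, 3), selenium = r(15, 50), phosphorus = r(130, 250),
      potassium = r(200, 400), vitamin_e = r(0.5, 2.5),
      niacin = r(1.5, 4)
    )),
    milk = list(energy = r(50, 75), nutrients = list(
      protein = r(2.8, 3.8), fat = r(1, 4.2), saturated_fat = r(0.6, 2.7),
      carbohydrate = r(3.5, 6), sodium = r(35, 65),
      calcium = r(100, 130), vitamin_a = r(15, 60),
      vitamin_b2 = r(0.1, 0.25), phosphorus = r(70, 110),
      potassium = r(100, 180), zinc = r(0.3, 0.6)
    )),
    soybeans = list(energy = r(350, 420), nutrients = list(
      protein = r(30, 40), fat = r(15, 20), saturated_fat = r(2, 3.5),
      carbohydrate = r(18, 34), fiber = r(9, 16), sodium = r(1, 6),
      calcium = r(150, 250), iron = r(6, 10), magnesium = r(150, 250),
      potassium = r(1200, 1700), zinc = r(3, 5),
      phosphorus = r(400, 600), vitamin_e = r(10, 25)
    )),
    nuts = list(energy = r(520, 650), nutrients = list(
      protein = r(12, 25), fat = r(40, 60), saturated_fat = r(4, 10),
      carbohydrate = r(10, 25), fiber = r(5, 12), sodium = r(1, 10),
      magnesium = r(100, 300), potassium = r(400, 800),
      vitamin_e = r(5, 40), zinc = r(2, 6), iron = r(2, 6),
      phosphorus = r(300, 500)
    )),
    cooking_oil = list(energy = r(880, 900), nutrients = list(
      fat = r(99, 100), saturated_fat = r(8, 45), vitamin_e = r(5, 90),
      sodium = r(0, 2)
    )),
    salt = list(energy = r(0.05, 0.5), nutrients = list(
      sodium = r(38000, 39500)
    ))
  )
}
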