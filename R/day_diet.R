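#' Construct a one-day diet
#'
#' A day diet is an ordered list of (food, grams consumed) entries with a
#' preset energy level (the pagoda's 2000 kcal by default). Grams are
#' edible portion.
#'
#' @param foods List of [food_composition()] objects (or a single one).
#' @param grams Numeric vector of grams consumed, one per food (> 0).
#' @param preset_energy_kcal Preset daily energy level, kcal.
#' @param label Free-text label for reports.
#' @return A `day_diet` object.
#' @export
#' @examples
#' oil <- food_composition("oil1", "Soybean oil", "cooking_oil", 899,
#'                         c(fat = 99.9, saturated_fat = 14))
#' day_diet(list(oil), 25)
day_diet <- function(foods, grams, preset_energy_kcal = 2000, label = "") {
  if (inherits(foods, "food_composition")) foods <- list(foods)
  if (length(foods) == 0) stop("A day diet needs at least one entry",
                               call. = FALSE)
  if (length(grams) != length(foods)) {
    stop("grams must have one value per food", call. = FALSE)
  }
  if (any(is.na(grams) | grams <= 0)) {
    stop("Entry grams must all be > 0", call. = FALSE)
  }
  ok <- vapply(foods, inherits, TRUE, "food_composition")
  if (!all(ok)) stop("foods must be food_composition objects", call. = FALSE)
  structure(
    list(
      entries = lapply(seq_along(foods), function(i) {
        list(food = foods[[i]], grams = as.numeric(grams[[i]]))
      }),
      preset_energy_kcal = preset_energy_kcal,
      label = label
    ),
    class = "day_diet"
  )
}

#' @export
print.day_diet <- function(x, ...) {
  cat("<day_diet> ", if (nzchar(x$label)) x$label else "(unlabelled)",
      ": ", length(x$entries), " entr",
      if (length(x$entries) == 1) "y" else "ies",
      ", preset ", x$preset_energy_kcal, " kcal\n", sep = "")
  for (e in x$entries) {
    cat(sprintf("  %-12s %8.1f g  %s\n", e$food$food_id, e$grams,
                e$food$name))
  }
  invisible(x)
}

#' Total daily intake of one nutrient
#'
#' Sums `amount per 100 g x grams / 100` over all entries. Linear in
#' grams.
#'
#' @param diet A [day_diet()].
#' @param nutrient A nutrient id from [nutrient_registry()].
#' @return Amount per day in the registry unit.
#' @export
total_nutrient_intake <- function(diet, nutrient) {
  stopifnot(inherits(diet, "day_diet"))
  nutrient_unit(nutrient) # errors on unknown id
  sum(vapply(diet$entries, function(e) {
    food_nutrient(e$food, nutrient) * e$grams / 100
  }, numeric(1)))
}

#' Total daily energy of a diet
#'
#' @param diet A [day_diet()].
#' @return kcal per day: the sum of energy density times grams / 100 over
#'   entries.
#' @export
total_energy <- function(diet) {
  stopifnot(inherits(diet, "day_diet"))
  sum(vapply(diet$entries, function(e) {
    e$food$energy_kcal_100g * e$grams / 100
  }, numeric(1)))
}

#' Read a diet from file
#'
#' CSV needs columns `food_id`, `grams`; JSON an array of
#' `{food_id, grams}` objects (optionally `label`, `preset_energy_kcal`
#' at top level under keys `entries`/`label`/`preset_energy_kcal`).
#' Foods are looked up in `foods` by id.
#'
#' @param path Diet file (`.csv` or `.json`).
#' @param foods Named list of [food_composition()] objects, as returned
#'   by [read_food_table()].
#' @return A [day_diet()].
#' @export
read_diet <- function(path, foods) {
  ext <- tolower(tools::file_ext(path))
  label <- ""
  preset <- 2000
  if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(payload)) {
      tab <- payload
    } else {
      tab <- as.data.frame(payload$entries)
      if (!is.null(payload$label)) label <- payload$label
      if (!is.null(payload$preset_energy_kcal)) {
        preset <- payload$preset_energy_kcal
      }
    }
  } else {
    stop("Unsupported diet format: .", ext, call. = FALSE)
  }
  missing_ids <- setdiff(tab$food_id, names(foods))
  if (length(missing_ids)) {
    stop("Diet ", path, " references unknown food_id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  day_diet(foods[tab$food_id], tab$grams, preset_energy_kcal = preset,
           label = label)
}

#' Worked-example one-day diets
#'
#' The educational tool is illustrated with three one-day diets built
#' from the pagoda's 2000 kcal quantities with foods of high, medium and
#' low nutrient density (NRF9.2 score). Their published per-day totals —
#' 15 adequacy-panel nutrient intakes, macronutrient grams and energy —
#' are shipped here. The per-food recipes behind them are not published,
#' so each diet is encoded as a single `"composite"` pseudo-food whose
#' per-100 g composition equals the daily totals, consumed at 100 g; all
#' per-day quantities derived from it are exact.
#'
#' The pseudo-food's energy density carries the published total energy
#' (1686 / 2002 / 2362 kcal), which differs from the 4/9/4
#' Atwater-factor value of the macronutrient grams by < 1 kcal.
#'
#' @param which `"high"`, `"medium"` or `"low"` (nutrient density).
#' @return A [day_diet()] with one composite entry and attribute
#'   `macro_kcal`, the published per-macronutrient kcal
#'   (protein/fat/carbohydrate).
#' @export
#' @examples
#' d <- demo_diet("high")
#' total_energy(d)
#' total_nutrient_intake(d, "fiber")
demo_diet <- function(which = c("high", "medium", "low")) {
  which <- match.arg(which)
  path <- system.file("extdata", "demo_diets.json", package = "nutridense")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  rec <- payload[[which]]
  nutrients <- unlist(rec$nutrients_per_day)
  food <- food_composition(
    food_id = paste0("demo_", which),
    name = rec$name,
    food_group = "composite",
    energy_kcal_100g = rec$total_kcal,
    nutrients = nutrients
  )
  d <- day_diet(list(food), 100, preset_energy_kcal = 2000,
                label = rec$name)
  attr(d, "macro_kcal") <- unlist(rec$macro_kcal_per_day)
  d
}
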