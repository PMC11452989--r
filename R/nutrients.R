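#' Canonical nutrient registry
#'
#' Every nutrient handled by the package is identified by a canonical
#' lowercase token. Units are attached here, in the data model — they are
#' never inferred from column or nutrient names. Amounts are always per day
#' (intakes, reference values) or per 100 g edible portion (food
#' composition), in the unit listed below.
#'
#' @return A data frame with columns `nutrient` (canonical id), `unit`
#'   (unit token, e.g. `"g"`, `"mg"`, `"ug_re"` for retinol equivalents,
#'   `"mg_ate"` for alpha-tocopherol equivalents, `"mg_ne"` for niacin
#'   equivalents) and `label` (display name).
#' @export
#' @examples
#' nutrient_registry()
nutrient_registry <- function() {
  data.frame(
    nutrient = c(
      "protein", "fat", "carbohydrate", "fiber", "saturated_fat",
      "sodium", "vitamin_a", "vitamin_c", "vitamin_e", "vitamin_b1",
      "vitamin_b2", "niacin", "calcium", "iron", "magnesium",
      "potassium", "phosphorus", "zinc", "selenium"
    ),
    unit = c(
      "g", "g", "g", "g", "g",
      "mg", "ug_re", "mg", "mg_ate", "mg",
      "mg", "mg_ne", "mg", "mg", "mg",
      "mg", "mg", "mg", "ug"
    ),
    label = c(
      "Protein", "Fat", "Carbohydrate", "Dietary fiber", "Saturated fat",
      "Sodium", "Vitamin A", "Vitamin C", "Vitamin E", "Vitamin B1",
      "Vitamin B2", "Niacin (vitamin PP)", "Calcium", "Iron", "Magnesium",
      "Potassium", "Phosphorus", "Zinc", "Selenium"
    ),
    stringsAsFactors = FALSE
  )
}

known_nutrients <- function() nutrient_registry()$nutrient

nutrient_unit <- function(nutrient) {
  reg <- nutrient_registry()
  idx <- match(nutrient, reg$nutrient)
  if (anyNA(idx)) {
    stop("Unknown nutrient id(s): ",
         paste(nutrient[is.na(idx)], collapse = ", "),
         ". Known ids: ", paste(reg$nutrient, collapse = ", "),
         call. = FALSE)
  }
  reg$unit[idx]
}
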