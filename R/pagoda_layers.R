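#' Food guide pagoda layer structure (2000 kcal)
#'
#' The Chinese food guide pagoda (2022) recommends a daily quantity per
#' food group at the 2000 kcal energy level. For the educational tool each
#' group's quantity is discretized into gram "blocks" (half blocks
#' allowed). This loader returns the 13 layer rows: the 11 main groups
#' plus two sub-rows (dark-coloured vegetables within vegetables, and
#' tubers within cereals, the latter carrying the fresh-weight conversion:
#' 75 g fresh tuber is equivalent to 15 g cereals). The whole-grain
#' recommendation (50–150 g within cereals) is a range, not a layer, and
#' is carried as metadata on the cereals row.
#'
#' `grams_per_block` is the gram weight of one *full* block, so
#' `block_count * grams_per_block == recommended_grams` holds exactly on
#' every block-bearing row (e.g. soybeans: 0.5 block of 30 g = 15 g/day,
#' displayed as "15 g / 0.5 block").
#'
#' @return A data frame with one row per layer and columns `food_group`,
#'   `recommended_grams`, `block_count`, `grams_per_block`, `parent_group`
#'   (`NA` for main layers), `note`, `whole_grains_min_g`,
#'   `whole_grains_max_g` (cereals row only).
#' @export
#' @examples
#' layers <- load_pagoda_layers()
#' layers[layers$food_group == "cereals", ]
load_pagoda_layers <- function() {
  layers <- data.frame(
    food_group = c(
      "cereals", "tubers", "vegetables", "dark_vegetables", "fruits",
      "meat_poultry", "eggs", "aquatic", "milk", "soybeans", "nuts",
      "cooking_oil", "salt"
    ),
    recommended_grams = c(250, 75, 450, 225, 300, 50, 50, 50, 300, 15,
                          10, 25, 5),
    block_count = c(5, NA, 2, 1, 2, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5),
    grams_per_block = c(50, NA, 225, 225, 150, 50, 50, 50, 300, 30, 20,
                        50, 10),
    parent_group = c(NA, "cereals", NA, "vegetables", NA, NA, NA, NA,
                     NA, NA, NA, NA, NA),
    note = c(
      "whole grains and mixed beans 50-150 g within the quota",
      "fresh weight; 75 g fresh tuber equivalent to 15 g cereals",
      NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA
    ),
    whole_grains_min_g = c(50, rep(NA, 12)),
    whole_grains_max_g = c(150, rep(NA, 12)),
    stringsAsFactors = FALSE
  )
  has_blocks <- !is.na(layers$block_count)
  stopifnot(all(abs(layers$block_count[has_blocks] *
                      layers$grams_per_block[has_blocks] -
                      layers$recommended_grams[has_blocks]) < 1e-12))
  layers
}

# grams of fresh tuber that substitute for one gram of cereals
TUBER_G_PER_CEREAL_G <- 75 / 15

pagoda_main_groups <- function() {
  layers <- load_pagoda_layers()
  layers$food_group[is.na(layers$parent_group)]
}

pagoda_groups <- function() load_pagoda_layers()$food_group

#' Write the pagoda layer table as JSON
#'
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_pagoda_layers <- function(path) {
  jsonlite::write_json(load_pagoda_layers(), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
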