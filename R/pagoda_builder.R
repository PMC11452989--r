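#' Build a pagoda-compliant one-day diet
#'
#' Constructs a [day_diet()] whose gram quantities are exactly the food
#' guide pagoda recommendations at the 2000 kcal level (see
#' [load_pagoda_layers()]): one chosen food per main layer, with its
#' layer's recommended grams. Swapping a food for another of the same
#' group never changes the gram quantities — only the diet's nutrient
#' density.
#'
#' A fresh tuber may substitute part of the cereal quota at the
#' fresh-weight conversion 75 g tuber = 15 g cereals: the cereals entry
#' is reduced by `tuber_cereal_g` and a tuber entry of
#' `5 x tuber_cereal_g` fresh grams is appended.
#'
#' @param foods Named list mapping each main food group (`cereals`,
#'   `vegetables`, `fruits`, `meat_poultry`, `eggs`, `aquatic`, `milk`,
#'   `soybeans`, `nuts`, `cooking_oil`, `salt`) to a
#'   [food_composition()] of that group.
#' @param energy_level_kcal Preset energy level; only 2000 kcal is
#'   supported (the pagoda quantities are defined at that level).
#' @param tuber Optional [food_composition()] of group `"tubers"`.
#' @param tuber_cereal_g Grams of the cereal quota covered by the tuber
#'   (cereal-equivalent weight, default 15 when a tuber is given).
#' @param label Diet label.
#' @return A [day_diet()].
#' @export
build_diet_from_pagoda <- function(foods, energy_level_kcal = 2000,
                                   tuber = NULL, tuber_cereal_g = 15,
                                   label = "pagoda diet") {
  if (energy_level_kcal != 2000) {
    stop("Only the 2000 kcal energy level is supported; the pagoda ",
         "block quantities are defined at 2000 kcal", call. = FALSE)
  }
  layers <- load_pagoda_layers()
  required <- pagoda_main_groups()
  missing_layers <- setdiff(required, names(foods))
  if (length(missing_layers)) {
    stop("No food chosen for layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  for (g in required) {
    if (foods[[g]]$food_group != g) {
      stop("Food ", foods[[g]]$food_id, " given for layer ", g,
           " belongs to group ", foods[[g]]$food_group, call. = FALSE)
    }
  }
  grams <- layers$recommended_grams[match(required, layers$food_group)]
  names(grams) <- required
  sel <- foods[required]
  if (!is.null(tuber)) {
    if (tuber$food_group != "tubers") {
      stop("tuber must be a food of group 'tubers'", call. = FALSE)
    }
    if (tuber_cereal_g <= 0 || tuber_cereal_g >= grams[["cereals"]]) {
      stop("tuber_cereal_g must be in (0, ", grams[["cereals"]], ")",
           call. = FALSE)
    }
    grams[["cereals"]] <- grams[["cereals"]] - tuber_cereal_g
    sel <- c(sel, list(tubers = tuber))
    grams <- c(grams, tubers = tuber_cereal_g * TUBER_G_PER_CEREAL_G)
  }
  day_diet(unname(sel), unname(grams),
           preset_energy_kcal = energy_level_kcal, label = label)
}

#' Energy label state for the pagoda's energy bar
#'
#' The energy label at the foot of the pagoda compares the diet's energy
#' with the preset level: on target the label turns dark; above target a
#' gray fill, below target a white fill. The fill fraction is the
#' relative deviation `|diet - preset| / preset`, capped at 1 ("on
#' target" fills fully dark).
#'
#' @param diet_kcal Diet energy, kcal/day (>= 0).
#' @param preset_kcal Preset energy level (> 0, default 2000).
#' @param tolerance Relative half-width of the "within" band (default
#'   0.005, i.e. +/-0.5% of preset).
#' @return An `energy_label_state`: list with `diet_kcal`, `preset_kcal`,
#'   `state` (`"within"`, `"above"` or `"below"`), `fill_fraction` and
#'   `fill_color` token (`"dark"`, `"gray"`, `"white"`).
#' @export
#' @examples
#' energy_label_state(2362, 2000) # above, fill 0.181
energy_label_state <- function(diet_kcal, preset_kcal = 2000,
                               tolerance = 0.005) {
  if (is.na(diet_kcal) || diet_kcal < 0) {
    stop("diet_kcal must be >= 0", call. = FALSE)
  }
  if (is.na(preset_kcal) || preset_kcal <= 0) {
    stop("preset_kcal must be > 0", call. = FALSE)
  }
  dev <- (diet_kcal - preset_kcal) / preset_kcal
  if (abs(dev) <= tolerance) {
    state <- "within"; fill <- "dark"; frac <- 1
  } else if (dev > 0) {
    state <- "above"; fill <- "gray"; frac <- min(dev, 1)
  } else {
    state <- "below"; fill <- "white"; frac <- min(-dev, 1)
  }
  structure(
    list(diet_kcal = diet_kcal, preset_kcal = preset_kcal,
         state = state, fill_fraction = frac, fill_color = fill,
         tolerance = tolerance),
    class = "energy_label_state"
  )
}

#' @export
print.energy_label_state <- function(x, ...) {
  cat(sprintf(
    "<energy_label_state> %s: %.0f kcal vs preset %.0f kcal (fill %.3f, %s)\n",
    x$state, x$diet_kcal, x$preset_kcal, x$fill_fraction, x$fill_color))
  invisible(x)
}

# block colour fraction from quartile points
POINTS_TO_FRACTION <- c(`1` = 0.25, `2` = 0.5, `3` = 0.75, `4` = 1.0)

# default layer palette tokens (configurable, not normative)
default_palette <- function() {
  c(cereals = "brown", tubers = "brown", vegetables = "green",
    dark_vegetables = "darkgreen", fruits = "lightgreen",
    meat_poultry = "red", eggs = "orange", aquatic = "blue",
    milk = "lavender", soybeans = "khaki", nuts = "tan",
    cooking_oil = "gold", salt = "gray")
}

#' Compute the pagoda render model for a scored diet
#'
#' A pure function of (diet, points, preset): per pagoda layer present
#' in the diet it records the block count, the layer's point value (the
#' energy-weighted mean of its foods' points, rounded to the nearest
#' integer) and the resulting per-block colour fraction under the fixed
#' map 1 point = 1/4 of the block keeps its colour, 2 = 1/2, 3 = 3/4,
#' 4 = full original colour; plus the energy-label state.
#'
#' @param diet A [day_diet()].
#' @param points Data frame with `food_id` and `points` columns (see
#'   [assign_quartile_points()]) covering every diet food.
#' @param preset_kcal Preset energy level for the label.
#' @param tolerance Energy-label tolerance, see [energy_label_state()].
#' @param palette Named character vector of base-colour tokens per food
#'   group; defaults to the pagoda palette tokens.
#' @param title Title rendered above the pagoda.
#' @return A `pagoda_render_model`: list with `layers` (data frame:
#'   `food_group`, `block_count`, `points`, `color_fraction`,
#'   `base_color`), `energy_label` and `title`.
#' @export
render_model <- function(diet, points, preset_kcal = 2000,
                         tolerance = 0.005, palette = default_palette(),
                         title = "Dietary nutrient density") {
  stopifnot(inherits(diet, "day_diet"))
  ids <- vapply(diet$entries, function(e) e$food$food_id, character(1))
  idx <- match(ids, points$food_id)
  if (anyNA(idx)) {
    stop("No point assignment for food(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  grp <- vapply(diet$entries, function(e) e$food$food_group, character(1))
  kcal <- vapply(diet$entries, function(e) {
    e$food$energy_kcal_100g * e$grams / 100
  }, numeric(1))
  pts <- points$points[idx]
  layers <- load_pagoda_layers()
  order_grp <- layers$food_group[layers$food_group %in% grp]
  layer_pts <- vapply(order_grp, function(g) {
    i <- grp == g
    w <- kcal[i]
    p <- if (sum(w) > 0) sum(pts[i] * w) / sum(w) else mean(pts[i])
    max(1L, min(4L, as.integer(round(p))))
  }, integer(1))
  lay <- data.frame(
    food_group = order_grp,
    block_count = layers$block_count[match(order_grp, layers$food_group)],
    points = layer_pts,
    color_fraction = unname(POINTS_TO_FRACTION[as.character(layer_pts)]),
    base_color = unname(palette[order_grp]),
    stringsAsFactors = FALSE
  )
  # sub-rows without their own blocks render as a single half block
  lay$block_count[is.na(lay$block_count)] <- 0.5
  lay$base_color[is.na(lay$base_color)] <- "gray"
  structure(
    list(layers = lay,
         energy_label = energy_label_state(total_energy(diet),
                                           preset_kcal, tolerance),
         title = title),
    class = "pagoda_render_model"
  )
}

#' @export
print.pagoda_render_model <- function(x, ...) {
  cat("<pagoda_render_model> ", x$title, "\n", sep = "")
  for (i in seq_len(nrow(x$layers))) {
    l <- x$layers[i, ]
    cat(sprintf("  %-16s %4.1f block(s)  %d pt  colour %.2f (%s)\n",
                l$food_group, l$block_count, l$points, l$color_fraction,
                l$base_color))
  }
  e <- x$energy_label
  cat(sprintf("  energy label: %s (%.0f vs %.0f kcal, fill %.3f %s)\n",
              e$state, e$diet_kcal, e$preset_kcal, e$fill_fraction,
              e$fill_color))
  invisible(x)
}
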