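#' Assign within-group quartile points (1-4) to scored foods
#'
#' Within each food group, foods are split at the quartiles of their
#' NRF9.2 scores and assigned 1 point (lowest nutritional quality, bottom
#' quartile) to 4 points (highest). Cuts are the 25th/50th/75th sample
#' percentiles under the linear-interpolation rule
#' (`stats::quantile(type = 7)`); bins are left-open: score <= Q1 gives
#' 1, (Q1, Q2] gives 2, (Q2, Q3] gives 3, > Q3 gives 4. Tied scores share
#' a bin by value, so identical foods always get identical points (and if
#' all scores in a group are equal, every food gets 1). A group needs at
#' least 4 foods for quartiles to be meaningful.
#'
#' @param scores List of `nrf_score` objects (from [score_food()]).
#' @param groups Character vector of food groups, one per score (taken
#'   from `foods` if you pass the same order; must be supplied
#'   explicitly).
#' @return A data frame with columns `food_id`, `group`, `nrf92`,
#'   `points` (integer 1-4) and `q1`, `q2`, `q3` (the group's cut
#'   values), in the input order.
#' @export
#' @examples
#' foods <- generate_synthetic_foods(c(cereals = 8), seed = 42)
#' scores <- lapply(foods, score_food)
#' assign_quartile_points(scores, rep("cereals", 8))
assign_quartile_points <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  nrf <- vapply(scores, function(s) s$nrf92, numeric(1))
  ids <- vapply(scores, function(s) s$subject_id, character(1))
  small <- names(which(table(groups) < 4))
  if (length(small)) {
    stop("Quartile points need at least 4 foods per group; too few in: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(food_id = ids, group = groups, nrf92 = nrf,
                    points = NA_integer_, q1 = NA_real_, q2 = NA_real_,
                    q3 = NA_real_, stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    q <- stats::quantile(nrf[idx], probs = c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    out$q1[idx] <- q[1]; out$q2[idx] <- q[2]; out$q3[idx] <- q[3]
    out$points[idx] <- ifelse(nrf[idx] <= q[1], 1L,
                       ifelse(nrf[idx] <= q[2], 2L,
                       ifelse(nrf[idx] <= q[3], 3L, 4L)))
  }
  out
}

#' Diet-level point score
#'
#' Summarises a diet's quartile points as the energy-weighted mean of its
#' foods' points (weights = each entry's share of total diet energy),
#' matching the tool's premise of nutrition per calorie.
#'
#' @param diet A [day_diet()].
#' @param points A data frame as returned by [assign_quartile_points()]
#'   (or any data frame with `food_id` and `points` columns) covering
#'   every food in the diet.
#' @return A number in \[1, 4\].
#' @export
diet_point_score <- function(diet, points) {
  stopifnot(inherits(diet, "day_diet"))
  ids <- vapply(diet$entries, function(e) e$food$food_id, character(1))
  idx <- match(ids, points$food_id)
  if (anyNA(idx)) {
    stop("No point assignment for food(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  kcal <- vapply(diet$entries, function(e) {
    e$food$energy_kcal_100g * e$grams / 100
  }, numeric(1))
  if (sum(kcal) <= 0) stop("Diet has zero energy", call. = FALSE)
  sum(points$points[idx] * kcal) / sum(kcal)
}
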