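#' Nutrient adequacy ratio (NAR)
#'
#' NAR is the actual daily intake of a nutrient divided by its daily
#' reference intake (RNI/AI). Values above 1 indicate intake beyond the
#' reference; for the mean adequacy ratio each NAR is truncated at 1
#' first.
#'
#' @param intake Daily intake (>= 0), in the reference's unit.
#' @param reference Daily reference intake (> 0).
#' @return `intake / reference` at full precision. Round only for
#'   display (reports use 2 decimals).
#' @export
#' @examples
#' compute_nar(19.27, 25) # fiber, 0.77 at 2 dp
compute_nar <- function(intake, reference) {
  if (any(is.na(reference)) || any(reference <= 0)) {
    stop("Reference intake must be > 0", call. = FALSE)
  }
  if (any(is.na(intake)) || any(intake < 0)) {
    stop("Intake must be >= 0", call. = FALSE)
  }
  intake / reference
}

#' Mean adequacy ratio (MAR)
#'
#' The mean of the nutrient adequacy ratios, each truncated at 1, over a
#' fixed nutrient panel; a diet-quality summary in \[0, 1\].
#'
#' @param nars Named numeric vector of NARs (untruncated is fine; the
#'   truncation happens here).
#' @return `mean(pmin(nars, 1))` at full precision.
#' @export
#' @examples
#' compute_mar(c(a = 0.5, b = 1.5)) # 0.75
compute_mar <- function(nars) {
  if (length(nars) == 0) stop("MAR of an empty NAR set is undefined",
                              call. = FALSE)
  mean(pmin(nars, 1))
}

#' Full adequacy report for a one-day diet
#'
#' Computes daily intakes for every nutrient in the reference panel, the
#' per-nutrient NAR (raw and truncated at 1), the MAR, and which
#' nutrients fall short (raw NAR strictly below 1). A panel nutrient for
#' which the diet's foods carry no data at all gets NAR 0 with a warning.
#'
#' @param diet A [day_diet()].
#' @param refs An adequacy-reference set (15 nutrients); default
#'   `adequacy_table3`. Use `adequacy_table6_rni` to reproduce the
#'   worked-example diets (see [reference_sets]).
#' @return An `adequacy_report`: list with `nar` (raw ratios),
#'   `nar_truncated`, `mar`, `n_below_one`, `below_one` (nutrient ids
#'   with raw NAR < 1), `intakes`, `reference_set`.
#' @export
#' @examples
#' rep_ <- adequacy_report(demo_diet("high"),
#'                         load_reference_set("adequacy_table6_rni"))
#' round(rep_$mar, 2)
adequacy_report <- function(diet,
                            refs = load_reference_set("adequacy_table3")) {
  stopifnot(inherits(diet, "day_diet"),
            inherits(refs, "nutrient_reference_set"))
  if (refs$kind != "adequacy-reference") {
    stop("adequacy_report needs an adequacy-reference set (15 nutrients)",
         call. = FALSE)
  }
  panel <- names(refs$values)
  recorded <- unique(unlist(lapply(diet$entries,
                                   function(e) names(e$food$nutrients))))
  absent <- setdiff(panel, recorded)
  if (length(absent)) {
    warning("Diet carries no data for: ",
            paste(absent, collapse = ", "), "; NAR taken as 0",
            call. = FALSE)
  }
  intakes <- vapply(panel, function(n) total_nutrient_intake(diet, n),
                    numeric(1))
  nar <- compute_nar(intakes, refs$values)
  nar_trunc <- pmin(nar, 1)
  structure(
    list(
      nar = nar,
      nar_truncated = nar_trunc,
      mar = compute_mar(nar),
      n_below_one = sum(nar < 1),
      below_one = panel[nar < 1],
      intakes = intakes,
      reference_set = refs$name
    ),
    class = "adequacy_report"
  )
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat("<adequacy_report> refs: ", x$reference_set,
      sprintf("; MAR = %.2f; %d nutrient(s) with NAR < 1\n",
              x$mar, x$n_below_one), sep = "")
  units <- nutrient_unit(names(x$nar))
  for (n in names(x$nar)) {
    cat(sprintf("  %-12s intake %9.2f %-6s NAR %.2f%s\n", n,
                x$intakes[[n]], units[match(n, names(x$nar))],
                x$nar[[n]], if (x$nar[[n]] < 1) "  *" else ""))
  }
  invisible(x)
}

# Atwater energy conversion factors, kcal per gram
ATWATER_KCAL_PER_G <- c(protein = 4, fat = 9, carbohydrate = 4)

# recommended share of total energy per macronutrient
ENERGY_BANDS <- list(protein = c(0.10, 0.15), fat = c(0.20, 0.30),
                     carbohydrate = c(0.50, 0.65))

#' Macronutrient energy-supply profile
#'
#' Converts protein/fat/carbohydrate to energy and checks each
#' macronutrient's share of total energy against the recommended bands
#' (protein 10-15%, fat 20-30%, carbohydrate 50-65%). Pass either a
#' [day_diet()] (grams come from its nutrient totals), explicit `grams`,
#' or explicit `kcal` per macronutrient (e.g. values printed in a report
#' you are checking); grams are converted with the Atwater factors
#' 4/9/4 kcal/g.
#'
#' @param diet A [day_diet()], or `NULL` when `grams`/`kcal` is given.
#' @param grams Named vector with entries `protein`, `fat`,
#'   `carbohydrate` (g/day).
#' @param kcal Named vector with the same keys (kcal/day); takes
#'   precedence over `grams` for the energy split.
#' @return An `energy_profile`: list with `grams`, `kcal`, `ratio`
#'   (fractions of total energy), `total_kcal`, `bands`, `within_band`
#'   (logical per macronutrient).
#' @export
#' @examples
#' p <- energy_profile(grams = c(protein = 73.33, fat = 52.84,
#'                               carbohydrate = 229.4))
#' round(p$ratio * 100, 2)
energy_profile <- function(diet = NULL, grams = NULL, kcal = NULL) {
  keys <- names(ATWATER_KCAL_PER_G)
  if (!is.null(diet)) {
    stopifnot(inherits(diet, "day_diet"))
    grams <- vapply(keys, function(n) total_nutrient_intake(diet, n),
                    numeric(1))
  }
  if (is.null(kcal)) {
    if (is.null(grams)) {
      stop("Provide a diet, grams or kcal", call. = FALSE)
    }
    grams <- grams[keys]
    if (anyNA(grams)) {
      stop("grams must name protein, fat and carbohydrate", call. = FALSE)
    }
    names(grams) <- keys
    kcal <- grams * ATWATER_KCAL_PER_G
  } else {
    kcal <- kcal[keys]
    if (anyNA(kcal)) {
      stop("kcal must name protein, fat and carbohydrate", call. = FALSE)
    }
    names(kcal) <- keys
    if (is.null(grams)) grams <- kcal / ATWATER_KCAL_PER_G
    grams <- grams[keys]
    names(grams) <- keys
  }
  total <- sum(kcal)
  if (total <= 0) {
    stop("All macronutrients are zero; energy profile is undefined",
         call. = FALSE)
  }
  ratio <- kcal / total
  within <- vapply(keys, function(k) {
    ratio[[k]] >= ENERGY_BANDS[[k]][1] & ratio[[k]] <= ENERGY_BANDS[[k]][2]
  }, logical(1))
  structure(
    list(grams = grams, kcal = kcal, ratio = ratio, total_kcal = total,
         bands = ENERGY_BANDS, within_band = within),
    class = "energy_profile"
  )
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("<energy_profile> total %.2f kcal/day\n", x$total_kcal))
  for (k in names(x$ratio)) {
    cat(sprintf("  %-12s %7.2f g %8.2f kcal %6.2f%%  [%d-%d%%]%s\n",
                k, x$grams[[k]], x$kcal[[k]], 100 * x$ratio[[k]],
                100 * x$bands[[k]][1], 100 * x$bands[[k]][2],
                if (x$within_band[[k]]) "" else "  out of band"))
  }
  invisible(x)
}
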