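#' Construct a food composition record
#'
#' A food is described per 100 g edible portion: its energy density
#' (kcal/100 g) and nutrient content (registry units per 100 g). All
#' downstream scoring derives per-100-kcal amounts from these two.
#'
#' @param food_id Unique identifier string.
#' @param name Display name.
#' @param food_group One of the pagoda food groups (see
#'   [load_pagoda_layers()]) or `"composite"` for a diet-level aggregate
#'   pseudo-food.
#' @param energy_kcal_100g Energy density, kcal per 100 g edible portion
#'   (>= 0).
#' @param nutrients Named numeric vector, nutrient id (see
#'   [nutrient_registry()]) to amount per 100 g edible portion. Nutrients
#'   not listed are treated as absent (0).
#' @return A `food_composition` object.
#' @export
#' @examples
#' food_composition("oat1", "Rolled oats", "cereals", 367,
#'                  c(protein = 15, fiber = 9, iron = 4))
food_composition <- function(food_id, name, food_group, energy_kcal_100g,
                             nutrients = numeric()) {
  obj <- structure(
    list(
      food_id = as.character(food_id),
      name = as.character(name),
      food_group = as.character(food_group),
      energy_kcal_100g = as.numeric(energy_kcal_100g),
      nutrients = nutrients
    ),
    class = "food_composition"
  )
  validate_food(obj)
}

validate_food <- function(x) {
  if (!nzchar(x$food_id)) stop("food_id must be non-empty", call. = FALSE)
  allowed <- c(pagoda_groups(), "composite")
  if (!x$food_group %in% allowed) {
    stop("Food ", x$food_id, ": food_group ", deparse(x$food_group),
         " is not a pagoda food group (", paste(allowed, collapse = ", "),
         ")", call. = FALSE)
  }
  if (is.na(x$energy_kcal_100g) || x$energy_kcal_100g < 0) {
    stop("Food ", x$food_id, ": energy_kcal_100g must be >= 0",
         call. = FALSE)
  }
  if (length(x$nutrients)) {
    if (is.null(names(x$nutrients)) || any(!nzchar(names(x$nutrients)))) {
      stop("Food ", x$food_id, ": nutrients must be a named vector",
           call. = FALSE)
    }
    bad <- setdiff(names(x$nutrients), known_nutrients())
    if (length(bad)) {
      stop("Food ", x$food_id, ": unknown nutrient id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    neg <- names(x$nutrients)[!is.na(x$nutrients) & x$nutrients < 0]
    if (length(neg)) {
      stop("Food ", x$food_id, ": negative amount for ",
           paste(neg, collapse = ", "), call. = FALSE)
    }
    if (anyNA(x$nutrients)) {
      warning("Food ", x$food_id, ": missing nutrient value(s) for ",
              paste(names(x$nutrients)[is.na(x$nutrients)], collapse = ", "),
              "; treated as 0", call. = FALSE)
      x$nutrients[is.na(x$nutrients)] <- 0
    }
    x$nutrients <- as.numeric(x$nutrients) |>
      stats::setNames(names(x$nutrients))
    storage.mode(x$nutrients) <- "double"
  }
  x
}

# amount per 100 g, 0 when the nutrient is not recorded for this food
food_nutrient <- function(food, nutrient) {
  v <- food$nutrients[nutrient]
  ifelse(is.na(v), 0, v) |> unname()
}

#' @export
print.food_composition <- function(x, ...) {
  cat("<food_composition> ", x$food_id, " (", x$name, ", ", x$food_group,
      ")\n  energy: ", x$energy_kcal_100g, " kcal/100 g; ",
      length(x$nutrients), " nutrients recorded\n", sep = "")
  invisible(x)
}

#' Read and write food composition tables
#'
#' Supported formats, chosen by file extension:
#' * CSV (UTF-8, header row, dot decimal): columns `food_id`, `name`,
#'   `group`, `energy_kcal_100g`, then one column per nutrient named
#'   `<nutrient>_<unit>` with the registry unit as suffix (e.g.
#'   `protein_g`, `sodium_mg`, `vitamin_a_ug_re`). Unknown nutrient
#'   columns are rejected; empty nutrient cells are read as 0 with a
#'   warning (composition tables are routinely sparse).
#' * JSON: an array of objects with fields `food_id`, `name`,
#'   `food_group`, `energy_kcal_100g`, `nutrients` (object). JSON
#'   round-trips are lossless.
#'
#' @param path File path (`.csv` or `.json`).
#' @param foods A list of [food_composition()] objects.
#' @return `read_food_table` returns a named list of `food_composition`
#'   objects (names = food ids); `write_food_table` returns `path`
#'   invisibly.
#' @export
read_food_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  foods <- if (ext == "csv") .read_food_csv(path)
           else if (ext == "json") .read_food_json(path)
           else stop("Unsupported food table format: .", ext, call. = FALSE)
  ids <- vapply(foods, `[[`, "", "food_id")
  if (anyDuplicated(ids)) {
    stop("Duplicate food_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(foods, ids)
}

.nutrient_columns <- function() {
  reg <- nutrient_registry()
  stats::setNames(paste0(reg$nutrient, "_", reg$unit), reg$nutrient)
}

.read_food_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("food_id", "name", "group", "energy_kcal_100g")
  missing_cols <- setdiff(fixed, names(tab))
  if (length(missing_cols)) {
    stop("Food table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  nut_cols <- .nutrient_columns()
  extra <- setdiff(names(tab), c(fixed, unname(nut_cols)))
  if (length(extra)) {
    stop("Food table ", path, " has unknown nutrient column(s): ",
         paste(extra, collapse = ", "),
         ". Nutrient columns must be named <nutrient>_<unit>, e.g. ",
         "protein_g, sodium_mg.", call. = FALSE)
  }
  present <- nut_cols[nut_cols %in% names(tab)]
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    vals <- vapply(present, function(col) {
      v <- suppressWarnings(as.numeric(row[[col]]))
      if (!is.na(row[[col]]) && nzchar(trimws(as.character(row[[col]]))) &&
          is.na(v)) {
        stop("Food table ", path, ", row ", i, ", column ", col,
             ": not a number (", deparse(as.character(row[[col]])), ")",
             call. = FALSE)
      }
      v
    }, numeric(1))
    neg <- names(present)[!is.na(vals) & vals < 0]
    if (length(neg)) {
      stop("Food table ", path, ", row ", i, " (", row$food_id,
           "): negative value in column ",
           paste(present[neg], collapse = ", "), call. = FALSE)
    }
    if (anyNA(vals)) {
      warning("Food table ", path, ", row ", i, " (", row$food_id,
              "): missing value(s) for ",
              paste(names(present)[is.na(vals)], collapse = ", "),
              "; treated as 0", call. = FALSE)
      vals[is.na(vals)] <- 0
    }
    food_composition(row$food_id, row$name, row$group,
                     row$energy_kcal_100g,
                     stats::setNames(vals, names(present)))
  })
}

.read_food_json <- function(path) {
  arr <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(arr, function(rec) {
    food_composition(rec$food_id, rec$name, rec$food_group,
                     rec$energy_kcal_100g, unlist(rec$nutrients))
  })
}

#' @rdname read_food_table
#' @export
write_food_table <- function(foods, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- lapply(unname(foods), function(f) {
      list(food_id = f$food_id, name = f$name, food_group = f$food_group,
           energy_kcal_100g = f$energy_kcal_100g,
           nutrients = as.list(f$nutrients))
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext == "csv") {
    nut_cols <- .nutrient_columns()
    used <- sort(unique(unlist(lapply(foods, function(f) names(f$nutrients)))))
    rows <- lapply(unname(foods), function(f) {
      base <- data.frame(food_id = f$food_id, name = f$name,
                         food_group = f$food_group,
                         energy_kcal_100g = f$energy_kcal_100g,
                         stringsAsFactors = FALSE)
      for (n in used) base[[nut_cols[[n]]]] <- food_nutrient(f, n)
      base
    })
    tab <- do.call(rbind, rows)
    names(tab)[names(tab) == "food_group"] <- "group"
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    stop("Unsupported food table format: .", ext, call. = FALSE)
  }
  invisible(path)
}
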