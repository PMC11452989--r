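# small builders used across test files

make_food <- function(id, group = "cereals", energy = 100,
                      nutrients = numeric()) {
  food_composition(id, paste("Test", id), group, energy, nutrients)
}

# food whose every beneficial nutrient sits at 5% of its NRV per 100 kcal
# (energy density 100 kcal/100 g makes per-100 g == per-100 kcal),
# so NR9 = 9 x 5 = 45 by hand arithmetic
beneficial_5pct_food <- function(id = "b5") {
  nrv <- load_reference_set("nrf92_beneficial")$values
  make_food(id, energy = 100, nutrients = nrv * 0.05)
}

# independent quartile-points oracle: explicit sorting, hand-rolled
# linear-interpolation quantiles (h = (n-1)p + 1) and bin counting
brute_quartile_points <- function(values) {
  x <- sort(values)
  n <- length(x)
  qs <- vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    if (lo >= n) x[n] else x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }, numeric(1))
  vapply(values, function(v) {
    if (v <= qs[1]) 1L else if (v <= qs[2]) 2L else if (v <= qs[3]) 3L
    else 4L
  }, integer(1))
}
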