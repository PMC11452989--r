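main_selection <- function(seed = 2) {
  f <- generate_synthetic_foods(
    stats::setNames(rep(1, 11),
                    c("cereals", "vegetables", "fruits", "meat_poultry",
                      "eggs", "aquatic", "milk", "soybeans", "nuts",
                      "cooking_oil", "salt")), seed = seed)
  stats::setNames(f, vapply(f, `[[`, "", "food_group"))
}

entry_grams <- function(diet) {
  stats::setNames(vapply(diet$entries, `[[`, 0, "grams"),
                  vapply(diet$entries, function(e) e$food$food_group, ""))
}

test_that("pagoda diets carry exactly the recommended gram quantities", {
  d <- build_diet_from_pagoda(main_selection())
  g <- entry_grams(d)
  expect_equal(g[["cereals"]], 250)
  expect_equal(g[["vegetables"]], 450)
  expect_equal(g[["milk"]], 300)
  expect_equal(g[["soybeans"]], 15)
  expect_equal(g[["salt"]], 5)
  layers <- load_pagoda_layers()
  main <- layers[is.na(layers$parent_group), ]
  expect_equal(unname(g[main$food_group]), main$recommended_grams)

  # swapping one cereal for another never changes quantities
  sel2 <- main_selection(seed = 77)
  expect_equal(entry_grams(build_diet_from_pagoda(sel2)), g)
})

test_that("tubers substitute cereal quota at 75 g fresh per 15 g cereals", {
  tuber <- food_composition("pot", "Potato", "tubers", 77,
                            c(carbohydrate = 17, vitamin_c = 27))
  d <- build_diet_from_pagoda(main_selection(), tuber = tuber)
  g <- entry_grams(d)
  expect_equal(g[["tubers"]], 75)
  expect_equal(g[["cereals"]], 235)
})

test_that("missing layers and unsupported energy levels are rejected", {
  sel <- main_selection()
  expect_error(build_diet_from_pagoda(sel[names(sel) != "milk"]), "milk")
  expect_error(build_diet_from_pagoda(sel, energy_level_kcal = 1800),
               "2000")
  # a food offered for the wrong layer is caught
  bad <- sel
  bad$milk <- sel$cereals
  expect_error(build_diet_from_pagoda(bad), "cereals")
})

test_that("energy label state follows the preset comparison rule", {
  on_target <- energy_label_state(2000, 2000)
  expect_equal(on_target$state, "within")
  expect_equal(on_target$fill_color, "dark")

  # the 2002 kcal worked example reads as on target (+/-0.5% band)
  expect_equal(energy_label_state(2002, 2000)$state, "within")

  above <- energy_label_state(2362, 2000)
  expect_equal(above$state, "above")
  expect_equal(above$fill_color, "gray")
  expect_equal(above$fill_fraction, 0.181)

  below <- energy_label_state(1686, 2000)
  expect_equal(below$state, "below")
  expect_equal(below$fill_color, "white")
  expect_equal(below$fill_fraction, 0.157)

  expect_equal(energy_label_state(9000, 2000)$fill_fraction, 1)
  expect_error(energy_label_state(-5, 2000), ">= 0")
})

test_that("block colour fractions follow the fixed 1-4 point map", {
  sel <- main_selection()
  d <- build_diet_from_pagoda(sel)
  ids <- vapply(d$entries, function(e) e$food$food_id, "")

  for (p in 1:4) {
    pts <- data.frame(food_id = ids, points = rep(p, length(ids)))
    m <- render_model(d, pts)
    expect_equal(unique(m$layers$color_fraction),
                 c(`1` = 0.25, `2` = 0.5, `3` = 0.75, `4` = 1.0)[[as.character(p)]],
                 info = paste("points", p))
  }

  # a 1-point cereal colours the cereal blocks at 0.25
  pts <- data.frame(food_id = ids, points = rep(4L, length(ids)))
  pts$points[pts$food_id == sel$cereals$food_id] <- 1L
  m <- render_model(d, pts)
  expect_equal(m$layers$color_fraction[m$layers$food_group == "cereals"],
               0.25)
  expect_equal(m$layers$color_fraction[m$layers$food_group == "milk"], 1.0)

  expect_error(render_model(d, pts[-1, ]), "No point assignment")
})

test_that("render model is a pure function of its inputs", {
  d <- build_diet_from_pagoda(main_selection())
  ids <- vapply(d$entries, function(e) e$food$food_id, "")
  pts <- data.frame(food_id = ids, points = rep(c(1L, 2L, 3L, 4L),
                                                length.out = length(ids)))
  expect_identical(render_model(d, pts), render_model(d, pts))
})

test_that("SVG output is byte-deterministic with the documented geometry", {
  d <- build_diet_from_pagoda(main_selection())
  ids <- vapply(d$entries, function(e) e$food$food_id, "")
  pts <- data.frame(food_id = ids, points = rep(c(3L, 1L, 4L, 2L),
                                                length.out = length(ids)))
  m <- render_model(d, pts)
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  write_svg(m, p1)
  write_svg(m, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # one <g> per layer
  doc <- xml2::read_xml(p1)
  expect_length(xml2::xml_find_all(doc, "//*[@data-group]"),
                nrow(m$layers))

  # a 0.75-fraction block: coloured and light widths in ratio 3:1,
  # summing to the block width
  grp3 <- m$layers$food_group[m$layers$color_fraction == 0.75][1]
  node <- xml2::xml_find_first(doc, sprintf("//*[@id='layer-%s']", grp3))
  rects <- xml2::xml_find_all(node, ".//*")
  w <- as.numeric(xml2::xml_attr(rects, "width"))
  cls <- xml2::xml_attr(rects, "class")
  expect_equal(w[cls == "colored"][1] / w[cls == "light"][1], 3)
  expect_equal(w[cls == "colored"][1] + w[cls == "light"][1], 48)
})

test_that("a 13-layer model writes 13 layer groups and back-parses", {
  f13 <- generate_synthetic_foods(
    stats::setNames(rep(1, 13), load_pagoda_layers()$food_group), seed = 4)
  d <- day_diet(unname(f13), rep(100, 13))
  ids <- vapply(d$entries, function(e) e$food$food_id, "")
  pts <- data.frame(food_id = ids,
                    points = rep(1:4, length.out = 13))
  m <- render_model(d, pts)
  expect_equal(nrow(m$layers), 13)
  path <- withr::local_tempfile(fileext = ".svg")
  write_svg(m, path)
  back <- read_svg_fractions(path)
  expect_equal(as.vector(back),
               m$layers$color_fraction[match(names(back),
                                             m$layers$food_group)])
  expect_length(back, 13)
  expect_equal(attr(back, "energy_fill"),
               m$energy_label$fill_fraction, tolerance = 1e-6)
})
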