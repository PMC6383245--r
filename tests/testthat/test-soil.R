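soil_3x3 <- function(values = matrix(c(3, 9, 3, 7, 3, 5, 9, 7, 3), 3, 3)) {
  tiny_grid(values, kind = "categorical")
}

test_that("suitable classes are the distinct codes under the occurrences", {
  g <- soil_3x3()
  cells <- tibble::tibble(row = c(1, 3, 1), col = c(1, 1, 2))  # codes 3, 3, 7
  cls <- suitable_soil_classes(g, cells)
  expect_equal(cls$code, c(3L, 7L))

  one <- suitable_soil_classes(g, tibble::tibble(row = 1, col = 1))
  expect_equal(one$code, 3L)

  g$values[2, 2] <- NA
  expect_error(suitable_soil_classes(g, tibble::tibble(row = 2, col = 2)),
               class = "nichebox_error_empty_sample")
  expect_error(suitable_soil_classes(g, cells[0, ]), class = "nichebox_error_empty")
  cont <- tiny_grid(matrix(1.5, 2, 2))
  expect_error(suitable_soil_classes(cont, cells), class = "nichebox_error_soil")
})

test_that("labels attach to derived codes when provided", {
  cls <- suitable_soil_classes(soil_3x3(), tibble::tibble(row = c(1, 1), col = c(1, 2)),
                               labels = c("3" = "cambisols", "7" = "leptosols"))
  expect_equal(cls$label, c("cambisols", "leptosols"))
})

test_that("the soil mask marks member codes 1, others 0, nodata NA", {
  g <- tiny_grid(matrix(c(3, 9, 7, 3), 2, 2), kind = "categorical")
  m <- soil_mask(g, 3)
  expect_equal(m$values, matrix(c(1, 0, 0, 1), 2, 2))

  all_in <- soil_mask(g, c(3, 7, 9))
  expect_true(all(all_in$values == 1))
  none <- soil_mask(g, 999)
  expect_true(all(none$values == 0))

  g$values[1, 1] <- NA
  expect_true(is.na(soil_mask(g, 3)$values[1, 1]))
})

test_that("the climate mask selects classes, defaulting to class 0", {
  cls_grid <- tiny_grid(matrix(c(0, 1, 2, 0, NA, 3), 2, 3), kind = "categorical")
  map <- structure(list(grid = cls_grid, breaks = c(1, 2, 3), n_classes = 4L),
                   class = "nb_suitability")
  m <- climate_mask(map)
  expect_equal(as.vector(m$values), c(1, 0, 0, 1, NA, 0))
  expect_true(all(climate_mask(map, 0:3)$values == 1, na.rm = TRUE))
  expect_error(climate_mask(map, 7), class = "nichebox_error_classify")
})

test_that("mask intersection is the 1+1=2 overlay on all binary combinations", {
  combos <- expand.grid(a = c(0, 1), b = c(0, 1))
  a <- tiny_grid(matrix(combos$a, 2, 2), kind = "categorical")
  b <- tiny_grid(matrix(combos$b, 2, 2), kind = "categorical")
  out <- intersect_masks(a, b)
  expect_equal(as.vector(out$values), as.numeric(combos$a + combos$b == 2))
})

test_that("intersection is commutative, associative, idempotent on random masks", {
  rmask <- function(seed) {
    tiny_grid(matrix(withr::with_seed(seed, sample(c(0, 1), 36, TRUE)), 6, 6),
              kind = "categorical")
  }
  a <- rmask(1); b <- rmask(2); c <- rmask(3)
  expect_identical(intersect_masks(a, b)$values, intersect_masks(b, a)$values)
  expect_identical(intersect_masks(intersect_masks(a, b), c)$values,
                   intersect_masks(a, intersect_masks(b, c))$values)
  expect_identical(intersect_masks(a, a)$values, a$values)
  # contracting: result is a subset of both inputs
  out <- intersect_masks(a, b)
  expect_true(all(out$values <= a$values & out$values <= b$values))
})

test_that("nodata in either mask yields nodata, and misalignment errors", {
  a <- tiny_grid(matrix(c(1, NA, 1, 1), 2, 2), kind = "categorical")
  b <- tiny_grid(matrix(c(1, 1, NA, 1), 2, 2), kind = "categorical")
  out <- intersect_masks(a, b)
  expect_equal(as.vector(out$values), c(1, NA, NA, 1))

  shifted <- tiny_grid(matrix(1, 2, 2), cellsize = 2, kind = "categorical")
  expect_error(intersect_masks(a, shifted), class = "nichebox_error_misaligned")
  bad <- tiny_grid(matrix(c(0, 2, 1, 1), 2, 2), kind = "categorical")
  expect_error(intersect_masks(a, bad), class = "nichebox_error_soil")
})

test_that("the attribute filter is an all-attributes-in-range test", {
  s <- tiny_stack(2, nr = 4, nc = 4, seed = 6)
  cells <- tibble::tibble(row = c(1, 2, 3), col = c(1, 2, 3))
  m <- attribute_filter(s, cells)
  vals <- purrr::map(s$layers, ~ .x$values[cbind(cells$row, cells$col)])
  rng <- purrr::map(vals, range)
  manual <- matrix(1, 4, 4)
  for (j in 1:2) {
    manual <- manual * (s$layers[[j]]$values >= rng[[j]][1] &
                        s$layers[[j]]$values <= rng[[j]][2])
  }
  expect_equal(m$values, manual)
  # occurrence cells always pass their own filter
  expect_true(all(m$values[cbind(cells$row, cells$col)] == 1))
})

test_that("a single-attribute filter equals a 1-dim envelope zero-distance test", {
  g <- tiny_grid(matrix(stats::runif(16, 0, 10), 4, 4))
  s <- nb_stack(list(attr1 = g))
  cells <- tibble::tibble(row = c(2, 4), col = c(1, 3))
  m <- attribute_filter(s, cells)
  env <- envelope_fit(data.frame(attr1 = g$values[cbind(cells$row, cells$col)]))
  d <- envelope_distance(matrix(as.vector(g$values), ncol = 1), env)
  expect_equal(as.vector(m$values), as.numeric(d == 0))
})
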