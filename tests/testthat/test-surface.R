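make_surface_fixture <- function(seed = 20, nr = 20, nc = 20, n_layers = 3) {
  stack <- withr::with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(j) {
      tiny_grid(matrix(stats::runif(nr * nc, 0, 100), nr, nc))
    })
    nb_stack(layers, names = paste0("L", seq_len(n_layers)))
  })
  samp <- extract_values(stack, occ_at_cells(stack$layers[[1]],
                                             rows = c(3, 8, 15, 18),
                                             cols = c(2, 9, 11, 19)))
  list(stack = stack, env = envelope_fit(samp), samples = samp)
}

test_that("the distance surface equals cell-by-cell envelope distances", {
  f <- make_surface_fixture()
  surf <- distance_surface(f$stack, f$env)
  for (cell in list(c(1, 1), c(5, 7), c(20, 20), c(12, 3))) {
    p <- vapply(f$stack$layers, function(g) g$values[cell[1], cell[2]], 1)
    expect_equal(surf$grid$values[cell[1], cell[2]],
                 clamp_box_distance(p, f$env$lo, f$env$hi), tolerance = 1e-12)
  }
  expect_equal(surf$min_d, min(surf$grid$values))
  expect_equal(surf$max_d, max(surf$grid$values))
  expect_true(all(surf$grid$values >= 0))
})

test_that("fitting occurrence cells sit at distance zero on the surface", {
  f <- make_surface_fixture()
  surf <- distance_surface(f$stack, f$env)
  cells <- attr(f$samples, "cells")
  expect_true(all(surf$grid$values[cbind(cells$row, cells$col)] == 0))
})

test_that("an all-covering envelope yields an all-zero surface", {
  g <- tiny_grid(matrix(stats::runif(25, 0, 100), 5, 5))
  stack <- nb_stack(list(L = g))
  env <- envelope_fit(data.frame(L = c(0, 100)))
  surf <- distance_surface(stack, env)
  expect_true(all(surf$grid$values == 0))
})

test_that("nodata in any layer propagates to the surface", {
  f <- make_surface_fixture()
  f$stack$layers[[2]]$values[4, 6] <- NA
  stack <- nb_stack(f$stack$layers, names(f$stack))
  surf <- distance_surface(stack, f$env)
  expect_true(is.na(surf$grid$values[4, 6]))
  expect_equal(sum(is.na(surf$grid$values)), 1)
})

test_that("space and layer mismatches are hard errors", {
  f <- make_surface_fixture()
  std_env <- f$env
  attr(std_env, "space") <- "standardized"
  expect_error(distance_surface(f$stack, std_env), class = "nichebox_error_space")
  renamed <- nb_stack(f$stack$layers, names = c("A", "B", "C"))
  expect_error(distance_surface(renamed, f$env), class = "nichebox_error_mismatch")
})

test_that("classification uses equal-width bins over (0, max_d]", {
  # distances {0, 1, 2, 3, 4} with 3 classes -> breaks at 2 and 4
  g <- tiny_grid(matrix(c(0, 1, 2, 3, 4, NA), 2, 3))
  surf <- structure(list(grid = g, min_d = 0, max_d = 4, aggregate = "euclidean"),
                    class = "nb_distance_surface")
  cls <- classify_distance(surf, n_classes = 3)
  expect_equal(as.vector(cls$grid$values), c(0, 1, 1, 2, 2, NA))
  expect_equal(cls$breaks, c(2, 4))
  expect_identical(cls$grid$kind, "categorical")
})

test_that("class 0 is exactly the zero-distance set, for any class count", {
  f <- make_surface_fixture(seed = 44)
  surf <- distance_surface(f$stack, f$env)
  zero_set <- which(surf$grid$values == 0)
  for (k in c(2, 5, 9)) {
    cls <- classify_distance(surf, n_classes = k)
    expect_identical(which(cls$grid$values == 0), zero_set)
    # total, deterministic relabelling: every unmasked cell gets one class
    expect_identical(is.na(cls$grid$values), is.na(surf$grid$values))
    expect_true(all(cls$grid$values %in% 0:(k - 1), na.rm = TRUE))
  }
})

test_that("an all-zero surface collapses to a single class 0", {
  g <- tiny_grid(matrix(0, 3, 3))
  surf <- structure(list(grid = g, min_d = 0, max_d = 0, aggregate = "euclidean"),
                    class = "nb_distance_surface")
  cls <- classify_distance(surf, n_classes = 4)
  expect_true(all(cls$grid$values == 0))
})

test_that("explicit breaks override and must be sorted", {
  g <- tiny_grid(matrix(c(0, 0.5, 1.4, 2.7, 9, 3), 2, 3))
  surf <- structure(list(grid = g, min_d = 0, max_d = 9, aggregate = "euclidean"),
                    class = "nb_distance_surface")
  cls <- classify_distance(surf, breaks = c(1, 3))
  expect_equal(as.vector(cls$grid$values), c(0, 1, 2, 2, 2, 2))
  expect_error(classify_distance(surf, breaks = c(3, 1)),
               class = "nichebox_error_classify")
  expect_error(classify_distance(surf, n_classes = 1),
               class = "nichebox_error_classify")
})
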