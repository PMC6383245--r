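test_that("occurrence CSVs parse fully, keeping duplicate coordinates", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("species,longitude,latitude",
               "sp,10.5,45.2", "sp,11.0,44.0", "sp,11.0,44.0"), p)
  occ <- read_occurrences(p)
  expect_equal(nrow(occ), 3)            # dedup deferred to cell level
  expect_s3_class(occ, "nb_occurrences")

  writeLines(c("species,longitude,latitude", "sp,10,45", "sp,10,95"), p)
  expect_error(read_occurrences(p), regexp = "row\\(s\\) 2",
               class = "nichebox_error_coords")

  writeLines(c("a,b", "1,2"), p)
  expect_error(read_occurrences(p), class = "nichebox_error_format")
})

test_that("edge points follow the half-open floor convention, row 0 at top", {
  g <- tiny_grid(matrix(0, 4, 5))      # extent x [0,5], y [0,4]
  # exact top-left corner belongs to cell (1,1)
  expect_equal(as.list(cell_of(g, 0, 4)), list(row = 1L, col = 1L))
  # interior cell edge: x = 2 belongs to col 3, y = 2 belongs to row 3
  expect_equal(as.list(cell_of(g, 2, 2)), list(row = 3L, col = 3L))
  # bottom and right edges fall outside (half-open)
  expect_true(is.na(cell_of(g, 5, 2)$col))
  expect_true(is.na(cell_of(g, 2, 0)$row))
  # cell_of and cell_center are inverse on centers
  cc <- cell_center(g, 3, 4)
  expect_equal(as.list(cell_of(g, cc$longitude, cc$latitude)),
               list(row = 3L, col = 4L))
})

test_that("extract_values returns one ordered row per retained cell", {
  s <- tiny_stack(2, nr = 4, nc = 5)
  occ <- occ_at_cells(s$layers[[1]], rows = c(2, 3, 1), cols = c(2, 4, 5))
  m <- extract_values(s, occ)
  expect_equal(nrow(m), 3)
  expect_identical(names(m), c("L1", "L2"))
  # rows come back in input order with the right per-layer values
  expect_equal(m$L1, s$layers[[1]]$values[cbind(c(2, 3, 1), c(2, 4, 5))])
  expect_equal(m$L2, s$layers[[2]]$values[cbind(c(2, 3, 1), c(2, 4, 5))])
  expect_identical(attr(m, "space"), "raw")
})

test_that("single-layer single-point extraction reads the cell value", {
  g <- tiny_grid(matrix(0, 3, 3))
  g$values[2, 2] <- 7
  s <- nb_stack(list(only = g))
  m <- extract_values(s, occ_at_cells(g, 2, 2))
  expect_equal(m$only, 7)
})

test_that("cell dedup collapses, and dropped points are counted and warned", {
  s <- tiny_stack(2, nr = 4, nc = 5)
  g <- s$layers[[1]]
  two_same <- occ_at_cells(g, c(2, 2), c(3, 3))
  expect_equal(nrow(extract_values(s, two_same, dedup = TRUE)), 1)
  expect_equal(nrow(extract_values(s, two_same, dedup = FALSE)), 2)

  s$layers[[1]]$values[1, 1] <- NA      # nodata in one layer masks the cell
  mixed <- occ_at_cells(g, c(1, 2, 3), c(1, 2, 100))  # nodata, good, outside
  expect_warning(m <- extract_values(nb_stack(s$layers, names(s)), mixed),
                 class = "nichebox_warning_dropped_points")
  expect_equal(nrow(m), 1)
  drops <- attr(m, "dropped")
  expect_equal(unname(drops["out_of_extent"] + drops["nodata"] + nrow(m)),
               nrow(mixed))             # dropped + retained = input

  all_out <- occ_at_cells(g, 1, 1)      # only the nodata cell
  expect_error(suppressWarnings(extract_values(nb_stack(s$layers, names(s)), all_out)),
               class = "nichebox_error_empty_sample")
})

test_that("k distinct in-extent points yield exactly k rows across random draws", {
  s <- tiny_stack(3, nr = 10, nc = 10, seed = 5)
  for (seed in 1:5) {
    cells <- withr::with_seed(seed, {
      idx <- sample(100, 12)
      list(row = ((idx - 1) %% 10) + 1, col = ((idx - 1) %/% 10) + 1)
    })
    occ <- occ_at_cells(s$layers[[1]], cells$row, cells$col)
    expect_equal(nrow(extract_values(s, occ)), 12)
  }
})

test_that("out-of-range coordinates are rejected at construction", {
  expect_error(as_occurrences(data.frame(species = "x", longitude = 181,
                                         latitude = 0)),
               class = "nichebox_error_coords")
  expect_error(as_occurrences(data.frame(species = "x", longitude = 0,
                                         latitude = -91)),
               class = "nichebox_error_coords")
})
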