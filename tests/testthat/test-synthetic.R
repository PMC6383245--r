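test_that("landscapes are deterministic in the seed and vary across seeds", {
  a <- make_landscape(3, c(15, 12), smoothness = 2, seed = 5)
  b <- make_landscape(3, c(15, 12), smoothness = 2, seed = 5)
  c <- make_landscape(3, c(15, 12), smoothness = 2, seed = 6)
  expect_identical(purrr::map(a$layers, "values"), purrr::map(b$layers, "values"))
  expect_false(identical(a$layers[[1]]$values, c$layers[[1]]$values))
  expect_identical(names(a), c("BIO1", "BIO2", "BIO3"))
  expect_true(all(check_aligned(a)$aligned))
  expect_error(make_landscape(0), class = "nichebox_error_synth")
  expect_error(make_landscape(2, c(0, 5)), class = "nichebox_error_synth")
})

test_that("zero smoothness gives uncorrelated noise; smoothing adds correlation", {
  g0 <- make_landscape(1, c(200, 200), smoothness = 0, seed = 9)$layers[[1]]
  v <- g0$values
  r_lag1 <- stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  expect_lt(abs(r_lag1), 0.1)

  g5 <- make_landscape(1, c(200, 200), smoothness = 5, seed = 9)$layers[[1]]
  v5 <- g5$values
  r5 <- stats::cor(as.vector(v5[, -1]), as.vector(v5[, -ncol(v5)]))
  expect_gt(r5, 0.8)
})

test_that("soil layers hold exactly the requested contiguous codes", {
  s2 <- make_soil(c(12, 12), n_classes = 2, seed = 3)
  expect_setequal(unique(as.vector(s2$values)), c(1, 2))
  expect_identical(s2$kind, "categorical")

  expect_identical(make_soil(c(10, 10), 4, seed = 8)$values,
                   make_soil(c(10, 10), 4, seed = 8)$values)
  # every code appears at fixed seeds on a 10x10 or larger grid
  for (seed in 1:4) {
    s <- make_soil(c(10, 10), n_classes = 5, seed = seed)
    expect_setequal(unique(as.vector(s$values)), 1:5)
  }
  expect_error(make_soil(c(5, 5), 1), class = "nichebox_error_synth")
})

test_that("the truth mask is the brute-force envelope-and-soil test", {
  stack <- make_landscape(3, c(25, 25), smoothness = 3, seed = 2)
  soil <- make_soil(c(25, 25), 4, seed = 3)
  env <- quantile_envelope(stack, 0.2, 0.8)
  truth <- make_truth(stack, soil, env, suitable_codes = c(1, 2))
  manual <- matrix(NA_real_, 25, 25)
  for (r in 1:25) for (co in 1:25) {
    p <- vapply(stack$layers, function(g) g$values[r, co], 1)
    manual[r, co] <- as.numeric(all(p >= env$lo & p <= env$hi) &&
                                soil$values[r, co] %in% c(1, 2))
  }
  expect_equal(truth$true_mask$values, manual)

  everything <- quantile_envelope(stack, 0, 1)
  all_codes <- make_truth(stack, soil, everything, 1:4)
  expect_true(all(all_codes$true_mask$values == 1))
  expect_error(make_truth(stack, soil, envelope_fit(data.frame(a = 1)), 1),
               class = "nichebox_error_mismatch")
  empty <- make_truth(stack, soil, local({e <- everything; e$lo <- e$hi <- e$hi + 10; e}), 1:4)
  expect_true(all(empty$true_mask$values == 0))
})

test_that("sampled occurrences land only on truly suitable cells", {
  stack <- make_landscape(4, c(30, 30), smoothness = 3, seed = 7)
  soil <- make_soil(c(30, 30), 5, seed = 8)
  truth <- make_truth(stack, soil, quantile_envelope(stack, 0.15, 0.85), 1:3)
  occ <- sample_occurrences(truth, 25, seed = 4)
  expect_equal(nrow(occ), 25)
  cells <- cell_of(truth$true_mask, occ$longitude, occ$latitude)
  expect_true(all(truth$true_mask$values[cbind(cells$row, cells$col)] == 1))
  expect_identical(sample_occurrences(truth, 25, seed = 4)$longitude,
                   occ$longitude)

  n_suit <- sum(truth$true_mask$values == 1)
  all_of_them <- sample_occurrences(truth, n_suit, seed = 1)
  cells_all <- cell_of(truth$true_mask, all_of_them$longitude, all_of_them$latitude)
  expect_equal(nrow(dplyr::distinct(cells_all)), n_suit)  # each cell exactly once
  expect_warning(sample_occurrences(truth, n_suit + 10, seed = 1),
                 class = "nichebox_warning_oversample")
})

test_that("the fitted envelope nests inside the truth and tightens with n", {
  stack <- make_landscape(3, c(40, 40), smoothness = 3, seed = 10)
  soil <- make_soil(c(40, 40), 3, seed = 11)
  true_env <- quantile_envelope(stack, 0.2, 0.8)
  truth <- make_truth(stack, soil, true_env, 1:3)

  prev <- NULL
  for (n in c(10, 40, 120)) {
    occ <- sample_occurrences(truth, min(n, sum(truth$true_mask$values == 1)),
                              seed = 2)
    samp <- extract_values(stack, occ)
    fit <- envelope_fit(samp)
    expect_true(all(fit$lo >= true_env$lo - 1e-12))
    expect_true(all(fit$hi <= true_env$hi + 1e-12))
    if (!is.null(prev)) {   # adding samples never shrinks the envelope
      expect_true(all(fit$lo <= prev$lo + 1e-12))
      expect_true(all(fit$hi >= prev$hi - 1e-12))
    }
    prev <- fit
  }
})
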