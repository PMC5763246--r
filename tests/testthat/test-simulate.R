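test_that("null process yields an all-constant landscape", {
  cfg <- simulation_config(extent = c(60, 60), n_years = 3,
                           deforestation_rate_per_year = 0,
                           logging_block_fraction_per_year = 0,
                           initial_nonforest_fraction = 0, seed = 1)
  truth <- simulate_landscape(cfg)
  for (y in 1:3) {
    expect_true(all(unclass(truth$labels[[y]]) == 1L))
    expect_equal(sum(truth$disturbed[[y]]), 0)
    expect_identical(truth$fractions[[y]], truth$fractions[[1]])
  }
})

test_that("same seed reproduces the truth bit-identically", {
  cfg <- simulation_config(extent = c(80, 80), n_years = 3, seed = 11)
  t1 <- simulate_landscape(cfg)
  t2 <- simulate_landscape(cfg)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$fractions, t2$fractions)
  expect_identical(t1$decks, t2$decks)
})

test_that("deck ledger matches the rendered truth", {
  cfg <- simulation_config(extent = c(100, 100), n_years = 3,
                           logging_block_fraction_per_year = 0.3, seed = 5)
  truth <- simulate_landscape(cfg)
  dk <- truth$decks[[2]]
  expect_gt(nrow(dk), 0)
  soil <- truth$fractions[[2]][, , 1]
  expect_true(all(soil[cbind(dk$row, dk$col)] > 0.10))
  # every pixel the ledger recorded as a deck carries the deck feature code
  expect_true(all(truth$features[[2]][cbind(dk$row, dk$col)] == 1L))
})

test_that("fractions sum to one and labels are temporally consistent", {
  truth <- small_truth(seed = 3)
  for (y in seq_len(truth$n_years)) {
    s <- truth$fractions[[y]][, , 1] + truth$fractions[[y]][, , 2] +
      truth$fractions[[y]][, , 3]
    expect_equal(max(abs(s - 1)), 0, tolerance = 1e-12)
  }
  for (y in 2:truth$n_years) {
    prev_nf <- unclass(truth$labels[[y - 1]]) != 1L
    now <- unclass(truth$labels[[y]])
    # deforested never reverts to forest
    expect_true(all(now[prev_nf] == 0L))
    # new deforestation only on prior forest
    expect_true(all(unclass(truth$labels[[y - 1]])[now == 2L] == 1L))
  }
})

test_that("logging evidence decays after recovery_years", {
  cfg <- simulation_config(extent = c(100, 100), n_years = 5,
                           recovery_years = 2, seed = 9)
  truth <- simulate_landscape(cfg)
  feat2 <- truth$features[[2]] > 0L
  # features placed in year 2, still forest and not re-logged later
  persists <- feat2 &
    unclass(truth$labels[[4]]) == 1L &
    truth$features[[3]] == 0L & truth$features[[4]] == 0L
  expect_gt(sum(persists), 0)
  expect_true(all(truth$disturbed[[2]][persists]))
  expect_true(all(truth$disturbed[[3]][persists]))
  expect_false(any(truth$disturbed[[4]][persists]))
})

test_that("noiseless rendering is the exact mixing identity", {
  truth <- small_truth(seed = 2, n_years = 2)
  sc <- render_scene(truth, 2, noise_sd = 0)
  E <- truth$config$endmembers$spectra
  FR <- matrix(truth$fractions[[2]], prod(dim(sc$bands)[1:2]), 3)
  expected <- array(FR %*% t(E), dim(sc$bands))
  expect_equal(sc$bands, expected, tolerance = 1e-12)
  # a pure-vegetation pixel equals the vegetation endmember exactly
  pure <- mixture_scene(c(0, 1, 0), nr = 2, nc = 2)
  expect_equal(as.numeric(pure$bands[1, 1, ]),
               unname(E[, "vegetation"]), tolerance = 1e-12)
})

test_that("additive noise has the expected mean absolute deviation", {
  truth <- simulate_landscape(simulation_config(extent = c(100, 100),
                                                n_years = 2, seed = 4))
  clean <- render_scene(truth, 2, noise_sd = 0)
  noisy <- render_scene(truth, 2, noise_sd = 0.01, seed = 123)
  mad_obs <- mean(abs(noisy$bands - clean$bands))
  expect_equal(mad_obs, 0.01 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(extent = c(20, 20)), "50")
  expect_error(simulation_config(n_years = 1), "n_years")
  expect_error(simulation_config(deforestation_rate_per_year = 1.5), "rates")
  bad <- default_endmembers()
  bad[, 2] <- bad[, 1]   # linearly dependent spectra
  expect_error(simulation_config(endmember_spectra = bad), "rank")
})
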