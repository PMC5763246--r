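test_that("endmember identities and exact mixtures are recovered", {
  sc_soil <- mixture_scene(c(1, 0, 0))
  fx <- unmix(sc_soil, em_default)
  expect_equal(fraction_band(fx, "soil"), matrix(1, 4, 4), tolerance = 1e-9)
  sc_mix <- mixture_scene(c(0, 0.5, 0.5))
  fx <- unmix(sc_mix, em_default)
  expect_equal(fraction_band(fx, "soil"), matrix(0, 4, 4), tolerance = 1e-9)
  expect_equal(fraction_band(fx, "vegetation"), matrix(0.5, 4, 4),
               tolerance = 1e-9)
  expect_equal(fraction_band(fx, "shade"), matrix(0.5, 4, 4),
               tolerance = 1e-9)
  expect_lt(max(fx$residual_rms), 1e-9)
})

test_that("constrained solver matches the simplex grid-search oracle", {
  set.seed(101)
  n <- 300
  FR <- matrix(rexp(3 * n), 3)
  FR <- sweep(FR, 2, colSums(FR), "/")
  E <- em_default$spectra
  Y <- E %*% FR + matrix(rnorm(nrow(E) * n, 0, 0.01), nrow(E))
  sc <- scene(array(t(Y), c(1, n, nrow(E))))
  fx <- unmix(sc, em_default)
  est <- rbind(as.numeric(fx$fractions[, , 1]),
               as.numeric(fx$fractions[, , 2]),
               as.numeric(fx$fractions[, , 3]))
  oracle <- simplex_grid_oracle(Y, E, 0.01)
  expect_lt(max(abs(est - oracle)), 0.02)
  expect_lt(sqrt(mean((est - FR)^2)), 0.05)
  # noiseless recovery is exact
  Y0 <- E %*% FR
  fx0 <- unmix(scene(array(t(Y0), c(1, n, nrow(E)))), em_default)
  est0 <- rbind(as.numeric(fx0$fractions[, , 1]),
                as.numeric(fx0$fractions[, , 2]),
                as.numeric(fx0$fractions[, , 3]))
  expect_lt(max(abs(est0 - FR)), 1e-9)
})

test_that("constraint regimes behave as documented", {
  set.seed(5)
  FR <- matrix(rexp(3 * 50), 3)
  FR <- sweep(FR, 2, colSums(FR), "/")
  E <- em_default$spectra
  Y <- E %*% FR + matrix(rnorm(nrow(E) * 50, 0, 0.02), nrow(E))
  sc <- scene(array(t(Y), c(1, 50, nrow(E))))
  full <- unmix(sc, em_default, "full")
  s <- full$fractions[, , 1] + full$fractions[, , 2] + full$fractions[, , 3]
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-6)
  expect_true(all(full$fractions >= 0))
  sum1 <- unmix(sc, em_default, "sum1")
  s1 <- sum1$fractions[, , 1] + sum1$fractions[, , 2] + sum1$fractions[, , 3]
  expect_equal(max(abs(s1 - 1)), 0, tolerance = 1e-6)
  none <- unmix(sc, em_default, "none")
  # unconstrained least squares can never fit worse than the constrained fit
  expect_true(all(none$residual_rms <= full$residual_rms + 1e-12))
  clip <- unmix(sc, em_default, "clip")
  expect_true(all(clip$fractions >= 0 & clip$fractions <= 1))
  sc2 <- clip$fractions[, , 1] + clip$fractions[, , 2] +
    clip$fractions[, , 3]
  expect_equal(max(abs(sc2 - 1)), 0, tolerance = 1e-6)
})

test_that("unmixing rejects invalid configurations and propagates nodata", {
  sc <- mixture_scene(c(0.2, 0.6, 0.2))
  bad <- default_endmembers()
  bad[, 3] <- 0.5 * bad[, 1] + 0.5 * bad[, 2]
  expect_error(endmembers(bad), "rank")
  two_band <- scene(sc$bands[, , 1:2])
  expect_error(unmix(two_band, em_default), "bands")
  sc$bands[2, 2, 1] <- NA
  fx <- unmix(sc, em_default)
  expect_true(is.na(fx$fractions[2, 2, 1]))
  expect_false(anyNA(fx$fractions[1, 1, ]))
})

test_that("soil threshold masking respects the forest mask and threshold", {
  soil <- matrix(c(0.12, 0.0, 0.50, 0.10), 2, 2)
  fx <- structure(list(
    fractions = array(c(soil, 1 - soil, matrix(0, 2, 2)), c(2, 2, 3)),
    names = c("soil", "vegetation", "shade")), class = "lg_fractions")
  forest <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  flag <- soil_disturbance_mask(fx, forest, 0.10)
  expect_identical(flag, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_error(soil_disturbance_mask(fx, forest, 1.5), "threshold")
  # monotonicity: raising the threshold never flags more pixels
  thresholds <- seq(0.05, 0.6, by = 0.05)
  counts <- vapply(thresholds, function(th)
    sum(soil_disturbance_mask(fx, forest, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fraction profiles track the simulation truth ledger", {
  cfg <- simulation_config(extent = c(100, 100), n_years = 5,
                           recovery_years = 2, seed = 9)
  truth <- simulate_landscape(cfg)
  stacks <- lapply(1:5, function(y) {
    structure(list(fractions = truth$fractions[[y]],
                   names = c("soil", "vegetation", "shade")),
              class = "lg_fractions")
  })
  names(stacks) <- as.character(1:5)
  # a deck placed in year 3 that stays forest and un-relogged afterwards
  dk <- truth$decks[[3]]
  ok <- which(unclass(truth$labels[[5]])[cbind(dk$row, dk$col)] == 1L &
              truth$features[[4]][cbind(dk$row, dk$col)] == 0L &
              truth$features[[5]][cbind(dk$row, dk$col)] == 0L)
  expect_gt(length(ok), 0)
  px <- dk[ok[1], ]
  prof <- fraction_profile(stacks, px)
  expect_equal(nrow(prof), 5)
  expect_equal(prof$soil > 0.10, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # undisturbed forest pixel: constant low soil
  und <- which(unclass(truth$labels[[1]]) == 1L &
               Reduce(`&`, lapply(1:5, function(y) !truth$disturbed[[y]])) &
               unclass(truth$labels[[5]]) == 1L, arr.ind = TRUE)[1, ]
  prof2 <- fraction_profile(stacks, data.frame(row = und[1], col = und[2]))
  expect_true(all(prof2$soil < 0.10))
  expect_equal(length(unique(prof2$soil)), 1)
  # empty list and out-of-range coordinates
  expect_equal(nrow(fraction_profile(stacks, data.frame(row = integer(),
                                                        col = integer()))), 0)
  expect_error(fraction_profile(stacks, data.frame(row = 999, col = 1)),
               "index error")
})
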