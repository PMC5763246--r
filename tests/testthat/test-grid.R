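test_that("grid arithmetic, partial flags and stability hash", {
  g <- build_grid(c(100, 100), 300, 30)           # 3000 m x 3000 m
  expect_equal(c(g$n_cell_rows, g$n_cell_cols), c(10, 10))
  expect_equal(g$pixels_per_cell^2, 100)
  expect_false(any(g$partial))
  g2 <- build_grid(c(100, 101), 300, 30)          # 3010 m wide
  expect_true(all(g2$partial[, 11]))
  expect_false(any(g2$partial[, 1:10]))
  expect_error(build_grid(c(100, 100), 250, 30), "multiple")
  expect_identical(grid_hash(g), grid_hash(build_grid(c(100, 100), 300, 30)))
})

test_that("intensity classes follow the reporting breaks", {
  expect_equal(as.character(classify_intensity(
    c(0.03, 0.30, 0.0, 0.05, 0.005, 0.07, 0.60, 0.10, 0.50, 1.0))),
    c("VERY_LOW", "MEDIUM", "UNDISTURBED", "LOW", "UNDISTURBED", "LOW",
      "HIGH", "MEDIUM", "HIGH", "HIGH"))
  expect_error(classify_intensity(1.2), "value error")
})

test_that("cell assessment reproduces a hand-counted cell", {
  m <- matrix(1L, 10, 10)
  m[1:2, 1:10] <- 0L                     # 20 non-forest px
  cm <- classmap(m, year = 2001)
  dist <- matrix(FALSE, 10, 10)
  dist[3, 1:8] <- TRUE                   # 8 flagged forest px
  g <- build_grid(c(10, 10), 300, 30)
  a <- assess_cells(g, cm, dist)
  expect_equal(nrow(a), 1)
  expect_equal(a$n_forest, 80)
  expect_equal(a$n_nonforest, 20)
  expect_equal(a$n_disturbed, 8)
  expect_equal(a$intensity, 0.10)
  expect_equal(as.character(a$intensity_class), "MEDIUM")
  # degenerate all-non-forest cell
  a2 <- assess_cells(g, classmap(matrix(0L, 10, 10)), matrix(FALSE, 10, 10))
  expect_true(is.na(a2$intensity))
  expect_equal(as.character(a2$intensity_class), "NO_FOREST")
  # per-cell count conservation on a simulated map
  truth <- small_truth(seed = 13, n_years = 3)
  gg <- build_grid(truth$config$extent, 300, 30)
  aa <- assess_cells(gg, truth$labels[[3]], truth$disturbed[[3]])
  expect_true(all(aa$n_forest + aa$n_nonforest + aa$n_deforested_new ==
                    aa$n_pixels))
  expect_true(all(aa$n_disturbed <= aa$n_forest))
})

test_that("annual rates follow the definitional arithmetic", {
  # 1000 ha of forest, 17 ha newly deforested -> 1.7% per year
  nr <- 120; nc <- 100
  m1 <- matrix(0L, nr, nc)
  m1[, 1:93] <- 1L
  m1[1:40, 93] <- 0L                     # 11120 px ~ 1000.8 ha of forest
  sum_forest <- sum(m1 == 1L)
  m2 <- m1
  new_idx <- which(m1 == 1L)[seq_len(round(17 / 0.09))]   # 189 px = 17.01 ha
  m2[new_idx] <- 2L
  g <- build_grid(c(nr, nc), 300, 30)
  dist <- matrix(FALSE, nr, nc)
  a1 <- assess_cells(g, classmap(m1, 1), dist)
  a2 <- assess_cells(g, classmap(m2, 2), dist)
  r <- annual_rates(list(a1, a2), list(classmap(m1, 1), classmap(m2, 2)))
  expect_equal(r$forest_area_ha, sum_forest * 0.09)
  expect_equal(r$deforestation_rate, (189 * 0.09) / (sum_forest * 0.09))
  expect_equal(round(100 * r$deforestation_rate, 1), 1.7)
  # no change -> both rates zero
  r0 <- annual_rates(list(a1, a1), list(classmap(m1, 1), classmap(m1, 2)),
                     disturbance = list(dist, dist))
  expect_equal(r0$deforestation_rate, 0)
  expect_equal(r0$disturbance_rate_cell, 0)
  expect_equal(r0$disturbance_rate_px, 0)
})

test_that("change matrices cross-tabulate areas with conserved marginals", {
  m1 <- matrix(1L, 10, 10)               # all undisturbed forest
  m2 <- m1
  m2[1, 1:3] <- 2L                       # 3 px become disturbed forest
  cm <- change_matrix(m1, m2)
  expect_equal(cm["undisturbed forest", "disturbed forest"], 0.27)
  expect_equal(sum(cm), 9)               # 100 px x 0.09 ha
  ident <- change_matrix(m2, m2)
  expect_equal(sum(ident) - sum(diag(unclass(ident))), 0)
  # row sums equal date-1 class areas
  t1 <- sample(0:2, 400, replace = TRUE)
  t2 <- sample(0:2, 400, replace = TRUE)
  cmx <- change_matrix(matrix(t1, 20, 20), matrix(t2, 20, 20))
  expect_equal(unname(attr(cmx, "row_total")),
               as.numeric(table(factor(t1, 0:2))) * 0.09,
               tolerance = 1e-12)
  expect_error(change_matrix(m1, matrix(1L, 5, 5)), "alignment")
})

test_that("recurrence counts disturbance years for fully forested cells", {
  g <- build_grid(c(10, 30), 300, 30)    # 1 x 3 cells
  mk <- function(int3) {
    m <- classmap(matrix(1L, 10, 30))
    d <- matrix(FALSE, 10, 30)
    for (k in 1:3) {
      n <- round(int3[k] * 100)
      if (n > 0) d[, (k - 1) * 10 + seq_len(10)][seq_len(n)] <- TRUE
    }
    assess_cells(g, m, d)
  }
  # cell intensities over three years: c1 (0.08, 0.02, 0.12), c2 all 0
  a <- list(mk(c(0.08, 0, 0)), mk(c(0.02, 0, 0)), mk(c(0.12, 0, 0)))
  r <- recurrence(a, level = 0.05)
  expect_equal(r$n_disturbed_years, c(2L, 0L, 0L))
  # monotonicity in the level
  counts <- vapply(c(0.01, 0.05, 0.10, 0.5), function(lv)
    sum(recurrence(a, level = lv)$n_disturbed_years), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # a cell with any non-forest never qualifies when forest_only
  m <- matrix(1L, 10, 30); m[1, 1] <- 0L
  a2 <- list(assess_cells(g, classmap(m), matrix(FALSE, 10, 30)))
  expect_equal(nrow(recurrence(a2)), 2)
})

test_that("area summaries allocate forest to intensity classes", {
  g <- build_grid(c(10, 40), 300, 30)    # 4 cells
  m <- matrix(1L, 10, 40)
  m[, 31:40] <- 0L                       # cell 4 fully non-forest
  d <- matrix(FALSE, 10, 40)
  d[, 11:13] <- TRUE                     # cell 2: 30/100 -> MEDIUM
  d[1:6, 21] <- TRUE                     # cell 3: 6/100 -> LOW
  a <- assess_cells(g, classmap(m), d)
  s <- area_summary(a)
  expect_equal(sum(s$pct), 100, tolerance = 0.1)
  expect_equal(s$area_ha[s$class == "non-forest"], 100 * 0.09)
  expect_equal(s$area_ha[s$class == "medium"], 100 * 0.09)
  expect_equal(s$area_ha[s$class == "low"], 100 * 0.09)
  expect_equal(s$area_ha[s$class == "undisturbed"], 100 * 0.09)
  alt <- attr(s, "cell_allocation")
  expect_equal(sum(alt$pct), 100, tolerance = 0.1)
  # all-forest undisturbed landscape -> 100% undisturbed
  s0 <- area_summary(assess_cells(g, classmap(matrix(1L, 10, 40)),
                                  matrix(FALSE, 10, 40)))
  expect_equal(s0$pct[s0$class == "undisturbed"], 100)
})
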