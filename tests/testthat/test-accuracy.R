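# Reference-count fixtures for the published error matrices. The 2x2 binary
# matrix is printed in full; for the pooled 4-class matrix the diagonal,
# reference column totals and the High row are treated as authoritative (the
# printed off-diagonal cells are not fully marginal-consistent), and the
# remaining cells are a consistent completion.
matrix_3b <- function() {
  as_error_matrix(matrix(c(57, 18, 16, 134), 2, 2, byrow = TRUE,
                         dimnames = list(c("undisturbed", "disturbed"),
                                         c("undisturbed", "disturbed"))))
}
matrix_3a <- function() {
  m <- rbind(
    undisturbed = c(236, 51, 11, 2, 0),
    low         = c(58, 95, 39, 7, 0),
    medium      = c(12, 15, 103, 61, 8),
    high        = c(4, 8, 38, 149, 1))
  colnames(m) <- c("undisturbed", "low", "medium", "high", "non-forest")
  as_error_matrix(m)
}

test_that("binary error-matrix metrics reproduce the published figures", {
  met <- accuracy_metrics(matrix_3b())
  expect_equal(round(met$overall_pct, 1), 84.9)
  expect_equal(round(met$class_metrics$users_pct, 1), c(76.0, 89.3))
  expect_equal(round(met$class_metrics$producers_pct, 1), c(78.1, 88.2))
})

test_that("4-class pooled matrix metrics reproduce the published figures", {
  met <- accuracy_metrics(matrix_3a())
  # overall excludes the 9 non-forest reference units from the denominator
  expect_equal(round(met$overall_pct, 1), 65.6)
  cm <- met$class_metrics
  expect_equal(round(cm$users_pct[cm$class == "high"], 1), 74.5)
  expect_equal(round(cm$producers_pct[cm$class == "high"], 1), 68.0)
  expect_equal(sum(unclass(matrix_3a())["high", ]), 200)
})

test_that("identity matrices give 100% everywhere", {
  m <- as_error_matrix(diag(c(5, 7, 9)))
  met <- accuracy_metrics(m)
  expect_equal(met$overall_pct, 100)
  expect_equal(met$class_metrics$users_pct, rep(100, 3))
  expect_equal(met$class_metrics$producers_pct, rep(100, 3))
})

test_that("metrics are invariant under simultaneous class permutation", {
  m <- unclass(matrix_3a())[, 1:4]
  perm <- c(3, 1, 4, 2)
  m2 <- as_error_matrix(m[perm, perm])
  met1 <- accuracy_metrics(as_error_matrix(m))
  met2 <- accuracy_metrics(m2)
  expect_equal(met2$overall_pct, met1$overall_pct)
  expect_equal(met2$class_metrics$users_pct,
               met1$class_metrics$users_pct[perm])
  expect_equal(met2$class_metrics$producers_pct,
               met1$class_metrics$producers_pct[perm])
})

test_that("class collapse sums blocks and preserves sample totals", {
  m <- matrix_3a()
  mapping <- c(undisturbed = "undisturbed", low = "disturbed",
               medium = "disturbed", high = "disturbed")
  coll <- collapse_classes(m, mapping)
  expect_equal(sum(coll), sum(m))
  expect_equal(unclass(coll)["disturbed", "disturbed"],
               sum(unclass(m)[2:4, 2:4]))
  # merging the confusable disturbance levels raises overall accuracy to
  # the published binary level
  ov <- accuracy_metrics(coll)$overall_pct
  expect_gt(ov, accuracy_metrics(m)$overall_pct)
  expect_gt(ov, 84); expect_lt(ov, 86)
  # identity mapping leaves the matrix unchanged
  idm <- c(undisturbed = "undisturbed", low = "low", medium = "medium",
           high = "high")
  expect_equal(unclass(collapse_classes(m, idm)), unclass(m))
  expect_error(collapse_classes(m, mapping[-1]), "mapping")
})

test_that("stratified sampling draws the requested design reproducibly", {
  truth <- small_truth(seed = 17, n_years = 3)
  g <- build_grid(truth$config$extent, 300, 30)
  a <- assess_cells(g, truth$labels[[3]], truth$disturbed[[3]])
  merge <- c(VERY_LOW = "LOW")
  avail <- table(ifelse(as.character(a$intensity_class) == "VERY_LOW",
                        "LOW", as.character(a$intensity_class)))
  design <- c(UNDISTURBED = 20,
              LOW = as.integer(min(avail[["LOW"]], 15)),
              MEDIUM = as.integer(min(avail[["MEDIUM"]], 10)))
  s1 <- stratified_sample(a, design, seed = 4, merge = merge)
  s2 <- stratified_sample(a, design, seed = 4, merge = merge)
  expect_identical(s1, s2)
  expect_equal(as.vector(table(s1$map_class)[names(design)]),
               unname(design))
  expect_true(all(is.na(s1$reference)))
  expect_error(stratified_sample(a, c(HIGH = 5000), seed = 1),
               "sampling error")
})

test_that("error_matrix round-trips labelled samples", {
  set.seed(8)
  classes <- c("undisturbed", "low", "medium", "high")
  n <- 120
  samples <- data.frame(map_class = sample(classes, n, replace = TRUE))
  samples$reference <- ifelse(runif(n) < 0.7, samples$map_class,
                              sample(c(classes, "non-forest"), n,
                                     replace = TRUE))
  m <- error_matrix(samples, map_classes = classes)
  expect_equal(sum(m), n)
  expect_equal(nrow(m), 4)
  expect_true("non-forest" %in% colnames(m) ||
                all(samples$reference != "non-forest"))
  # perfectly labelled samples give 100% everywhere
  perfect <- data.frame(map_class = samples$map_class,
                        reference = samples$map_class)
  expect_equal(accuracy_metrics(error_matrix(perfect))$overall_pct, 100)
  samples$reference[3] <- NA
  expect_error(error_matrix(samples), "missing labels")
})
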