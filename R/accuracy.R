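#' Stratified random sample of map units
#'
#' Draws a uniform without-replacement sample within each map stratum,
#' reproducibly for a given seed. The canonical design for the disturbance
#' assessment is 75 units in the undisturbed-forest stratum and 50 per
#' disturbance class (low, medium, high; very low and low merged to low for
#' interpretability), per assessed year. The returned table carries an empty
#' reference-label column to be filled by an independent interpreter and can
#' be round-tripped as CSV.
#'
#' @param strata character/factor matrix (per-pixel or per-cell map classes)
#'   or a vector; or an [assess_cells()] table, in which case
#'   `intensity_class` defines the strata.
#' @param n_per_stratum named integer vector: units requested per stratum.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param merge optional named character vector renaming strata before
#'   sampling (e.g. `c(VERY_LOW = "LOW")`).
#' @return data.frame: unit, (cell_row/cell_col or index), map_class,
#'   reference (NA).
#' @export
stratified_sample <- function(strata, n_per_stratum, seed = 1L,
                              merge = NULL) {
  if (is.data.frame(strata)) {
    loc <- strata[, c("cell_row", "cell_col")]
    cls <- as.character(strata$intensity_class)
  } else if (is.matrix(strata)) {
    loc <- data.frame(cell_row = as.vector(row(strata)),
                      cell_col = as.vector(col(strata)))
    cls <- as.character(as.vector(strata))
  } else {
    loc <- data.frame(index = seq_along(strata))
    cls <- as.character(strata)
  }
  if (!is.null(merge)) {
    hit <- cls %in% names(merge)
    cls[hit] <- merge[cls[hit]]
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  picks <- NULL
  for (s in names(n_per_stratum)) {
    idx <- which(!is.na(cls) & cls == s)
    k <- n_per_stratum[[s]]
    if (length(idx) < k)
      stop(sprintf(
        "sampling error: stratum '%s' has %d units, %d requested",
        s, length(idx), k), call. = FALSE)
    picks <- c(picks, sort(sample(idx, k)))
  }
  out <- cbind(data.frame(unit = seq_along(picks)),
               loc[picks, , drop = FALSE],
               data.frame(map_class = cls[picks],
                          reference = NA_character_))
  rownames(out) <- NULL
  out
}

#' Error (confusion) matrix from labelled samples
#'
#' Cross-tabulates map against reference labels. Reference classes absent
#' from the map legend (e.g. units the interpreter called non-forest) appear
#' as extra columns after the map-class columns.
#'
#' @param samples data.frame with complete `map_class` and `reference`
#'   columns.
#' @param map_classes optional ordering of the map classes.
#' @return integer matrix of class `lg_errormatrix`, rows = map classes,
#'   columns = reference classes.
#' @export
error_matrix <- function(samples, map_classes = NULL) {
  bad <- is.na(samples$map_class) | is.na(samples$reference)
  if (any(bad))
    stop("data error: missing labels for units ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  mp <- as.character(samples$map_class)
  rf <- as.character(samples$reference)
  if (is.null(map_classes)) map_classes <- sort(unique(mp))
  extra <- setdiff(sort(unique(rf)), map_classes)
  tab <- table(factor(mp, levels = map_classes),
               factor(rf, levels = c(map_classes, extra)))
  as_error_matrix(unclass(as.matrix(tab)))
}

#' Build an error matrix directly from a count table
#'
#' @param counts numeric matrix of confusion counts; row names are map
#'   classes, column names reference classes (defaulting to the row names).
#' @return an `lg_errormatrix`.
#' @export
as_error_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("data error: counts must be non-negative integers", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("class_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- rownames(counts)[seq_len(ncol(counts))]
  structure(counts, class = c("lg_errormatrix", "matrix"))
}

#' @export
print.lg_errormatrix <- function(x, ...) {
  cat("<lg_errormatrix> rows = map, cols = reference\n")
  print(unclass(x))
  invisible(x)
}

#' Accuracy metrics of an error matrix
#'
#' User's accuracy (complement of commission error) is the diagonal count
#' over the full row total; producer's accuracy (complement of omission
#' error) the diagonal over the column total, for each map class. Overall
#' accuracy is the diagonal sum over the total of the columns that have a
#' map counterpart: units whose reference class has no map analogue (e.g.
#' non-forest among forest-only strata) stay in the matrix but are excluded
#' from the overall denominator. Values are percentages at full precision;
#' round only for report output.
#'
#' @param x an `lg_errormatrix`.
#' @return list with `class_metrics` (data.frame: class, n_map, n_ref,
#'   users_pct, producers_pct) and `overall_pct`.
#' @export
accuracy_metrics <- function(x) {
  stopifnot(inherits(x, "lg_errormatrix"), nrow(x) >= 1)
  m <- unclass(x)
  mapc <- rownames(m)
  refc <- colnames(m)
  common <- intersect(mapc, refc)
  rowtot <- rowSums(m)
  coltot <- colSums(m)
  diag_ct <- vapply(mapc, function(k)
    if (k %in% refc) m[k, k] else NA_real_, numeric(1))
  users <- ifelse(rowtot > 0, 100 * diag_ct / rowtot, NA_real_)
  producers <- vapply(mapc, function(k) {
    if (!k %in% refc || coltot[k] == 0) return(NA_real_)
    100 * m[k, k] / coltot[k]
  }, numeric(1))
  denom <- sum(coltot[common])
  overall <- if (denom > 0) 100 * sum(diag_ct[common], na.rm = TRUE) / denom
             else NA_real_
  list(class_metrics = data.frame(
         class = mapc, n_map = as.numeric(rowtot),
         n_ref = as.numeric(coltot[match(mapc, refc)]),
         users_pct = as.numeric(users),
         producers_pct = as.numeric(producers), row.names = NULL),
       overall_pct = overall)
}

#' Collapse error-matrix classes into superclasses
#'
#' Sums rows and columns according to a class-to-superclass mapping, e.g.
#' merging the disturbance levels into a binary undisturbed/disturbed
#' legend. Reference-only columns not covered by the mapping are preserved
#' (or dropped with `drop_unmapped = TRUE`); total sample count is preserved
#' whenever they are kept.
#'
#' @param x an `lg_errormatrix`.
#' @param mapping named character vector: old class -> superclass. Must
#'   cover every map class.
#' @param drop_unmapped drop reference-only columns absent from the mapping.
#' @return an `lg_errormatrix`.
#' @export
collapse_classes <- function(x, mapping, drop_unmapped = FALSE) {
  m <- unclass(x)
  if (!all(rownames(m) %in% names(mapping)))
    stop("configuration error: mapping does not cover map classes ",
         paste(setdiff(rownames(m), names(mapping)), collapse = ", "),
         call. = FALSE)
  sup_rows <- mapping[rownames(m)]
  sup_levels <- unique(unname(mapping))
  newm <- rowsum(m, group = sup_rows, reorder = FALSE)
  newm <- newm[match(intersect(sup_levels, rownames(newm)), rownames(newm)),
               , drop = FALSE]
  cn <- colnames(m)
  mapped <- cn %in% names(mapping)
  colgrp <- ifelse(mapped, mapping[cn], cn)
  newc <- t(rowsum(t(newm), group = colgrp, reorder = FALSE))
  ord <- c(intersect(sup_levels, colnames(newc)),
           setdiff(colnames(newc), sup_levels))
  newc <- newc[, ord, drop = FALSE]
  if (drop_unmapped)
    newc <- newc[, colnames(newc) %in% sup_levels, drop = FALSE]
  as_error_matrix(newc)
}
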