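#' Fixed reporting grid
#'
#' A regular grid of square cells (default 300 m, i.e. 10 x 10 Landsat
#' pixels) anchored at the raster origin. The cell size follows the average
#' spacing of logging decks (200-250 m) plus context; keeping the grid fixed
#' across all years is what makes disturbance dynamics comparable through
#' time. Edge cells that are not fully covered by the raster are flagged
#' partial and excluded from area statistics by default.
#'
#' @param extent `(rows, cols)` of the pixel raster.
#' @param cell_size_m cell edge in metres; must be a positive multiple of
#'   the pixel size.
#' @param pixel_size pixel edge in metres (default 30).
#' @return object of class `lg_grid`.
#' @export
build_grid <- function(extent, cell_size_m = 300, pixel_size = 30) {
  if (cell_size_m <= 0 || cell_size_m %% pixel_size != 0)
    stop("configuration error: cell size must be a positive multiple of ",
         "the pixel size", call. = FALSE)
  ppc <- as.integer(cell_size_m / pixel_size)
  nrows <- as.integer(extent[1]); ncols <- as.integer(extent[2])
  ncr <- as.integer(ceiling(nrows / ppc)); ncc <- as.integer(ceiling(ncols / ppc))
  partial <- matrix(FALSE, ncr, ncc)
  if (nrows %% ppc != 0) partial[ncr, ] <- TRUE
  if (ncols %% ppc != 0) partial[, ncc] <- TRUE
  structure(list(cell_size_m = cell_size_m, pixel_size = pixel_size,
                 pixels_per_cell = ppc, rows = nrows, cols = ncols,
                 n_cell_rows = ncr, n_cell_cols = ncc, partial = partial),
            class = "lg_grid")
}

#' @export
print.lg_grid <- function(x, ...) {
  cat(sprintf("<lg_grid> %d x %d cells of %g m (%d px/cell), %d partial\n",
              x$n_cell_rows, x$n_cell_cols, x$cell_size_m,
              x$pixels_per_cell^2, sum(x$partial)))
  invisible(x)
}

#' Stable textual fingerprint of a grid definition
#'
#' Used to assert that the same grid underlies every year of a run.
#' @param grid an [build_grid()] grid.
#' @return character scalar.
#' @export
grid_hash <- function(grid) {
  paste(grid$cell_size_m, grid$pixel_size, grid$rows, grid$cols,
        grid$n_cell_rows, grid$n_cell_cols, sep = "/")
}

cell_index <- function(grid) {
  cr <- (seq_len(grid$rows) - 1L) %/% grid$pixels_per_cell
  cc <- (seq_len(grid$cols) - 1L) %/% grid$pixels_per_cell
  outer(cr, cc, function(a, b) a + b * grid$n_cell_rows) + 1L
}

#' Classify disturbance intensity
#'
#' Maps a per-cell disturbance intensity (flagged disturbed pixels over
#' forest pixels) to the reporting classes: undisturbed [0, 1%), very low
#' [1%, 5%), low [5%, 10%), medium [10%, 50%), high [50%, 100%]. Intervals
#' are lower-inclusive/upper-exclusive except the high class, which includes
#' 0.5: a pixel-count ratio can hit 50/100 exactly and is assigned high.
#'
#' @param intensity numeric vector in [0, 1] (`NA` allowed, returned as
#'   `NA`).
#' @param breaks the four interior break points.
#' @return factor with levels UNDISTURBED, VERY_LOW, LOW, MEDIUM, HIGH.
#' @export
classify_intensity <- function(intensity,
                               breaks = c(0.01, 0.05, 0.10, 0.50)) {
  ok <- is.na(intensity) | (intensity >= 0 & intensity <= 1)
  if (!all(ok))
    stop("value error: intensity outside [0, 1]", call. = FALSE)
  cut(intensity, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c("UNDISTURBED", "VERY_LOW", "LOW", "MEDIUM", "HIGH"))
}

#' Per-cell pixel accounting for one date
#'
#' Counts forest, non-forest, new-deforestation and soil-flagged disturbed
#' pixels in every grid cell, computes the disturbance intensity
#' (disturbed / forest pixels; undefined where the cell holds no forest) and
#' assigns the intensity class (`NO_FOREST` for forest-free cells).
#'
#' @param grid an [build_grid()] grid.
#' @param cm an [classmap()] for the date.
#' @param disturbance logical matrix from [soil_disturbance_mask()].
#' @param year optional year label attached to the table.
#' @return data.frame with one row per cell.
#' @export
assess_cells <- function(grid, cm, disturbance, year = attr(cm, "year")) {
  m <- unclass(cm)
  if (!all(dim(m) == c(grid$rows, grid$cols)) ||
      !all(dim(disturbance) == dim(m)))
    stop("alignment error: rasters do not share the grid geometry",
         call. = FALSE)
  ci <- cell_index(grid)
  ncell <- grid$n_cell_rows * grid$n_cell_cols
  cnt <- function(mask) tabulate(ci[mask], nbins = ncell)
  n_pixels <- tabulate(ci, nbins = ncell)
  n_forest <- cnt(m == 1L)
  n_nonforest <- cnt(m == 0L)
  n_defor <- cnt(m == 2L)
  n_dist <- cnt(disturbance & m == 1L)
  intensity <- ifelse(n_forest > 0, n_dist / n_forest, NA_real_)
  cls <- as.character(classify_intensity(intensity))
  cls[n_forest == 0] <- "NO_FOREST"
  out <- data.frame(
    cell_row = rep(seq_len(grid$n_cell_rows), times = grid$n_cell_cols),
    cell_col = rep(seq_len(grid$n_cell_cols), each = grid$n_cell_rows),
    partial = as.vector(grid$partial),
    n_pixels = n_pixels, n_forest = n_forest, n_nonforest = n_nonforest,
    n_deforested_new = n_defor, n_disturbed = n_dist,
    intensity = intensity,
    intensity_class = factor(cls, levels = c("UNDISTURBED", "VERY_LOW",
                                             "LOW", "MEDIUM", "HIGH",
                                             "NO_FOREST")))
  attr(out, "year") <- year
  attr(out, "grid_hash") <- grid_hash(grid)
  attr(out, "pixel_area_ha") <- grid$pixel_size^2 / 1e4
  out
}

#' Annual deforestation and disturbance rates
#'
#' For each consecutive pair of dates: the deforestation rate is the area
#' newly deforested at `t` over the forest area at `t-1`; the disturbance
#' rate is the area newly flagged as disturbed over the same denominator.
#' "Newly disturbed" is computed at cell level (forest area of cells whose
#' intensity newly exceeds `level`) with a pixel-level variant (pixels
#' flagged at `t` but not at `t-1`) reported alongside when the pixel masks
#' are supplied. Rates are fractions per interval.
#'
#' @param assessments list of [assess_cells()] tables in date order.
#' @param masks list of [classmap()]s in the same order.
#' @param disturbance optional list of logical pixel masks for the
#'   pixel-level variant.
#' @param level cell reporting level for "disturbed" (default 0.05).
#' @return data.frame, one row per interval.
#' @export
annual_rates <- function(assessments, masks, disturbance = NULL,
                         level = 0.05) {
  stopifnot(length(assessments) >= 2, length(masks) == length(assessments))
  px_ha <- attr(assessments[[1]], "pixel_area_ha") %||% 0.09
  yrs <- names(assessments) %||% as.character(seq_along(assessments))
  out <- NULL
  for (t in 2:length(assessments)) {
    m0 <- unclass(masks[[t - 1]]); m1 <- unclass(masks[[t]])
    forest0_ha <- sum(m0 == 1L) * px_ha
    defor_ha <- sum(m1 == 2L) * px_ha
    a0 <- assessments[[t - 1]]; a1 <- assessments[[t]]
    newly <- !is.na(a1$intensity) & a1$intensity > level &
      (is.na(a0$intensity) | a0$intensity <= level)
    dist_cell_ha <- sum(a1$n_forest[newly]) * px_ha
    dist_px_ha <- NA_real_
    if (!is.null(disturbance)) {
      d0 <- disturbance[[t - 1]]; d1 <- disturbance[[t]]
      dist_px_ha <- sum(d1 & !d0 & m1 == 1L) * px_ha
    }
    if (forest0_ha == 0) {
      dr <- NA_real_; sr_cell <- NA_real_; sr_px <- NA_real_
    } else {
      dr <- defor_ha / forest0_ha
      sr_cell <- dist_cell_ha / forest0_ha
      sr_px <- dist_px_ha / forest0_ha
    }
    out <- rbind(out, data.frame(
      from = yrs[t - 1], to = yrs[t], forest_area_ha = forest0_ha,
      deforested_ha = defor_ha, deforestation_rate = dr,
      newly_disturbed_cell_ha = dist_cell_ha,
      disturbance_rate_cell = sr_cell,
      newly_disturbed_px_ha = dist_px_ha, disturbance_rate_px = sr_px,
      disturbance_to_deforestation =
        ifelse(!is.na(dr) & dr > 0, sr_cell / dr, NA_real_)))
  }
  rownames(out) <- NULL
  out
}

#' Combined land-cover + disturbance map for change trajectories
#'
#' Collapses a class map and a disturbance mask into the three transition
#' classes: `0` non-forest (including that date's new deforestation),
#' `1` undisturbed forest, `2` disturbed forest.
#'
#' @param cm an [classmap()].
#' @param disturbance logical matrix of flagged pixels.
#' @return integer matrix.
#' @export
combined_map <- function(cm, disturbance) {
  m <- unclass(cm)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m == 1L] <- 1L
  out[m == 1L & disturbance] <- 2L
  out
}

#' Land-cover change matrix between two dates
#'
#' Pixel-level cross-tabulation of the three transition classes
#' (non-forest, undisturbed forest, disturbed forest) between two dates,
#' expressed in hectares, with marginals. Row sums equal date-1 class areas
#' and the grand total the valid area.
#'
#' @param map_t1,map_t2 integer grids from [combined_map()].
#' @param pixel_area_ha pixel area (default 0.09 ha for 30 m pixels).
#' @return matrix of class `lg_changematrix` (rows = date 1, cols = date 2,
#'   hectares) with `row_total`/`col_total` attributes.
#' @export
change_matrix <- function(map_t1, map_t2, pixel_area_ha = 0.09) {
  if (!all(dim(map_t1) == dim(map_t2)))
    stop("alignment error: maps do not share geometry", call. = FALSE)
  labs <- c("non-forest", "undisturbed forest", "disturbed forest")
  f1 <- factor(as.vector(map_t1), levels = 0:2, labels = labs)
  f2 <- factor(as.vector(map_t2), levels = 0:2, labels = labs)
  tab <- table(t1 = f1, t2 = f2) * pixel_area_ha
  m <- unclass(as.matrix(tab))
  structure(m, row_total = rowSums(m), col_total = colSums(m),
            class = c("lg_changematrix", "matrix"))
}

#' @export
print.lg_changematrix <- function(x, ...) {
  cat("<lg_changematrix> area (ha), rows = date 1, cols = date 2\n")
  print(unclass(x))
  invisible(x)
}

#' Disturbance recurrence over a series
#'
#' For each qualifying grid cell, the number of assessed years in which its
#' disturbance intensity exceeded `level`. By default only cells that are
#' 100% forest (disturbed or not) in every assessed year qualify, so the
#' count reads as repeated disturbance of standing forest.
#'
#' @param assessments list of [assess_cells()] tables in date order.
#' @param level intensity level defining "disturbed" (default 0.05,
#'   i.e. the >5% reporting level).
#' @param forest_only restrict to always-100%-forest cells (default TRUE).
#' @return data.frame (cell_row, cell_col, n_disturbed_years) for
#'   qualifying cells, with a `distribution` attribute tabulating counts.
#' @export
recurrence <- function(assessments, level = 0.05, forest_only = TRUE) {
  stopifnot(length(assessments) >= 1)
  base <- assessments[[1]][, c("cell_row", "cell_col")]
  qual <- rep(TRUE, nrow(base))
  count <- rep(0L, nrow(base))
  for (a in assessments) {
    if (forest_only) qual <- qual & a$n_forest == a$n_pixels
    count <- count + as.integer(!is.na(a$intensity) & a$intensity > level)
  }
  out <- cbind(base[qual, , drop = FALSE],
               n_disturbed_years = count[qual])
  rownames(out) <- NULL
  attr(out, "distribution") <- table(out$n_disturbed_years)
  attr(out, "share_disturbed") <-
    if (nrow(out)) mean(out$n_disturbed_years >= 1) else NA_real_
  out
}

#' Landscape composition by disturbance class
#'
#' Percentage of the total area in each reporting class: each cell's
#' non-forest area (including new deforestation) goes to non-forest and its
#' forest area to the cell's intensity class. Partial edge cells are
#' excluded by default. A whole-cell allocation variant (each cell's full
#' area assigned to its class) is attached as attribute `cell_allocation`.
#'
#' @param assessment an [assess_cells()] table.
#' @param include_partial include partial edge cells (default FALSE).
#' @return data.frame (class, area_ha, pct); percentages sum to 100.
#' @export
area_summary <- function(assessment, include_partial = FALSE) {
  stopifnot(nrow(assessment) > 0)
  px_ha <- attr(assessment, "pixel_area_ha") %||% 0.09
  a <- if (include_partial) assessment else
    assessment[!assessment$partial, , drop = FALSE]
  classes <- c("non-forest", "undisturbed", "very low", "low", "medium",
               "high")
  area <- stats::setNames(numeric(6), classes)
  area["non-forest"] <- sum(a$n_nonforest + a$n_deforested_new) * px_ha
  keymap <- c(UNDISTURBED = "undisturbed", VERY_LOW = "very low",
              LOW = "low", MEDIUM = "medium", HIGH = "high")
  for (k in names(keymap)) {
    sel <- a$intensity_class == k
    area[keymap[k]] <- sum(a$n_forest[sel]) * px_ha
  }
  total <- sum(a$n_pixels) * px_ha
  out <- data.frame(class = classes, area_ha = as.numeric(area),
                    pct = 100 * as.numeric(area) / total)
  # whole-cell allocation: a cell's full area follows its intensity class
  cell_area <- stats::setNames(numeric(6), classes)
  cell_px <- a$n_pixels
  cell_area["non-forest"] <- sum(cell_px[a$intensity_class == "NO_FOREST"]) *
    px_ha
  for (k in names(keymap))
    cell_area[keymap[k]] <- sum(cell_px[a$intensity_class == k]) * px_ha
  attr(out, "cell_allocation") <- data.frame(
    class = classes, area_ha = as.numeric(cell_area),
    pct = 100 * as.numeric(cell_area) / total)
  out
}
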