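#' Segmentation parameter set
#'
#' Parameters of the bottom-up multiresolution region merging. `scale` is the
#' heterogeneity threshold: merging stops when the cheapest fusion cost
#' exceeds `scale^2`. `shape_weight` is the weight of shape heterogeneity
#' (colour weight is its complement); `compactness_weight` weights
#' compactness against smoothness inside the shape term. Reflectance is
#' multiplied by `value_scale` before computing heterogeneity so that the
#' conventional scale values used with 8-bit digital-number imagery (10 for
#' the base-year mask, 50 for the annual clearing update) keep their meaning
#' on [0, 1] reflectance data.
#'
#' @param scale positive heterogeneity threshold.
#' @param shape_weight shape weight in [0, 1] (colour weight = 1 - shape).
#' @param compactness_weight compactness weight in [0, 1].
#' @param bands band indices or names used for segmentation; default the
#'   red/NIR/SWIR triplet (bands 3, 4, 5 of a 6-band Landsat-style stack).
#' @param value_scale multiplier applied to reflectance before merging
#'   (default 255, the 8-bit convention).
#' @return list of class `lg_segparams`.
#' @export
segmentation_params <- function(scale = 10, shape_weight = 0.2,
                                compactness_weight = 0.5,
                                bands = c(3, 4, 5), value_scale = 255) {
  if (!is.numeric(scale) || scale <= 0)
    stop("configuration error: scale must be positive", call. = FALSE)
  if (shape_weight < 0 || shape_weight > 1 ||
      compactness_weight < 0 || compactness_weight > 1)
    stop("configuration error: weights must lie in [0, 1]", call. = FALSE)
  structure(list(scale = scale, shape_weight = shape_weight,
                 compactness_weight = compactness_weight, bands = bands,
                 value_scale = value_scale),
            class = "lg_segparams")
}

#' Multiresolution segmentation of a scene
#'
#' Iterative pairwise region merging minimising the combined colour/shape
#' heterogeneity increase, globally lowest-cost-first with deterministic
#' lowest-id tie-breaking; merging stops when the minimal fusion cost reaches
#' `scale^2`.
#'
#' @param x an [scene()].
#' @param params an [segmentation_params()].
#' @param mask optional logical matrix; `FALSE` pixels are excluded (id 0)
#'   and never merged across.
#' @return object of class `lg_segments`: integer id matrix (1..n, 0 outside
#'   mask) plus a per-segment attribute table.
#' @export
segment_multiresolution <- function(x, params = segmentation_params(),
                                    mask = NULL) {
  stopifnot(inherits(x, "lg_scene"))
  d <- dim(x$bands)
  bidx <- params$bands
  if (is.character(bidx)) bidx <- match(bidx, x$band_names)
  if (any(is.na(bidx)) || any(bidx < 1) || any(bidx > d[3]))
    stop("configuration error: segmentation band not present in scene",
         call. = FALSE)
  if (is.null(mask)) mask <- scene_valid(x)
  sub <- x$bands[, , bidx, drop = FALSE] * params$value_scale
  ids <- cpp_segment_mr(as.numeric(sub), d[1], d[2], length(bidx),
                        params$scale, 1 - params$shape_weight,
                        params$compactness_weight, mask)
  new_segments(ids, x, params)
}

#' Chessboard segmentation split along a thematic layer
#'
#' Regular square tiles of `tile_size` pixels, each split by the classes of a
#' thematic layer (typically the previous year's mask) so that every segment
#' is class-pure. Segment count is therefore always at least the tile count.
#'
#' @param x an [scene()] providing the extent (attributes are computed from
#'   it when given) or `NULL`.
#' @param tile_size tile edge in pixels (> 0).
#' @param thematic an [classmap()] or integer matrix; when `NULL` the tiling
#'   is pure.
#' @param extent `(rows, cols)` when `x` is `NULL`.
#' @return an `lg_segments`.
#' @export
segment_chessboard <- function(x = NULL, tile_size, thematic = NULL,
                               extent = NULL) {
  if (tile_size <= 0)
    stop("configuration error: tile_size must be positive", call. = FALSE)
  if (!is.null(x)) {
    d <- dim(x$bands)[1:2]
  } else {
    d <- extent
  }
  tr <- (seq_len(d[1]) - 1L) %/% tile_size
  tc <- (seq_len(d[2]) - 1L) %/% tile_size
  tile <- outer(tr, tc, function(a, b) a * (max(tc) + 1L) + b)
  key <- tile
  if (!is.null(thematic)) {
    th <- if (inherits(thematic, "lg_classmap")) unclass(thematic) else thematic
    stopifnot(all(dim(th) == d))
    key <- tile * (max(th, na.rm = TRUE) + 1L) + th
  }
  ids <- matrix(match(key, sort(unique(as.vector(key)))), d[1], d[2])
  new_segments(ids, x, list(algorithm = "chessboard", tile_size = tile_size))
}

new_segments <- function(ids, x = NULL, params = NULL,
                         fractions = NULL) {
  structure(list(ids = ids, params = params,
                 attributes = segment_attributes(ids, x, fractions)),
            class = "lg_segments")
}

#' @export
print.lg_segments <- function(x, ...) {
  cat(sprintf("<lg_segments> %d segments over %d x %d px\n",
              max(x$ids), nrow(x$ids), ncol(x$ids)))
  invisible(x)
}

#' Per-segment attribute table
#'
#' Computes area, per-band mean/sd, mean endmember fractions (when supplied)
#' and a bounding-box elongation index for every segment. These attributes
#' are the vocabulary available to classification rules.
#'
#' @param ids integer segment-id matrix (0 = outside mask).
#' @param x optional [scene()] for spectral attributes.
#' @param fractions optional `lg_fractions` for fraction attributes.
#' @param pixel_size pixel edge (m); taken from `x` when given.
#' @return data.frame keyed by `segment`.
#' @export
segment_attributes <- function(ids, x = NULL, fractions = NULL,
                               pixel_size = 30) {
  v <- as.vector(ids)
  keep <- v > 0L
  f <- factor(v[keep], levels = seq_len(max(v)))
  n <- as.vector(table(f))
  if (!is.null(x)) pixel_size <- x$pixel_size
  rows <- row(ids)[keep]; cols <- col(ids)[keep]
  rmin <- tapply(rows, f, min); rmax <- tapply(rows, f, max)
  cmin <- tapply(cols, f, min); cmax <- tapply(cols, f, max)
  h <- rmax - rmin + 1; w <- cmax - cmin + 1
  att <- data.frame(segment = seq_len(max(v)), n_pixels = n,
                    area_ha = n * pixel_size^2 / 1e4,
                    elongation = pmax(h, w) / pmin(h, w))
  grp_stats <- function(m, name) {
    vals <- as.vector(m)[keep]
    mu <- tapply(vals, f, mean)
    sdv <- tapply(vals, f, stats::sd)
    sdv[is.na(sdv)] <- 0
    out <- data.frame(mu, sdv)
    names(out) <- paste0(c("mean_", "sd_"), name)
    out
  }
  if (!is.null(x)) {
    for (b in seq_len(n_bands(x)))
      att <- cbind(att, grp_stats(x$bands[, , b], x$band_names[b]))
  }
  if (!is.null(fractions)) {
    for (k in seq_along(fractions$names))
      att <- cbind(att, grp_stats(fractions$fractions[, , k],
                                  fractions$names[k]))
  }
  rownames(att) <- NULL
  att
}
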