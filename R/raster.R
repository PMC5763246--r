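#' Lightweight in-memory raster scene
#'
#' A `lg_scene` holds a dated stack of co-registered reflectance bands as a
#' 3-D array `[row, col, band]` plus a minimal geotransform (upper-left
#' origin, square pixel size). Rows increase southward, matching the usual
#' north-up raster convention. All pipeline stages carry this geotransform
#' through unchanged.
#'
#' @param bands numeric 3-D array `[rows, cols, bands]`, or a matrix for a
#'   single band.
#' @param date scene date (`Date` or string coercible to one).
#' @param pixel_size pixel edge length in metres (default 30).
#' @param origin numeric length-2 `(x, y)` of the upper-left corner.
#' @param crs free-form projection identifier carried as metadata.
#' @param nodata sentinel value marking invalid pixels (default `NA`).
#' @param band_names optional character vector naming the bands.
#' @return An object of class `lg_scene`.
#' @export
scene <- function(bands, date = as.Date("2000-01-01"), pixel_size = 30,
                  origin = c(0, 0), crs = "local-metric", nodata = NA_real_,
                  band_names = NULL) {
  if (is.matrix(bands)) bands <- array(bands, dim = c(dim(bands), 1L))
  stopifnot(is.array(bands), length(dim(bands)) == 3L)
  if (is.null(band_names)) band_names <- paste0("band_", seq_len(dim(bands)[3]))
  stopifnot(length(band_names) == dim(bands)[3])
  structure(
    list(bands = bands, date = as.Date(date), pixel_size = pixel_size,
         origin = as.numeric(origin), crs = crs, nodata = nodata,
         band_names = band_names),
    class = "lg_scene")
}

#' @export
print.lg_scene <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<lg_scene> %s  %d x %d px, %d band(s), %g m pixels\n",
              format(x$date), d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' @export
dim.lg_scene <- function(x) dim(x$bands)

n_bands <- function(x) dim(x$bands)[3]

#' Extract one band as a matrix
#' @param x an `lg_scene`
#' @param band band index or name
#' @return numeric matrix
#' @export
scene_band <- function(x, band) {
  if (is.character(band)) band <- match(band, x$band_names)
  x$bands[, , band, drop = TRUE]
}

#' Valid-pixel mask of a scene
#'
#' A pixel is valid when every band is finite and differs from the nodata
#' sentinel.
#' @param x an `lg_scene`
#' @return logical matrix
#' @export
scene_valid <- function(x) {
  d <- dim(x$bands)
  ok <- matrix(TRUE, d[1], d[2])
  for (b in seq_len(d[3])) {
    bb <- x$bands[, , b]
    v <- is.finite(bb)
    if (!is.na(x$nodata)) v <- v & (bb != x$nodata)
    ok <- ok & v
  }
  ok
}

same_geometry <- function(a, b) {
  da <- dim(a$bands)[1:2]; db <- dim(b$bands)[1:2]
  all(da == db) && isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_geometry <- function(a, b, what = "scenes") {
  if (!same_geometry(a, b))
    stop(sprintf("alignment error: %s do not share shape/geotransform", what),
         call. = FALSE)
  invisible(TRUE)
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------
# One .asc file per band; a JSON sidecar records date, band names, crs.
# Kept deliberately minimal: the grid format is the interchange surface, the
# lg_scene object is the working container.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m numeric matrix (row 1 = northernmost row).
#' @param path output file path.
#' @param origin `(x, y)` of the upper-left corner in map units.
#' @param pixel_size cell size in map units.
#' @param nodata value written for `NA` cells.
#' @param digits significant digits written.
#' @export
write_asc <- function(m, path, origin = c(0, 0), pixel_size = 30,
                      nodata = -9999, digits = 7) {
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", origin[1]),
    sprintf("yllcorner %.10g", origin[2] - nr * pixel_size),
    sprintf("cellsize %.10g", pixel_size),
    sprintf("NODATA_value %.10g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `data` (matrix, `NA` for nodata), `origin`, `pixel_size`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  list(data = m, origin = origin, pixel_size = hdr$cellsize)
}

#' Write a scene to disk as ASCII grids plus a JSON sidecar
#'
#' @param x an `lg_scene`.
#' @param stem path stem; files are `<stem>_<band>.asc` and `<stem>.json`.
#' @export
write_scene <- function(x, stem) {
  paths <- character(n_bands(x))
  for (b in seq_len(n_bands(x))) {
    paths[b] <- paste0(stem, "_", x$band_names[b], ".asc")
    write_asc(x$bands[, , b], paths[b], origin = x$origin,
              pixel_size = x$pixel_size)
  }
  meta <- list(date = format(x$date), band_names = x$band_names,
               crs = x$crs, files = basename(paths))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Read a scene written by [write_scene()]
#' @param stem path stem used when writing.
#' @return an `lg_scene`.
#' @export
read_scene <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dirn <- dirname(stem)
  first <- read_asc(file.path(dirn, meta$files[1]))
  d <- dim(first$data)
  arr <- array(NA_real_, c(d, length(meta$files)))
  arr[, , 1] <- first$data
  for (b in seq_along(meta$files)[-1])
    arr[, , b] <- read_asc(file.path(dirn, meta$files[b]))$data
  scene(arr, date = meta$date, pixel_size = first$pixel_size,
        origin = first$origin, crs = meta$crs, band_names = meta$band_names)
}
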