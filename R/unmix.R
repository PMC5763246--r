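#' Endmember set for linear spectral mixture analysis
#'
#' Pure-cover reference spectra, one column per endmember, one row per band,
#' reflectance in [0, 1]. The canonical set for logging detection is
#' (soil, vegetation, shade).
#'
#' @param spectra numeric matrix, bands x endmembers.
#' @param names endmember names; defaults to the column names or
#'   `c("soil", "vegetation", "shade")`.
#' @return object of class `lg_endmembers`.
#' @export
endmembers <- function(spectra, names = NULL) {
  spectra <- as.matrix(spectra)
  if (is.null(names))
    names <- colnames(spectra) %||% c("soil", "vegetation", "shade")[
      seq_len(ncol(spectra))]
  stopifnot(length(names) == ncol(spectra))
  if (any(!is.finite(spectra)) || any(spectra < 0) || any(spectra > 1))
    stop("configuration error: endmember reflectance must be finite in [0,1]",
         call. = FALSE)
  if (qr(spectra)$rank < ncol(spectra))
    stop("configuration error: endmember matrix is rank-deficient ",
         "(spectra are linearly dependent)", call. = FALSE)
  colnames(spectra) <- names
  structure(list(spectra = spectra, names = names), class = "lg_endmembers")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read endmembers from a long-format CSV
#'
#' Columns: `endmember`, `band`, `reflectance`.
#' @param path CSV file path.
#' @return an `lg_endmembers`.
#' @export
read_endmembers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("endmember", "band", "reflectance") %in% names(df)))
  ems <- unique(df$endmember)
  bands <- sort(unique(df$band))
  spec <- matrix(NA_real_, length(bands), length(ems),
                 dimnames = list(NULL, ems))
  for (i in seq_len(nrow(df)))
    spec[match(df$band[i], bands), df$endmember[i]] <- df$reflectance[i]
  endmembers(spec, ems)
}

# Precompute the affine solution map (A, b) of the equality-constrained
# least-squares problem on one face of the simplex: minimise |E_S f - y|^2
# subject to sum(f) = 1, free endmembers S. The solution is f = A y + b,
# which lets the per-pixel solve become one matrix product over all pixels.
face_solver <- function(E) {
  k <- ncol(E)
  if (k == 1L) return(list(A = matrix(0, 1, nrow(E)), b = 1))
  G <- crossprod(E)
  K <- rbind(cbind(G, 1), c(rep(1, k), 0))
  Ki <- solve(K)
  list(A = Ki[seq_len(k), seq_len(k), drop = FALSE] %*% t(E),
       b = Ki[seq_len(k), k + 1L])
}

# Exact fully constrained least squares (sum-to-one + non-negativity) by
# enumeration of the simplex faces. The constrained optimum has some active
# set Z of zeroed fractions; restricted to the complement it solves the
# sum-to-one equality problem and is feasible there, so it appears among the
# enumerated candidates and is recovered as the feasible minimum-residual one.
# Vectorised: Y is bands x pixels; returns K x pixels fractions plus rss.
fcls_faces <- function(Y, E, tol = 1e-9) {
  K <- ncol(E); B <- nrow(E); N <- ncol(Y)
  best_rss <- rep(Inf, N)
  best_f <- matrix(NA_real_, K, N)
  yss <- colSums(Y^2)
  subsets <- unlist(lapply(seq_len(K), function(k)
    utils::combn(K, k, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    Es <- E[, S, drop = FALSE]
    fs <- face_solver(Es)
    FS <- fs$A %*% Y + fs$b            # |S| x N candidate fractions
    feas <- colSums(FS < -tol) == 0L
    if (!any(feas)) next
    Rfit <- Es %*% FS                  # fitted spectra
    rss <- yss - 2 * colSums(Rfit * Y) + colSums(Rfit^2)
    upd <- feas & (rss < best_rss - 1e-12)
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      blk <- matrix(0, K, sum(upd))
      blk[S, ] <- FS[, upd, drop = FALSE]
      best_f[, upd] <- blk
    }
  }
  best_f[best_f < 0] <- 0
  best_f <- sweep(best_f, 2, colSums(best_f), "/")
  list(fractions = best_f, rss = pmax(best_rss, 0))
}

#' Linear spectral mixture analysis of a scene
#'
#' Decomposes each pixel spectrum into fractional abundances of the
#' endmembers under a linear mixing model. The default regime enforces both
#' the sum-to-one and non-negativity constraints (fully constrained least
#' squares, solved exactly by simplex-face enumeration); `"sum1"` enforces
#' only the sum constraint, `"none"` is plain least squares, and `"clip"`
#' clips the unconstrained solution to [0, 1] and renormalises — the latter
#' modes exist for sensitivity checks.
#'
#' @param x an [scene()] with at least as many bands as endmembers.
#' @param em an [endmembers()] set whose band count matches the scene.
#' @param constraints one of `"full"` (default), `"sum1"`, `"none"`, `"clip"`.
#' @return object of class `lg_fractions`: fraction array
#'   `[row, col, endmember]`, per-pixel residual RMS, constraint flags.
#' @export
unmix <- function(x, em, constraints = c("full", "sum1", "none", "clip")) {
  constraints <- match.arg(constraints)
  stopifnot(inherits(x, "lg_scene"), inherits(em, "lg_endmembers"))
  E <- em$spectra
  d <- dim(x$bands)
  if (d[3] < ncol(E))
    stop("configuration error: fewer bands than endmembers", call. = FALSE)
  if (nrow(E) != d[3])
    stop("configuration error: endmember band count does not match scene",
         call. = FALSE)
  valid <- scene_valid(x)
  Y <- t(matrix(x$bands, d[1] * d[2], d[3]))   # bands x pixels
  vi <- which(as.vector(valid))
  K <- ncol(E)
  frac <- matrix(NA_real_, K, d[1] * d[2])
  rss <- rep(NA_real_, d[1] * d[2])
  if (length(vi)) {
    Yv <- Y[, vi, drop = FALSE]
    if (constraints == "full") {
      sol <- fcls_faces(Yv, E)
      frac[, vi] <- sol$fractions
      rss[vi] <- sol$rss
    } else {
      if (constraints == "sum1") {
        fs <- face_solver(E)
        Fv <- fs$A %*% Yv + fs$b
      } else {
        Fv <- solve(crossprod(E), t(E) %*% Yv)
      }
      if (constraints == "clip") {
        Fv[Fv < 0] <- 0; Fv[Fv > 1] <- 1
        s <- colSums(Fv); s[s == 0] <- 1
        Fv <- sweep(Fv, 2, s, "/")
      }
      Rfit <- E %*% Fv
      frac[, vi] <- Fv
      rss[vi] <- colSums((Rfit - Yv)^2)
    }
  }
  arr <- array(t(frac), c(d[1], d[2], K))
  structure(
    list(fractions = arr, names = em$names,
         residual_rms = matrix(sqrt(rss / d[3]), d[1], d[2]),
         constraints = constraints,
         sum_to_one = constraints %in% c("full", "sum1", "clip"),
         non_negative = constraints %in% c("full", "clip")),
    class = "lg_fractions")
}

#' @export
print.lg_fractions <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("<lg_fractions> %d x %d px, endmembers: %s (constraints: %s)\n",
              d[1], d[2], paste(x$names, collapse = ", "), x$constraints))
  invisible(x)
}

#' Extract one fraction image as a matrix
#' @param x an `lg_fractions`
#' @param name endmember name or index
#' @return numeric matrix of fractions
#' @export
fraction_band <- function(x, name) {
  if (is.character(name)) name <- match(name, x$names)
  x$fractions[, , name, drop = TRUE]
}

#' Flag within-forest disturbance evidence from the soil fraction
#'
#' A pixel is flagged as logging evidence when it lies inside the forest
#' mask and its soil fraction meets the threshold (inclusive). Pixels outside
#' the mask are never flagged, whatever their soil fraction: clearings are
#' deforestation, not disturbance.
#'
#' @param fractions an `lg_fractions` from [unmix()].
#' @param forest logical matrix (`TRUE` = forest) or an [classmap()] whose
#'   `FOREST` pixels define the mask.
#' @param threshold soil-fraction threshold in (0, 1); default 0.10, the
#'   empirical value for Landsat-scale logging infrastructure.
#' @return logical matrix of flagged pixels.
#' @export
soil_disturbance_mask <- function(fractions, forest, threshold = 0.10) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie in (0, 1)", call. = FALSE)
  if (inherits(forest, "lg_classmap")) forest <- unclass(forest) == 1L
  soil <- fraction_band(fractions, "soil")
  if (!all(dim(soil) == dim(forest)))
    stop("alignment error: fraction and mask shapes differ", call. = FALSE)
  flag <- !is.na(soil) & soil >= threshold
  flag & forest
}

#' Temporal soil-fraction profiles at selected pixels
#'
#' Tidy table of per-year endmember fractions at listed pixel coordinates,
#' for threshold tuning and QA plots of key areas (undisturbed forest,
#' logged forest, cleared areas).
#'
#' @param stacks named list of `lg_fractions`, one per year (names = years).
#' @param pixels data.frame or matrix with columns `row`, `col` (1-based).
#' @return data.frame with columns year, row, col and one column per
#'   endmember fraction.
#' @export
fraction_profile <- function(stacks, pixels) {
  pixels <- as.data.frame(pixels)
  if (nrow(pixels) == 0)
    return(data.frame(year = character(), row = integer(), col = integer()))
  d <- dim(stacks[[1]]$fractions)
  if (any(pixels$row < 1 | pixels$row > d[1] |
          pixels$col < 1 | pixels$col > d[2]))
    stop("index error: pixel coordinate outside raster", call. = FALSE)
  out <- do.call(rbind, lapply(names(stacks), function(yr) {
    fs <- stacks[[yr]]
    vals <- sapply(seq_along(fs$names), function(k)
      fs$fractions[cbind(pixels$row, pixels$col, k)])
    vals <- matrix(vals, nrow = nrow(pixels))
    colnames(vals) <- fs$names
    cbind(data.frame(year = yr, row = pixels$row, col = pixels$col), vals)
  }))
  rownames(out) <- NULL
  out
}
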