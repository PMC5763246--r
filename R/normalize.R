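#' Select pseudo-invariant features between two scenes
#'
#' Pseudo-invariant features (PIFs) are pixels whose spectra are temporally
#' stable, used to fit a per-band linear transform that aligns the radiometry
#' of a target scene to a reference. Candidates are pixels valid in both
#' scenes, outside an optional change mask, lying in the lowest
#' `quantile` of summed absolute band differences after a coarse per-band
#' gain guess (median ratio) removes bulk brightness offsets.
#'
#' @param reference,target co-registered [scene()]s of identical shape.
#' @param quantile fraction of candidate pixels kept (default 0.10).
#' @param change_mask optional logical matrix; `TRUE` pixels are excluded.
#' @param min_pif minimum acceptable PIF count (default 100).
#' @return logical matrix, `TRUE` at PIF pixels, with attribute `n`.
#' @export
select_pif <- function(reference, target, quantile = 0.10,
                       change_mask = NULL, min_pif = 100) {
  stop_geometry(reference, target)
  valid <- scene_valid(reference) & scene_valid(target)
  if (!is.null(change_mask)) valid <- valid & !change_mask
  if (!any(valid))
    stop("normalization error: no valid overlapping pixels", call. = FALSE)
  d <- dim(reference$bands)
  diffsum <- matrix(0, d[1], d[2])
  for (b in seq_len(d[3])) {
    rb <- reference$bands[, , b]; tb <- target$bands[, , b]
    g <- stats::median(rb[valid]) / max(stats::median(tb[valid]), 1e-12)
    diffsum <- diffsum + abs(rb - g * tb)
  }
  # identical scenes: every valid pixel is trivially invariant
  if (max(diffsum[valid]) < 1e-12) {
    pif <- valid
  } else {
    cut <- stats::quantile(diffsum[valid], quantile, names = FALSE)
    pif <- valid & diffsum <= cut
  }
  n <- sum(pif)
  if (n < min_pif)
    stop(sprintf(
      "normalization error: only %d PIF pixels selected (min %d)", n, min_pif),
      call. = FALSE)
  attr(pif, "n") <- n
  pif
}

#' Normalize a target scene to a reference over PIF pixels
#'
#' Per band, fits `reference = gain * target + offset` by ordinary least
#' squares over the PIF pixels and applies the transform to the whole target
#' scene. Optionally iterates with outlier trimming at 2.5 MAD of the fit
#' residuals, for robustness to PIFs that did in fact change.
#'
#' @param target,reference co-registered [scene()]s.
#' @param pif logical PIF matrix from [select_pif()].
#' @param robust_trim if `TRUE`, one re-fit after trimming residuals beyond
#'   2.5 MAD (default `FALSE`: plain OLS).
#' @return list with `scene` (the normalized target) and `model` (class
#'   `lg_normmodel`: per-band gain, offset, r2, n).
#' @export
normalize_to_reference <- function(target, reference, pif,
                                   robust_trim = FALSE) {
  stop_geometry(reference, target)
  if (sum(pif) < 3)
    stop("normalization error: empty or near-empty PIF set", call. = FALSE)
  d <- dim(target$bands)
  out <- target$bands
  model <- data.frame(band = target$band_names, gain = NA_real_,
                      offset = NA_real_, r2 = NA_real_, n = NA_integer_)
  for (b in seq_len(d[3])) {
    xv <- target$bands[, , b][pif]
    yv <- reference$bands[, , b][pif]
    keep <- is.finite(xv) & is.finite(yv)
    xv <- xv[keep]; yv <- yv[keep]
    if (stats::sd(xv) < 1e-12)
      stop(sprintf(
        "normalization error: target band '%s' constant over PIFs",
        target$band_names[b]), call. = FALSE)
    fit <- stats::lm.fit(cbind(1, xv), yv)
    if (robust_trim) {
      r <- fit$residuals
      s <- stats::mad(r)
      if (s > 0) {
        keep2 <- abs(r) <= 2.5 * s
        if (sum(keep2) >= 3) {
          xv <- xv[keep2]; yv <- yv[keep2]
          fit <- stats::lm.fit(cbind(1, xv), yv)
        }
      }
    }
    gain <- fit$coefficients[2]; offset <- fit$coefficients[1]
    if (!is.finite(gain) || gain <= 0)
      stop(sprintf(
        "normalization error: non-positive or singular gain for band '%s'",
        target$band_names[b]), call. = FALSE)
    sst <- sum((yv - mean(yv))^2)
    r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
    model$gain[b] <- gain; model$offset[b] <- offset
    model$r2[b] <- r2; model$n[b] <- length(xv)
    band <- target$bands[, , b] * gain + offset
    out[, , b] <- band
  }
  sc <- target
  sc$bands <- out
  list(scene = sc,
       model = structure(list(coefficients = model, pif_n = sum(pif)),
                         class = "lg_normmodel"))
}

#' @export
print.lg_normmodel <- function(x, ...) {
  cat(sprintf("<lg_normmodel> %d PIF pixels\n", x$pif_n))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Write a normalization model as JSON
#' @param model an `lg_normmodel`.
#' @param path output path.
#' @export
write_normmodel <- function(model, path) {
  jsonlite::write_json(model$coefficients, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
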