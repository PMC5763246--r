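#' Annual land-cover class map
#'
#' Per-pixel integer codes for one date: `0 = NONFOREST`, `1 = FOREST`,
#' `2 = DEFORESTED_NEW` (forest at the previous date, cleared by this one).
#' `DEFORESTED_NEW` pixels become `NONFOREST` at the following date; regrowth
#' is never mapped, so the non-forest domain grows monotonically through the
#' series.
#'
#' @param codes integer matrix of class codes.
#' @param year label for the date (integer year or string).
#' @return object of class `lg_classmap` (an integer matrix with attributes).
#' @export
classmap <- function(codes, year = NA) {
  stopifnot(is.matrix(codes))
  storage.mode(codes) <- "integer"
  bad <- stats::na.omit(unique(as.vector(codes)))
  if (length(setdiff(bad, c(0L, 1L, 2L))) > 0)
    stop("class codes must be 0 (NONFOREST), 1 (FOREST) or 2 (DEFORESTED_NEW)",
         call. = FALSE)
  structure(codes, year = year, legend = lg_legend(), class = "lg_classmap")
}

lg_legend <- function() {
  c(NONFOREST = 0L, FOREST = 1L, DEFORESTED_NEW = 2L)
}

#' @export
print.lg_classmap <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = 0:2,
                      labels = names(lg_legend())))
  cat(sprintf("<lg_classmap> year %s, %d x %d px\n",
              attr(x, "year"), nrow(x), ncol(x)))
  print(tab)
  invisible(x)
}

#' Roll a class map forward one date
#'
#' New deforestation of the previous date becomes plain non-forest; forest is
#' untouched. Used internally by the mask-update stage.
#' @param x an `lg_classmap`.
#' @return integer matrix of codes with `DEFORESTED_NEW` folded into
#'   `NONFOREST`.
#' @keywords internal
roll_forward <- function(x) {
  m <- unclass(x)
  m[m == 2L] <- 0L
  m
}
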