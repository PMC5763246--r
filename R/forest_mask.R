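#' Declarative segment-classification rule set
#'
#' The non-forest delineation follows a sequential decision-tree style:
#' ordered predicates over segment attributes label non-forest segments
#' (crops, pasture, wide roads, water) first; whatever remains is forest.
#' Each rule is `list(attribute, op, value, class)` with `op` one of
#' `"<", "<=", ">", ">="`. Rules are applied in order; the first match wins.
#'
#' The defaults flag soil-dominated segments (fields, pastures, clearings)
#' and shade/water-dominated segments as non-forest. They are placeholders to
#' be tuned per scene — real scenes need scene-specific thresholds — and
#' every pipeline run logs the rule set it used.
#'
#' @param rules list of rules; default `default_rules()`.
#' @return object of class `lg_rules`.
#' @export
rule_set <- function(rules = default_rules()) {
  for (r in rules) {
    stopifnot(all(c("attribute", "op", "value", "class") %in% names(r)))
    if (!r$op %in% c("<", "<=", ">", ">="))
      stop("configuration error: unknown rule operator ", r$op, call. = FALSE)
  }
  structure(rules, class = "lg_rules")
}

#' @rdname rule_set
#' @export
default_rules <- function() {
  list(
    list(attribute = "mean_soil", op = ">=", value = 0.40,
         class = "NONFOREST"),
    list(attribute = "mean_shade", op = ">=", value = 0.70,
         class = "NONFOREST"))
}

#' Classify segments into forest / non-forest
#'
#' Applies a [rule_set()] sequentially to the segment attribute table:
#' segments matching a rule take that rule's class, the remainder is labelled
#' forest. Every segment is labelled exactly once.
#'
#' @param segments an `lg_segments` whose attribute table carries every
#'   attribute the rules reference (build it with the scene and fraction
#'   stack via [segment_attributes()]).
#' @param fractions optional `lg_fractions`; when given, fraction attributes
#'   are (re)computed and joined before rule evaluation.
#' @param scene optional [scene()] for spectral attributes.
#' @param rules an [rule_set()].
#' @param year year label for the resulting map.
#' @return an [classmap()]; pixels outside the segment mask are `NONFOREST`.
#' @export
classify_segments <- function(segments, scene = NULL, fractions = NULL,
                              rules = rule_set(), year = NA) {
  att <- if (!is.null(scene) || !is.null(fractions))
    segment_attributes(segments$ids, scene, fractions)
  else segments$attributes
  cls <- rep("FOREST", nrow(att))
  open <- rep(TRUE, nrow(att))
  for (r in rules) {
    if (!r$attribute %in% names(att))
      stop("configuration error: rule references unknown attribute '",
           r$attribute, "'", call. = FALSE)
    hit <- open & do.call(r$op, list(att[[r$attribute]], r$value))
    cls[hit] <- r$class
    open[hit] <- FALSE
  }
  codes <- lg_legend()[cls]
  m <- matrix(0L, nrow(segments$ids), ncol(segments$ids))
  inside <- segments$ids > 0L
  m[inside] <- codes[segments$ids[inside]]
  classmap(m, year = year)
}

#' Absorb small non-forest islands back into the forest
#'
#' The area criterion of the masking stage: non-forest connected components
#' smaller than `min_area_ha` whose border majority-touches forest are
#' relabelled forest, so logging features (decks, canopy gaps) stay inside
#' the forest polygons instead of being mapped as small clearings.
#'
#' @param x an [classmap()].
#' @param min_area_ha area threshold in hectares; 0 is the identity.
#' @param pixel_size pixel edge in metres.
#' @return the corrected [classmap()]; the number of absorbed components is
#'   attached as attribute `absorbed`.
#' @export
absorb_small_nonforest <- function(x, min_area_ha = 1, pixel_size = 30) {
  stopifnot(min_area_ha >= 0)
  m <- unclass(x)
  if (min_area_ha == 0) {
    attr(x, "absorbed") <- 0L
    return(x)
  }
  comp <- cpp_label_components(m == 0L)
  n_comp <- max(comp)
  if (n_comp == 0) {
    attr(x, "absorbed") <- 0L
    return(x)
  }
  px_area <- pixel_size^2 / 1e4
  sizes <- tabulate(comp[comp > 0L], nbins = n_comp)
  absorbed <- 0L
  nr <- nrow(m); nc <- ncol(m)
  for (k in which(sizes * px_area < min_area_ha)) {
    idx <- which(comp == k, arr.ind = TRUE)
    nb_forest <- 0L; nb_other <- 0L
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (comp[r2, c2] == k) next
        if (m[r2, c2] == 1L) nb_forest <- nb_forest + 1L
        else nb_other <- nb_other + 1L
      }
    }
    if (nb_forest > nb_other) {
      m[comp == k] <- 1L
      absorbed <- absorbed + 1L
    }
  }
  out <- classmap(m, year = attr(x, "year"))
  attr(out, "absorbed") <- absorbed
  out
}

#' Build the base-year forest mask
#'
#' Segments the base-year scene (multiresolution, conventional parameters
#' scale 10, shape 0.2, compactness 0.5, red/NIR/SWIR bands), classifies the
#' segments with the rule set, then applies the small-island area criterion.
#'
#' @param x base-year [scene()].
#' @param fractions `lg_fractions` of the base-year scene.
#' @param params an [segmentation_params()]; default the base-year set.
#' @param rules an [rule_set()].
#' @param min_area_ha area criterion for [absorb_small_nonforest()].
#' @param year year label.
#' @return an [classmap()].
#' @export
base_forest_mask <- function(x, fractions,
                             params = segmentation_params(scale = 10),
                             rules = rule_set(), min_area_ha = 1,
                             year = NA) {
  seg <- segment_multiresolution(x, params)
  cm <- classify_segments(seg, scene = x, fractions = fractions,
                          rules = rules, year = year)
  absorb_small_nonforest(cm, min_area_ha, pixel_size = x$pixel_size)
}

#' Update the forest mask with new deforestation
#'
#' The annual update keeps the previous mask fixed (prior non-forest and
#' prior new-deforestation become non-forest) and looks for new clearings
#' only inside prior forest: a multiresolution segmentation restricted to
#' the prior-forest domain (conventional scale 50, shape 0.1) is classified
#' with the rule set, and candidate clearing components at or above the
#' minimum mapping unit become `DEFORESTED_NEW`. Smaller openings stay
#' forest — they are logging evidence for the soil-fraction stage, not
#' deforestation.
#'
#' @param prev previous date's [classmap()].
#' @param scene_t current [scene()].
#' @param fractions_t current `lg_fractions`.
#' @param params an [segmentation_params()]; default the update set
#'   (scale 50, shape 0.1, compactness 0.5).
#' @param rules an [rule_set()].
#' @param mmu_ha minimum mapping unit for new clearings (default 1 ha).
#' @param year year label.
#' @return an [classmap()] for the current date.
#' @export
update_forest_mask <- function(prev, scene_t, fractions_t,
                               params = segmentation_params(
                                 scale = 50, shape_weight = 0.1),
                               rules = rule_set(), mmu_ha = 1, year = NA) {
  stopifnot(inherits(prev, "lg_classmap"))
  if (!all(dim(prev) == dim(scene_t$bands)[1:2]))
    stop("alignment error: previous mask does not cover the scene",
         call. = FALSE)
  base <- roll_forward(prev)           # 0 = non-forest carried forward
  forest_prior <- base == 1L
  out <- base
  if (any(forest_prior)) {
    seg <- segment_multiresolution(scene_t, params, mask = forest_prior)
    cm <- classify_segments(seg, scene = scene_t, fractions = fractions_t,
                            rules = rules, year = year)
    cand <- unclass(cm) == 0L & forest_prior
    if (any(cand)) {
      comp <- cpp_label_components(cand)
      sizes <- tabulate(comp[comp > 0L], nbins = max(comp))
      px_area <- scene_t$pixel_size^2 / 1e4
      big <- which(sizes * px_area >= mmu_ha)
      if (length(big))
        out[comp %in% big] <- 2L
    }
  }
  classmap(out, year = year)
}
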