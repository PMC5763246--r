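#' Configuration of the synthetic landscape simulator
#'
#' Describes a multi-year tropical-forest landscape undergoing deforestation
#' and selective logging, with known per-pixel truth. Defaults emulate the
#' study-region conditions: 30 m pixels, six reflectance bands, logging
#' decks on a jittered lattice at 225 m spacing (the observed 200-250 m
#' deck distance), ~2% y-1 deforestation growing from the agricultural
#' frontier, about a quarter of the forest entering logging blocks each
#' year (annual affected areas of 23-39% of forest were reported for the
#' region), and canopy recovery erasing logging evidence after 2 years
#' (within the observed 1-4 year closure range).
#'
#' @param extent `(rows, cols)` in pixels, at least 50 x 50.
#' @param pixel_size_m pixel edge (default 30).
#' @param n_years number of annual dates (>= 2).
#' @param endmember_spectra bands x 3 matrix (soil, vegetation, shade)
#'   reflectance in [0, 1]; default a typical Landsat-style set.
#' @param deck_spacing_m lattice spacing of logging decks (default 225).
#' @param deforestation_rate_per_year fraction of remaining forest cleared
#'   per year (default 0.02).
#' @param logging_block_fraction_per_year fraction of forest entering new
#'   logging blocks per year (default 0.25).
#' @param initial_nonforest_fraction landscape share that is already
#'   non-forest at the first date (default 0.19).
#' @param recovery_years years a logging feature stays visible (default 2).
#' @param noise_sd default additive reflectance noise used by
#'   [render_scene()] (default 0.01).
#' @param seed integer master seed; per-year streams are derived from it so
#'   extending the series never perturbs earlier years.
#' @return list of class `lg_simconfig`.
#' @export
simulation_config <- function(extent = c(100, 100), pixel_size_m = 30,
                              n_years = 5,
                              endmember_spectra = default_endmembers(),
                              deck_spacing_m = 225,
                              deforestation_rate_per_year = 0.02,
                              logging_block_fraction_per_year = 0.25,
                              initial_nonforest_fraction = 0.19,
                              recovery_years = 2, noise_sd = 0.01,
                              seed = 42L) {
  if (any(extent < 50))
    stop("configuration error: extent must be at least 50 x 50 pixels",
         call. = FALSE)
  if (n_years < 2)
    stop("configuration error: n_years must be >= 2", call. = FALSE)
  rates <- c(deforestation_rate_per_year, logging_block_fraction_per_year,
             initial_nonforest_fraction)
  if (any(rates < 0) || any(rates > 1))
    stop("configuration error: rates must lie in [0, 1]", call. = FALSE)
  em <- endmembers(endmember_spectra)   # validates range + rank
  structure(list(
    extent = as.integer(extent), pixel_size_m = pixel_size_m,
    n_years = as.integer(n_years), endmembers = em,
    deck_spacing_m = deck_spacing_m,
    deforestation_rate_per_year = deforestation_rate_per_year,
    logging_block_fraction_per_year = logging_block_fraction_per_year,
    initial_nonforest_fraction = initial_nonforest_fraction,
    recovery_years = as.integer(recovery_years), noise_sd = noise_sd,
    seed = as.integer(seed)), class = "lg_simconfig")
}

#' Default Landsat-style endmember spectra
#'
#' Bands blue, green, red, NIR, SWIR1, SWIR2; columns soil, vegetation,
#' shade. Values are typical image-derived top-of-atmosphere reflectance
#' for bright soil, closed green canopy and shade/water.
#' @return 6 x 3 numeric matrix.
#' @export
default_endmembers <- function() {
  m <- cbind(soil = c(0.11, 0.15, 0.21, 0.30, 0.40, 0.35),
             vegetation = c(0.03, 0.06, 0.04, 0.45, 0.22, 0.09),
             shade = c(0.02, 0.03, 0.02, 0.03, 0.02, 0.01))
  rownames(m) <- c("blue", "green", "red", "nir", "swir1", "swir2")
  m
}

# endmember fraction signatures (soil, vegetation, shade) of the landscape
# motifs; undisturbed forest stays well below the 10% soil threshold, every
# logging feature at or above it
lg_signatures <- function() {
  rbind(forest = c(0.03, 0.85, 0.12),
        nonforest = c(0.70, 0.20, 0.10),
        deck = c(0.60, 0.25, 0.15),
        road = c(0.30, 0.55, 0.15),
        gap = c(0.15, 0.70, 0.15))
}

# derive a per-(seed, year) RNG stream; keeps every year reproducible
# independently of how many years are simulated
with_year_seed <- function(seed, year, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed((as.integer(seed) %% 1000003L) * 1009L + as.integer(year))
  force(expr)
}

#' Simulate a multi-year logging/deforestation landscape
#'
#' Builds per-year truth: pixel labels (non-forest / forest / new
#' deforestation), endmember fraction maps summing to one, the set of
#' actively disturbed forest pixels, and a ledger of placed features. The
#' first date is the clean baseline; from the second date onward
#' deforestation grows as contiguous patches from the non-forest frontier
#' and logging blocks receive decks on a jittered lattice, one-pixel roads
#' linking the decks, and scattered canopy gaps. Logging evidence persists
#' in the fraction maps for `recovery_years` and then resets abruptly to
#' the undisturbed forest signature (no gradual regrowth curve is
#' modelled); deforestation never reverts.
#'
#' @param config an [simulation_config()].
#' @return object of class `lg_truth`: lists `labels`, `fractions`,
#'   `disturbed`, `features`, `decks` indexed by year, plus the config.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "lg_simconfig"))
  nr <- config$extent[1]; nc <- config$extent[2]
  ny <- config$n_years
  sig <- lg_signatures()

  # --- baseline non-forest: ragged strip along the left edge -------------
  lab <- matrix(1L, nr, nc)
  target_nf <- round(config$initial_nonforest_fraction * nr * nc)
  if (target_nf > 0) {
    base_w <- target_nf / nr
    w <- with_year_seed(config$seed, 0L, {
      drift <- cumsum(stats::rnorm(nr, 0, 0.6))
      pmax(0L, pmin(nc, round(base_w + drift - mean(drift))))
    })
    for (r in seq_len(nr)) if (w[r] > 0) lab[r, seq_len(w[r])] <- 0L
  }

  labels <- vector("list", ny)
  fractions <- vector("list", ny)
  disturbed <- vector("list", ny)
  features <- vector("list", ny)   # 0 none, 1 deck, 2 road, 3 gap
  decks <- vector("list", ny)

  features[[1]] <- matrix(0L, nr, nc)
  decks[[1]] <- data.frame(row = integer(), col = integer())
  labels[[1]] <- classmap(lab, year = 1)

  for (y in 2:ny) {
    lab <- roll_forward(labels[[y - 1]])
    with_year_seed(config$seed, y, {
      # -- logging blocks with decks, roads, gaps -------------------------
      # features are placed first and clearings are then kept at least
      # three pixels away from any still-visible evidence, so logging
      # features and clearings never share an object boundary
      feat <- matrix(0L, nr, nc)
      # logging blocks sit deep in the forest interior: at least 20 px from
      # any non-forest, which is more than the frontier can advance while
      # the block's evidence is still visible (patch radius 6, so <= 7 px
      # per year, two visible years), keeping clearings and active logging
      # features apart
      deep <- lab != 1L
      for (i in 1:20) deep <- deep | neighbour_any(deep)
      interior <- lab == 1L & !deep
      forest_now <- lab == 1L & !neighbour_any(lab != 1L)
      target_block <- config$logging_block_fraction_per_year * sum(forest_now)
      placed <- 0L
      dk <- NULL
      guard <- 0L
      spacing <- max(2L, round(config$deck_spacing_m / config$pixel_size_m))
      while (placed < target_block && guard < 60L) {
        guard <- guard + 1L
        h <- sample(24:36, 1); wd <- sample(24:36, 1)
        r0 <- sample.int(max(1L, nr - h), 1)
        c0 <- sample.int(max(1L, nc - wd), 1)
        rows <- r0:min(nr, r0 + h - 1L); cols <- c0:min(nc, c0 + wd - 1L)
        blk_forest <- forest_now[rows, cols]
        if (mean(interior[rows, cols]) < 0.999) next
        placed <- placed + sum(blk_forest)
        # jittered deck lattice
        dr <- seq(min(rows) + 2L, max(rows) - 2L, by = spacing)
        dc <- seq(min(cols) + 2L, max(cols) - 2L, by = spacing)
        for (rr in dr) for (cc in dc) {
          r <- rr + sample(-1:1, 1); c <- cc + sample(-1:1, 1)
          if (r < 1 || r > nr || c < 1 || c > nc) next
          if (!forest_now[r, c]) next
          feat[r, c] <- 1L
          dk <- rbind(dk, data.frame(row = r, col = c))
          if (c + 1L <= nc && forest_now[r, c + 1L] && stats::runif(1) < 0.5)
            feat[r, c + 1L] <- 1L       # some decks span two pixels
          # canopy gaps scattered around the deck
          for (g in seq_len(sample(1:3, 1))) {
            gr <- r + sample(-3:3, 1); gc <- c + sample(-3:3, 1)
            if (gr >= 1 && gr <= nr && gc >= 1 && gc <= nc &&
                forest_now[gr, gc] && feat[gr, gc] == 0L)
              feat[gr, gc] <- 3L
          }
        }
        # one-pixel logging roads along each lattice row, plus a spine
        for (rr in dr) {
          if (rr < 1 || rr > nr) next
          for (cc in min(cols):max(cols)) {
            if (forest_now[rr, cc] && feat[rr, cc] == 0L)
              feat[rr, cc] <- 2L
          }
        }
        spine <- min(cols)
        for (rr in min(rows):max(rows)) {
          if (forest_now[rr, spine] && feat[rr, spine] == 0L)
            feat[rr, spine] <- 2L
        }
      }
      features[[y]] <- feat
      decks[[y]] <- dk %||% data.frame(row = integer(), col = integer())
      # -- deforestation: contiguous patches grown from the frontier ------
      active <- feat > 0L
      for (src in seq_len(max(config$recovery_years - 1L, 0L))) {
        s <- y - src
        if (s >= 2 && s <= ny) active <- active | features[[s]] > 0L
      }
      spare <- active
      for (i in 1:2) spare <- spare | neighbour_any(spare)
      forest_n <- sum(lab == 1L)
      target <- round(config$deforestation_rate_per_year * forest_n)
      cleared <- 0L
      guard <- 0L
      while (cleared < target && guard < 200L) {
        guard <- guard + 1L
        allowed <- lab == 1L & !spare
        frontier <- which(allowed & neighbour_any(lab == 0L))
        if (!length(frontier)) break
        patch_target <- sample(15:45, 1)
        seed_px <- frontier[sample.int(length(frontier), 1)]
        patch <- grow_patch(allowed, seed_px, patch_target, nr, nc)
        if (length(patch) < 15L) next   # clearings never fall below the MMU
        lab[patch] <- 2L
        cleared <- cleared + length(patch)
      }
      # clearing strands no tiny forest pockets: small feature-free forest
      # components cut off from the main forest body by this year's patches
      # are cleared with the patch that isolated them
      if (cleared > 0L) {
        comp <- cpp_label_components(lab == 1L)
        if (max(comp) > 1L) {
          sizes <- tabulate(comp[comp > 0L], nbins = max(comp))
          main <- which.max(sizes)
          next_to_new <- neighbour_any(lab == 2L)
          for (k in seq_along(sizes)) {
            if (k == main || sizes[k] > 50L) next
            px <- comp == k
            if (any(active[px])) next
            if (any(next_to_new[px])) lab[px] <- 2L
          }
        }
      }
      labels[[y]] <- classmap(lab, year = y)
    })
  }

  # --- fraction maps and active-disturbance overlays ---------------------
  for (y in seq_len(ny)) {
    lab <- unclass(labels[[y]])
    fr <- array(0, c(nr, nc, 3))
    for (k in 1:3) {
      f <- matrix(sig["forest", k], nr, nc)
      f[lab != 1L] <- sig["nonforest", k]
      fr[, , k] <- f
    }
    active <- matrix(0L, nr, nc)
    for (age in seq_len(config$recovery_years) - 1L) {
      src <- y - age
      if (src < 2 || src > ny) next
      f <- features[[src]]
      upd <- f > 0L & lab == 1L      # deforested pixels lose their features
      active[upd] <- f[upd]
    }
    for (code in 1:3) {
      hit <- active == code
      if (!any(hit)) next
      nm <- c("deck", "road", "gap")[code]
      for (k in 1:3) {
        f <- fr[, , k]; f[hit] <- sig[nm, k]; fr[, , k] <- f
      }
    }
    fractions[[y]] <- fr
    disturbed[[y]] <- active > 0L
  }

  structure(list(config = config, n_years = ny, labels = labels,
                 fractions = fractions, disturbed = disturbed,
                 features = features, decks = decks),
            class = "lg_truth")
}

neighbour_any <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  out[-1, ] <- out[-1, ] | mask[-nr, ]
  out[-nr, ] <- out[-nr, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -nc]
  out[, -nc] <- out[, -nc] | mask[, -1]
  out
}

# randomized BFS region growth over allowed pixels, capped to a Chebyshev
# radius around the seed so each patch advances the frontier a bounded
# distance; returns linear indices
grow_patch <- function(allowed, seed_px, target, nr, nc, radius = 6L) {
  patch <- integer(0)
  frontier <- seed_px
  taken <- logical(nr * nc)
  r0 <- (seed_px - 1L) %% nr + 1L; c0 <- (seed_px - 1L) %/% nr + 1L
  while (length(patch) < target && length(frontier)) {
    i <- frontier[sample.int(length(frontier), 1)]
    frontier <- setdiff(frontier, i)
    if (taken[i] || !allowed[i]) next
    taken[i] <- TRUE
    patch <- c(patch, i)
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    nbr <- c(if (r > 1) i - 1L, if (r < nr) i + 1L,
             if (c > 1) i - nr, if (c < nc) i + nr)
    nbr <- nbr[!taken[nbr] & allowed[nbr]]
    nbr_r <- (nbr - 1L) %% nr + 1L; nbr_c <- (nbr - 1L) %/% nr + 1L
    nbr <- nbr[pmax(abs(nbr_r - r0), abs(nbr_c - c0)) <= radius]
    frontier <- c(frontier, nbr)
  }
  patch
}

#' @export
print.lg_truth <- function(x, ...) {
  cat(sprintf("<lg_truth> %d x %d px, %d years\n",
              x$config$extent[1], x$config$extent[2], x$n_years))
  invisible(x)
}

#' Render one year of a simulated landscape as a reflectance scene
#'
#' Forward linear mixing: per band, reflectance is the fraction-weighted
#' combination of the endmember spectra plus additive Gaussian noise,
#' clipped to [0, 1].
#'
#' @param truth an [simulate_landscape()] result.
#' @param year year index within the truth.
#' @param noise_sd per-band additive noise standard deviation; defaults to
#'   the config value.
#' @param seed noise seed; defaults to the config seed. Noise streams are
#'   keyed by (seed, year).
#' @return an [scene()].
#' @export
render_scene <- function(truth, year, noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(truth, "lg_truth"))
  if (year < 1 || year > truth$n_years)
    stop("year outside the simulated range", call. = FALSE)
  cfg <- truth$config
  noise_sd <- noise_sd %||% cfg$noise_sd
  seed <- seed %||% cfg$seed
  E <- cfg$endmembers$spectra
  nr <- cfg$extent[1]; nc <- cfg$extent[2]
  FR <- matrix(truth$fractions[[year]], nr * nc, 3)
  Y <- FR %*% t(E)                      # pixels x bands
  if (noise_sd > 0) {
    Y <- Y + with_year_seed(seed, year + 7919L,
                            matrix(stats::rnorm(length(Y), 0, noise_sd),
                                   nrow(Y), ncol(Y)))
  }
  Y[Y < 0] <- 0; Y[Y > 1] <- 1
  scene(array(Y, c(nr, nc, nrow(E))),
        date = as.Date(sprintf("%d-07-01", 1999 + year)),
        pixel_size = cfg$pixel_size_m,
        band_names = rownames(E) %||% paste0("band_", seq_len(nrow(E))))
}

#' Per-cell truth accounting for a simulated year
#'
#' The simulator's own ledger aggregated to a reporting grid: forest /
#' non-forest / new-deforestation / disturbed pixel counts and the implied
#' intensity, computed directly from the truth labels (independently of the
#' image-analysis pipeline).
#'
#' @param truth an [simulate_landscape()] result.
#' @param grid an [build_grid()] grid over the truth extent.
#' @param year year index.
#' @return data.frame as from [assess_cells()].
#' @export
truth_cells <- function(truth, grid, year) {
  assess_cells(grid, truth$labels[[year]], truth$disturbed[[year]],
               year = year)
}

#' Write a simulated year to disk (scene, labels, config sidecar)
#'
#' @param truth an [simulate_landscape()] result.
#' @param year year index.
#' @param stem output path stem.
#' @param noise_sd,seed passed to [render_scene()].
#' @export
write_simulated_year <- function(truth, year, stem, noise_sd = NULL,
                                 seed = NULL) {
  sc <- render_scene(truth, year, noise_sd = noise_sd, seed = seed)
  write_scene(sc, stem)
  write_asc(unclass(truth$labels[[year]]), paste0(stem, "_labels.asc"),
            pixel_size = truth$config$pixel_size_m)
  cfg <- truth$config
  jsonlite::write_json(
    list(extent = cfg$extent, pixel_size_m = cfg$pixel_size_m,
         n_years = cfg$n_years, deck_spacing_m = cfg$deck_spacing_m,
         deforestation_rate_per_year = cfg$deforestation_rate_per_year,
         logging_block_fraction_per_year =
           cfg$logging_block_fraction_per_year,
         initial_nonforest_fraction = cfg$initial_nonforest_fraction,
         recovery_years = cfg$recovery_years, noise_sd = cfg$noise_sd,
         seed = cfg$seed, year = year,
         label_codes = as.list(lg_legend())),
    paste0(stem, "_config.json"), auto_unbox = TRUE)
  invisible(stem)
}
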