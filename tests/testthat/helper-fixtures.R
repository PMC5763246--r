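# shared fixtures: tiny scenes, endmembers and an independent unmixing
# oracle; everything is built in code at test time

em_default <- endmembers(default_endmembers())

# scene whose every pixel is a fixed mixture of the default endmembers
mixture_scene <- function(fr, nr = 4, nc = 4, pixel_size = 30) {
  E <- em_default$spectra
  spec <- as.numeric(E %*% fr)
  arr <- array(rep(spec, each = nr * nc), c(nr, nc, length(spec)))
  scene(arr, pixel_size = pixel_size, band_names = rownames(E))
}

# brute-force oracle: exhaustive search over the unit simplex at a given
# resolution, vectorised over pixels (Y: bands x pixels)
simplex_grid_oracle <- function(Y, E, resolution = 0.01) {
  steps <- round(1 / resolution)
  g <- expand.grid(i = 0:steps, j = 0:steps)
  g <- g[g$i + g$j <= steps, ]
  FR <- cbind(g$i, g$j, steps - g$i - g$j) / steps   # candidates x 3
  S <- FR %*% t(E)                                   # candidate spectra
  # rss(candidate, pixel) = |y|^2 - 2 y.s + |s|^2
  cross <- S %*% Y                                   # candidates x pixels
  rss <- matrix(rowSums(S^2), nrow(S), ncol(Y)) - 2 * cross
  best <- apply(rss, 2, which.min)
  t(FR[best, , drop = FALSE])                        # 3 x pixels
}

# bare integer codes of a class map, metadata stripped
codes_of <- function(cm) {
  m <- unclass(cm)
  attributes(m) <- list(dim = dim(m))
  m
}

# small simulated world reused across tests
small_truth <- function(seed = 7, n_years = 4, extent = c(100, 100)) {
  simulate_landscape(simulation_config(extent = extent, n_years = n_years,
                                       seed = seed))
}
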