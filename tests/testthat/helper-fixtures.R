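# Shared fixtures: small seeded scenes and hand-built rasters.

# small multi-plot synthetic field (defaults keep tests fast)
small_scene <- function(n_plots = 4, snx = 4, sny = 3, px = 16,
                        noise_sd = 0.02, seed = 7,
                        plots_per_row = min(n_plots, 2), ...) {
  generate_scene(scene_config(n_plots = n_plots, snx = snx, sny = sny,
                              px_per_subplot = px,
                              plots_per_row = plots_per_row,
                              noise_sd = noise_sd, seed = seed, ...))
}

# 5-band raster from explicit per-band matrices (named BLUE..NIR)
raster_from_bands <- function(B, G, R, RE, N) {
  arr <- array(0, dim = c(nrow(B), ncol(B), 5))
  arr[, , 1] <- B; arr[, , 2] <- G; arr[, , 3] <- R
  arr[, , 4] <- RE; arr[, , 5] <- N
  multiband_raster(arr, c("BLUE", "GREEN", "RED", "REG", "NIR"))
}

# two-region raster: left columns soil-like, right columns canopy-like
two_region_raster <- function(nr = 8, nc = 10, split = 5, noise = 0,
                              seed = 1) {
  set.seed(seed)
  soil <- c(0.10, 0.14, 0.18, 0.22, 0.26)
  canopy <- c(0.05, 0.10, 0.05, 0.35, 0.55)
  arr <- array(0, dim = c(nr, nc, 5))
  for (b in 1:5) {
    m <- matrix(soil[b], nr, nc)
    m[, (split + 1):nc] <- canopy[b]
    if (noise > 0) m <- m + matrix(rnorm(nr * nc, 0, noise), nr, nc)
    arr[, , b] <- pmin(pmax(m, 0), 1)
  }
  multiband_raster(arr, c("BLUE", "GREEN", "RED", "REG", "NIR"))
}

expect_monotone_nonincreasing <- function(x, tol = 1e-9) {
  expect_true(all(diff(x) <= tol))
}
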