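# Seeded synthetic multispectral field scenes with known canopy masks,
# plot grids, latent traits and camera pose.

#' Synthetic scene configuration
#'
#' Defaults emulate the study field: 59 plots of 40 subplots (8 x 5 lattice
#' of 32 px tiles at 2.5 cm/px), soil vs canopy reflectance with the
#' vegetation spectral contract (canopy NIR above soil NIR, canopy red below
#' soil red), per-plot latent biomass / SPAD spanning the observed field
#' ranges, canopy cover increasing with dry biomass, NIR and red-edge
#' reflectance increasing and red decreasing with SPAD, and i.i.d. Gaussian
#' sensor noise.
#'
#' @param n_plots number of plots.
#' @param snx,sny subplots per plot along x / y (snx * sny subplots).
#' @param px_per_subplot subplot side, pixels.
#' @param plots_per_row,gap field layout (see [make_plot_grid()]).
#' @param gsd ground sample distance, cm/pixel.
#' @param soil_reflectance,canopy_reflectance_base per-band means in [0, 1],
#'   order B, G, R, RE, NIR.
#' @param spad_slopes per-band reflectance change per SPAD unit (affine
#'   trait-to-reflectance link, clipped to [0, 1]).
#' @param trait_ranges list with \code{dry} (g), \code{spad}, and
#'   \code{water_pct} intervals for the per-plot latent draws.
#' @param canopy_cover_range canopy cover fraction interval, mapped linearly
#'   from dry biomass.
#' @param noise_sd sensor noise standard deviation, reflectance units.
#' @param soil_texture_amp amplitude of the low-frequency soil texture.
#' @param seed integer seed for the scene's single random stream.
#' @return list of class \code{scene_config}.
#' @export
scene_config <- function(n_plots = 59, snx = 8, sny = 5, px_per_subplot = 32,
                         plots_per_row = 8, gap = 8, gsd = 2.5,
                         soil_reflectance = c(BLUE = 0.10, GREEN = 0.14,
                                              RED = 0.18, REG = 0.22, NIR = 0.26),
                         canopy_reflectance_base = c(BLUE = 0.05, GREEN = 0.10,
                                                     RED = 0.05, REG = 0.35,
                                                     NIR = 0.55),
                         spad_slopes = c(BLUE = -0.0005, GREEN = 0.002,
                                         RED = -0.002, REG = 0.008, NIR = 0.012),
                         trait_ranges = list(dry = c(200, 400),
                                             spad = c(30.58, 44.76),
                                             water_pct = c(64, 75)),
                         canopy_cover_range = c(0.35, 0.85),
                         noise_sd = 0.02, soil_texture_amp = 0.02, seed = 1) {
  stopifnot(all(soil_reflectance >= 0 & soil_reflectance <= 1),
            all(canopy_reflectance_base >= 0 & canopy_reflectance_base <= 1),
            canopy_reflectance_base["NIR"] > soil_reflectance["NIR"],
            canopy_reflectance_base["RED"] < soil_reflectance["RED"],
            noise_sd >= 0)
  structure(as.list(environment()), class = "scene_config")
}

# paint an ellipse (center cx,cy; semi-axes a,b; rotation th) into mask,
# restricted to its bounding box; 0-based coordinates
paint_ellipse <- function(mask, cx, cy, a, b, th) {
  r <- max(a, b)
  x0 <- max(floor(cx - r), 0); x1 <- min(ceiling(cx + r), ncol(mask) - 1)
  y0 <- max(floor(cy - r), 0); y1 <- min(ceiling(cy + r), nrow(mask) - 1)
  if (x1 < x0 || y1 < y0) return(mask)
  xs <- x0:x1; ys <- y0:y1
  X <- outer(rep(1, length(ys)), xs) - cx
  Y <- outer(ys, rep(1, length(xs))) - cy
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[ys + 1, xs + 1] <- mask[ys + 1, xs + 1] | inside
  mask
}

# low-frequency field texture: coarse uniform noise bilinearly upscaled
lowfreq_texture <- function(nr, nc, cell = 16, amp = 0.02) {
  gr <- ceiling(nr / cell) + 1; gc <- ceiling(nc / cell) + 1
  g <- matrix(stats::runif(gr * gc, -amp, amp), gr, gc)
  ry <- (seq_len(nr) - 1) / cell; rx <- (seq_len(nc) - 1) / cell
  i0 <- floor(ry); j0 <- floor(rx)
  fy <- ry - i0; fx <- rx - j0
  a <- g[cbind(i0 + 1)[, 1], j0 + 1, drop = FALSE]
  b <- g[cbind(i0 + 1)[, 1], pmin(j0 + 2, gc), drop = FALSE]
  c_ <- g[pmin(i0 + 2, gr), j0 + 1, drop = FALSE]
  d <- g[pmin(i0 + 2, gr), pmin(j0 + 2, gc), drop = FALSE]
  fxm <- matrix(fx, nr, nc, byrow = TRUE); fym <- matrix(fy, nr, nc)
  (1 - fym) * ((1 - fxm) * a + fxm * b) + fym * ((1 - fxm) * c_ + fxm * d)
}

#' Generate a synthetic multispectral field scene
#'
#' Draws per-plot latent traits (dry biomass, SPAD, water content) from the
#' configured ranges, paints a canopy of jittered overlapping ellipses (one
#' plant per subplot plus two tiller lobes) whose footprint grows with dry
#' biomass, assigns canopy reflectance by the affine SPAD link and soil
#' reflectance with low-frequency texture, adds Gaussian sensor noise, and
#' clips to [0, 1]. Deterministic for a fixed seed: one global stream.
#'
#' @param config a [scene_config()].
#' @return list of class \code{synthetic_scene} with \code{raster}
#'   (\code{multiband_raster}, bands B,G,R,RE,NIR), \code{truth_mask}
#'   (binary \code{canopy_mask}, 1 exactly where canopy was painted),
#'   \code{truth_records} (per-plot latent traits incl. per-band canopy
#'   reflectance), \code{grid}, and \code{config}.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  grid <- make_plot_grid(config$n_plots, config$snx, config$sny,
                         config$px_per_subplot, config$plots_per_row,
                         config$gap)
  fd <- attr(grid, "field_dim")
  nr <- unname(fd["rows"]); nc <- unname(fd["cols"])
  bands <- names(config$soil_reflectance)
  spad_ref <- mean(config$trait_ranges$spad)

  tr <- config$trait_ranges
  dry <- stats::runif(config$n_plots, tr$dry[1], tr$dry[2])
  spad <- stats::runif(config$n_plots, tr$spad[1], tr$spad[2])
  wc <- stats::runif(config$n_plots, tr$water_pct[1], tr$water_pct[2])
  wet <- dry / (1 - wc / 100)
  cover <- config$canopy_cover_range[1] +
    (dry - tr$dry[1]) / diff(tr$dry) * diff(config$canopy_cover_range)
  canopy_refl <- t(vapply(seq_len(config$n_plots), function(p)
    pmin(pmax(config$canopy_reflectance_base +
                config$spad_slopes * (spad[p] - spad_ref), 0), 1),
    numeric(length(bands))))
  colnames(canopy_refl) <- bands

  mask <- matrix(FALSE, nr, nc)
  plot_of_px <- matrix(0L, nr, nc)
  sub_area <- config$px_per_subplot^2
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- g$plot_id
    plot_of_px[(g$y0 + 1):g$y1, (g$x0 + 1):g$x1] <- p
    if (cover[p] >= 0.999) {
      mask[(g$y0 + 1):g$y1, (g$x0 + 1):g$x1] <- TRUE
      next
    }
    cx <- (g$x0 + g$x1 - 1) / 2 + stats::runif(1, -3, 3)
    cy <- (g$y0 + g$y1 - 1) / 2 + stats::runif(1, -3, 3)
    # main crown ~70% of the target footprint, two tiller lobes ~15% each
    r_main <- sqrt(0.70 * cover[p] * sub_area / pi)
    e <- exp(stats::runif(1, -0.2, 0.2))
    th <- stats::runif(1, 0, pi)
    mask <- paint_ellipse(mask, cx, cy, r_main * e, r_main / e, th)
    for (k in 1:2) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- r_main * stats::runif(1, 0.5, 0.9)
      r_lobe <- sqrt(0.15 * cover[p] * sub_area / pi)
      mask <- paint_ellipse(mask, cx + off * cos(ang), cy + off * sin(ang),
                            r_lobe * e, r_lobe / e, th)
    }
  }
  # canopy may spill a little into the soil gap; tag spill pixels by the
  # nearest plot so reflectance stays plot-consistent
  spill <- mask & plot_of_px == 0L
  if (any(spill)) {
    idx <- which(spill, arr.ind = TRUE)
    pr <- plot_rects(grid)
    cxs <- (pr$x0 + pr$x1) / 2; cys <- (pr$y0 + pr$y1) / 2
    for (k in seq_len(nrow(idx))) {
      d2 <- (idx[k, 2] - 1 - cxs)^2 + (idx[k, 1] - 1 - cys)^2
      plot_of_px[idx[k, 1], idx[k, 2]] <- pr$plot_id[which.min(d2)]
    }
  }

  arr <- array(0, dim = c(nr, nc, length(bands)))
  tex <- lowfreq_texture(nr, nc, cell = 16, amp = config$soil_texture_amp)
  canopy_px <- which(mask)
  plot_px <- plot_of_px[canopy_px]
  for (b in seq_along(bands)) {
    layer <- matrix(config$soil_reflectance[b], nr, nc) + tex
    layer[canopy_px] <- canopy_refl[plot_px, b]
    if (config$noise_sd > 0)
      layer <- layer + stats::rnorm(nr * nc, 0, config$noise_sd)
    arr[, , b] <- pmin(pmax(layer, 0), 1)
  }

  structure(list(
    raster = multiband_raster(arr, bands),
    truth_mask = canopy_mask(mask + 0, binary = TRUE),
    truth_records = data.frame(plot_id = seq_len(config$n_plots),
                               genotype_id = sprintf("G%02d", seq_len(config$n_plots)),
                               wet_g = wet, dry_g = dry, spad = spad,
                               water_pct = wc, cover = cover, canopy_refl),
    grid = grid, config = config), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene> ", x$config$n_plots, " plots x ",
      x$config$snx * x$config$sny, " subplots, seed ", x$config$seed, "\n",
      sep = "")
  print(x$raster)
  invisible(x)
}

#' Distort an orthorectified scene into a raw camera frame
#'
#' Applies the inverse of the orthorectification map: output frame pixel
#' (x, y) samples the ortho scene at the ground point that
#' [orthorectify_coords()] assigns to (x, y), so that a subsequent
#' [orthorectify_raster()] with the same camera recovers the original grid.
#' The identity camera (phi = 0, H = h, zero centers/offsets) is a no-op.
#'
#' @param raster an orthorectified \code{multiband_raster} (pixel coordinates
#'   are ground coordinates).
#' @param camera a [camera_model()].
#' @param out_dim output frame dimensions (rows, cols); defaults to the
#'   input's.
#' @return distorted \code{multiband_raster}.
#' @export
distort_frame <- function(raster, camera, out_dim = dim(raster$data)[1:2]) {
  stopifnot(inherits(raster, "multiband_raster"), inherits(camera, "camera_model"))
  if (abs(cos(camera$phi)) < .Machine$double.eps)
    stop("singular mapping: cos(phi) = 0")
  gg <- expand.grid(x = seq_len(out_dim[2]) - 1, y = seq_len(out_dim[1]) - 1)
  gc_ <- orthorectify_coords(gg$x, gg$y, camera)
  d <- dim(raster$data)
  out <- array(0, dim = c(out_dim[1], out_dim[2], d[3]))
  for (b in seq_len(d[3]))
    out[, , b] <- matrix(bilinear_sample(raster$data[, , b], gc_$Y, gc_$X),
                         nrow = out_dim[1], byrow = TRUE)
  multiband_raster(out, raster$bands)
}
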