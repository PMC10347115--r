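#' Camera model for single-frame orthorectification
#'
#' Parameters of the nadir-ish camera geometry used to map raw image pixels to
#' ground coordinates: image center, flying height, image height in pixels,
#' pitch angle and ground offsets of the image center.
#'
#' @param cx,cy image-center pixel coordinates (0-based).
#' @param H camera height above ground, m.
#' @param h image height, pixels.
#' @param phi camera pitch angle, radians; must satisfy |phi| < pi/2.
#' @param X0,Y0 ground coordinates of the image center.
#' @return object of class \code{camera_model}.
#' @export
camera_model <- function(cx = 0, cy = 0, H = 1, h = 1, phi = 0,
                         X0 = 0, Y0 = 0) {
  stopifnot(h > 0, H > 0)
  if (abs(phi) >= pi / 2) stop("camera pitch |phi| must be < pi/2")
  structure(list(cx = cx, cy = cy, H = H, h = h, phi = phi,
                 X0 = X0, Y0 = Y0), class = "camera_model")
}

#' Orthorectify pixel coordinates
#'
#' Maps raw image pixel coordinates (x, y) to ground coordinates (X, Y) under
#' the pitch-corrected scale model
#' \deqn{X = (x - c_x) H/h - (y - c_y) \tan(\phi) H/h + X_0}
#' \deqn{Y = (y - c_y) (H/h) \cos(\phi) + Y_0}
#' The map is affine in (x, y) for a fixed camera.
#'
#' @param x,y pixel coordinates (vectorized).
#' @param camera a [camera_model()].
#' @return list with numeric vectors \code{X} and \code{Y}.
#' @export
orthorectify_coords <- function(x, y, camera) {
  stopifnot(inherits(camera, "camera_model"))
  s <- camera$H / camera$h
  X <- (x - camera$cx) * s - (y - camera$cy) * tan(camera$phi) * s + camera$X0
  Y <- (y - camera$cy) * s * cos(camera$phi) + camera$Y0
  list(X = X, Y = Y)
}

#' Invert the orthorectification map
#'
#' Ground coordinates (X, Y) back to raw pixel coordinates (x, y); exact
#' inverse of [orthorectify_coords()] (the forward map is affine and
#' invertible whenever cos(phi) != 0).
#'
#' @inheritParams orthorectify_coords
#' @param X,Y ground coordinates (vectorized).
#' @return list with numeric vectors \code{x} and \code{y}.
#' @export
orthorectify_coords_inverse <- function(X, Y, camera) {
  stopifnot(inherits(camera, "camera_model"))
  s <- camera$H / camera$h
  if (abs(cos(camera$phi)) < .Machine$double.eps)
    stop("singular mapping: cos(phi) = 0")
  y <- (Y - camera$Y0) / (s * cos(camera$phi)) + camera$cy
  x <- (X - camera$X0) / s + (y - camera$cy) * tan(camera$phi) + camera$cx
  list(x = x, y = y)
}

# Bilinear sample of matrix m at fractional 0-based (row, col); outside -> fill
bilinear_sample <- function(m, row, col, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  get_px <- function(r, c) {
    ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
    v <- rep(fill, length(r))
    v[ok] <- m[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  v00 <- get_px(r0, c0);     v01 <- get_px(r0, c0 + 1)
  v10 <- get_px(r0 + 1, c0); v11 <- get_px(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Orthorectify a raster
#'
#' Resamples a raw frame onto a regular ground grid (unit spacing in ground
#' coordinates) by inverse mapping each output grid node through
#' [orthorectify_coords_inverse()] and bilinear interpolation of the input.
#' With the identity camera (phi = 0, H = h, zero centers and offsets) the
#' output equals the input.
#'
#' @param raster a \code{multiband_raster} (raw frame; x = column, y = row,
#'   0-based pixel centers).
#' @param camera a [camera_model()].
#' @param method \code{"bilinear"} (continuous bands) or \code{"nearest"}
#'   (masks / label images).
#' @return a \code{multiband_raster} on the ground grid, with attributes
#'   \code{origin} (ground coordinates of output pixel (0, 0)) recorded.
#' @export
orthorectify_raster <- function(raster, camera, method = c("bilinear", "nearest")) {
  stopifnot(inherits(raster, "multiband_raster"))
  method <- match.arg(method)
  d <- dim(raster$data)
  corners <- orthorectify_coords(x = c(0, d[2] - 1, 0, d[2] - 1),
                                 y = c(0, 0, d[1] - 1, d[1] - 1), camera)
  Xs <- seq(ceiling(min(corners$X)), floor(max(corners$X)))
  Ys <- seq(ceiling(min(corners$Y)), floor(max(corners$Y)))
  if (!length(Xs) || !length(Ys)) stop("orthorectified extent is empty")
  gg <- expand.grid(X = Xs, Y = Ys)
  px <- orthorectify_coords_inverse(gg$X, gg$Y, camera)
  if (method == "nearest") { px$x <- round(px$x); px$y <- round(px$y) }
  out <- array(0, dim = c(length(Ys), length(Xs), d[3]))
  for (b in seq_len(d[3]))
    out[, , b] <- matrix(bilinear_sample(raster$data[, , b], px$y, px$x),
                         nrow = length(Ys), byrow = TRUE)
  r <- multiband_raster(out, raster$bands)
  attr(r, "origin") <- c(X = Xs[1], Y = Ys[1])
  r
}

#' Register bands to a reference grid with control points
#'
#' Fits a 6-parameter affine transform per band from control-point pairs
#' (least squares), reports the residual RMS, and resamples each band onto
#' the reference pixel grid.
#'
#' @param rasters named list of single-band matrices, one per channel.
#' @param control_points named list (same names) of data.frames with columns
#'   \code{x_band}, \code{y_band}, \code{x_ref}, \code{y_ref}: at least 3
#'   non-collinear points per band.
#' @param ref_dim dimensions (rows, cols) of the reference grid; defaults to
#'   the first raster's.
#' @return list with \code{raster} (a \code{multiband_raster} of the
#'   registered bands), \code{transforms} (per-band 2x3 affine matrices,
#'   band -> reference) and \code{residual_rms} (per-band RMS in px).
#' @export
register_channels <- function(rasters, control_points, ref_dim = dim(rasters[[1]])) {
  stopifnot(is.list(rasters), length(rasters) >= 1,
            all(names(rasters) %in% names(control_points)))
  fit_band <- function(cp) {
    if (nrow(cp) < 3) stop("need at least 3 control points per band")
    A <- cbind(cp$x_band, cp$y_band, 1)
    if (qr(A)$rank < 3) stop("control points are collinear")
    # columns: affine coefficients mapping band px -> reference px
    coefs <- qr.solve(A, cbind(cp$x_ref, cp$y_ref))
    pred <- A %*% coefs
    rms <- sqrt(mean((pred - cbind(cp$x_ref, cp$y_ref))^2))
    list(M = t(coefs), rms = rms)  # 2x3: [a b tx; c d ty]
  }
  out <- array(0, dim = c(ref_dim[1], ref_dim[2], length(rasters)))
  transforms <- list(); rms <- numeric(length(rasters))
  names(rms) <- names(rasters)
  gg <- expand.grid(x = seq_len(ref_dim[2]) - 1, y = seq_len(ref_dim[1]) - 1)
  for (i in seq_along(rasters)) {
    nm <- names(rasters)[i]
    f <- fit_band(control_points[[nm]])
    transforms[[nm]] <- f$M; rms[i] <- f$rms
    # invert affine to pull reference pixels from the band image
    M <- rbind(f$M, c(0, 0, 1))
    Minv <- solve(M)
    xb <- Minv[1, 1] * gg$x + Minv[1, 2] * gg$y + Minv[1, 3]
    yb <- Minv[2, 1] * gg$x + Minv[2, 2] * gg$y + Minv[2, 3]
    out[, , i] <- matrix(bilinear_sample(rasters[[i]], yb, xb),
                         nrow = ref_dim[1], byrow = TRUE)
  }
  list(raster = multiband_raster(out, names(rasters)),
       transforms = transforms, residual_rms = rms)
}

#' Build the default plot/subplot grid
#'
#' Lays \code{n_plots} plots out row-major with a soil gap between plots; each
#' plot is an \code{snx x sny} lattice of square subplots. Rectangles are
#' half-open \code{[x0, x1) x [y0, y1)} in 0-based pixel coordinates.
#'
#' @param n_plots number of plots (default 59).
#' @param snx,sny subplots per plot along x and y (default 8 x 5 = 40).
#' @param px subplot side length in pixels (default 32).
#' @param plots_per_row plots per field row (default 8).
#' @param gap soil gap between plots and at the field border, px.
#' @return data.frame with columns \code{plot_id}, \code{subplot_id},
#'   \code{x0}, \code{y0}, \code{x1}, \code{y1}; attribute \code{field_dim}
#'   gives the (rows, cols) pixel size of the enclosing field.
#' @export
make_plot_grid <- function(n_plots = 59, snx = 8, sny = 5, px = 32,
                           plots_per_row = 8, gap = 8) {
  stopifnot(n_plots >= 1, snx >= 1, sny >= 1, px >= 1)
  pw <- snx * px; ph <- sny * px
  rows <- ceiling(n_plots / plots_per_row)
  recs <- vector("list", n_plots)
  for (p in seq_len(n_plots)) {
    pr <- (p - 1) %/% plots_per_row; pc <- (p - 1) %% plots_per_row
    ox <- gap + pc * (pw + gap); oy <- gap + pr * (ph + gap)
    sub <- expand.grid(sx = seq_len(snx) - 1, sy = seq_len(sny) - 1)
    recs[[p]] <- data.frame(
      plot_id = p, subplot_id = sub$sy * snx + sub$sx + 1,
      x0 = ox + sub$sx * px, y0 = oy + sub$sy * px,
      x1 = ox + (sub$sx + 1) * px, y1 = oy + (sub$sy + 1) * px)
  }
  g <- do.call(rbind, recs)
  g <- g[order(g$plot_id, g$subplot_id), ]
  rownames(g) <- NULL
  attr(g, "field_dim") <- c(rows = rows * (ph + gap) + gap,
                            cols = plots_per_row * (pw + gap) + gap)
  g
}

#' Plot-level rectangles of a grid
#'
#' @param grid data.frame from [make_plot_grid()].
#' @return data.frame with one row per plot: \code{plot_id, x0, y0, x1, y1}.
#' @export
plot_rects <- function(grid) {
  agg <- do.call(rbind, lapply(split(grid, grid$plot_id), function(g)
    data.frame(plot_id = g$plot_id[1], x0 = min(g$x0), y0 = min(g$y0),
               x1 = max(g$x1), y1 = max(g$y1))))
  agg[order(agg$plot_id), , drop = FALSE]
}

# Crop a matrix to a half-open [x0,x1)x[y0,y1) rectangle (0-based coords)
crop_rect <- function(m, rect) {
  m[(rect$y0 + 1):rect$y1, (rect$x0 + 1):rect$x1, drop = FALSE]
}

#' Extract per-subplot multiband tiles
#'
#' Crops one tile per subplot rectangle of the grid; tile pixel values equal
#' the raster crop exactly (no resampling).
#'
#' @param scene a \code{multiband_raster}.
#' @param grid data.frame from [make_plot_grid()].
#' @return list of tiles, each a list with \code{plot_id}, \code{subplot_id}
#'   and \code{raster} (a \code{multiband_raster}).
#' @export
extract_subplots <- function(scene, grid) {
  stopifnot(inherits(scene, "multiband_raster"))
  d <- dim(scene$data)
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    if (r$x0 < 0 || r$y0 < 0 || r$x1 > d[2] || r$y1 > d[1] || r$x1 <= r$x0 ||
        r$y1 <= r$y0)
      stop("subplot out of raster bounds: plot ", r$plot_id,
           " subplot ", r$subplot_id)
    tile <- scene$data[(r$y0 + 1):r$y1, (r$x0 + 1):r$x1, , drop = FALSE]
    list(plot_id = r$plot_id, subplot_id = r$subplot_id,
         raster = multiband_raster(tile, scene$bands))
  })
}
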