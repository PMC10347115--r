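# Ten per-pixel vegetation indices and mask-weighted plot statistics.

#' Vegetation index parameters
#'
#' @param L_savi soil adjustment factor for SAVI (default 0.5).
#' @param evi_G,evi_C1,evi_C2,evi_L EVI constants (canonical 2.5, 6, 7.5, 1).
#' @param gamma_arvi atmospheric correction factor for ARVI (default 1).
#' @param eps_div denominator guard: |denominator| below this yields NA.
#' @param arvi_literal use the red/blue-swapped ARVI variant
#'   \code{RB = BLUE - gamma (RED - BLUE)} instead of the standard
#'   \code{RB = RED - gamma (BLUE - RED)} (for auditing the two published
#'   forms of the index).
#' @return list of class \code{vi_params}.
#' @export
vi_params <- function(L_savi = 0.5, evi_G = 2.5, evi_C1 = 6, evi_C2 = 7.5,
                      evi_L = 1, gamma_arvi = 1, eps_div = 1e-10,
                      arvi_literal = FALSE) {
  stopifnot(eps_div > 0)
  structure(as.list(environment()), class = "vi_params")
}

#' Names of the ten supported vegetation indices
#' @return character vector.
#' @export
vi_names <- function() c("DVI", "NDVI", "GNDVI", "SAVI", "MSAVI", "CTVI",
                         "SR", "TVI", "EVI", "ARVI")

safe_div <- function(num, den, eps) {
  out <- num / den
  out[abs(den) < eps] <- NA_real_
  out
}

#' Compute one vegetation index per pixel
#'
#' Standard closed forms over reflectance bands in [0, 1]:
#' \itemize{
#' \item DVI = NIR - RED
#' \item NDVI = (NIR - RED) / (NIR + RED)
#' \item GNDVI = (NIR - GREEN) / (NIR + GREEN)
#' \item SAVI = (1 + L)(NIR - RED) / (NIR + RED + L)
#' \item MSAVI = (2 NIR + 1 - sqrt((2 NIR + 1)^2 - 8 (NIR - RED))) / 2
#' \item CTVI = sign(NDVI + 0.5) sqrt(|NDVI + 0.5|)
#' \item SR = NIR / RED
#' \item TVI = sqrt(NDVI + 0.5)
#' \item EVI = G (NIR - RED) / (NIR + C1 RED - C2 BLUE + L)
#' \item ARVI = (NIR - RB) / (NIR + RB), RB = RED - gamma (BLUE - RED)
#' }
#' Pixels whose denominator magnitude falls below \code{params$eps_div} are
#' returned as NA.
#'
#' @param bands a \code{multiband_raster} or named list of band matrices with
#'   names among BLUE, GREEN, RED, REG, NIR.
#' @param name index name (see [vi_names()]).
#' @param params a [vi_params()].
#' @return numeric matrix of the index.
#' @export
compute_index <- function(bands, name, params = vi_params()) {
  if (inherits(bands, "multiband_raster"))
    bands <- stats::setNames(lapply(bands$bands, function(b) get_band(bands, b)),
                             bands$bands)
  B <- bands$BLUE; G <- bands$GREEN; R <- bands$RED; N <- bands$NIR
  eps <- params$eps_div
  ndvi <- function() safe_div(N - R, N + R, eps)
  out <- switch(name,
    DVI = N - R,
    NDVI = ndvi(),
    GNDVI = safe_div(N - G, N + G, eps),
    SAVI = (1 + params$L_savi) * safe_div(N - R, N + R + params$L_savi, eps),
    MSAVI = (2 * N + 1 - sqrt(pmax((2 * N + 1)^2 - 8 * (N - R), 0))) / 2,
    CTVI = { v <- ndvi() + 0.5; sign(v) * sqrt(abs(v)) },
    SR = safe_div(N, R, eps),
    TVI = { v <- ndvi() + 0.5; out <- sqrt(pmax(v, 0)); out[v < 0] <- NA_real_; out },
    EVI = params$evi_G *
      safe_div(N - R, N + params$evi_C1 * R - params$evi_C2 * B + params$evi_L,
               eps),
    ARVI = {
      rb <- if (params$arvi_literal) B - params$gamma_arvi * (R - B)
            else R - params$gamma_arvi * (B - R)
      safe_div(N - rb, N + rb, eps)
    },
    stop("unknown vegetation index: ", name))
  out
}

#' Compute all ten indices
#'
#' @inheritParams compute_index
#' @return named list of index matrices.
#' @export
compute_all_indices <- function(bands, params = vi_params()) {
  stats::setNames(lapply(vi_names(), function(nm)
    compute_index(bands, nm, params)), vi_names())
}

# quantile of a weighted empirical CDF (left-continuous inverse)
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(p, function(pp) x[which(cw >= pp - 1e-12)[1]], numeric(1))
}

#' Mask-weighted statistics of an index over a plot rectangle
#'
#' Statistics are taken over pixels with mask 1 (binary mask) or weighted by
#' the soft mask value; box-plot fields follow Tukey's 1.5 IQR rule
#' (whiskers at the most extreme data points inside the fences).
#'
#' @param index numeric index matrix.
#' @param mask \code{canopy_mask} aligned with \code{index}.
#' @param rect optional one-row data.frame with \code{x0, y0, x1, y1}
#'   (half-open, 0-based); default: the whole raster.
#' @param plot_id optional id carried through to the result.
#' @param index_name optional name carried through to the result.
#' @return list of class \code{plot_vi_stats} with \code{mean}, \code{median},
#'   \code{q1}, \code{q3}, \code{whisker_lo}, \code{whisker_hi},
#'   \code{outliers}, \code{n_pixels}, \code{empty}; for zero mask coverage
#'   an explicit empty-plot result (\code{empty = TRUE}, all statistics NA).
#' @export
masked_stats <- function(index, mask, rect = NULL, plot_id = NA,
                         index_name = NA_character_) {
  m <- mask_matrix(mask)
  stopifnot(identical(unname(dim(index)), unname(dim(m))))
  if (!is.null(rect)) {
    index <- crop_rect(index, rect)
    m <- crop_rect(m, rect)
  }
  keep <- m > 0 & !is.na(index)
  x <- index[keep]; w <- m[keep]
  base <- list(plot_id = plot_id, index_name = index_name,
               n_pixels = sum(w))
  if (!length(x)) {
    return(structure(c(base, list(empty = TRUE, mean = NA_real_,
                                  median = NA_real_, q1 = NA_real_,
                                  q3 = NA_real_, whisker_lo = NA_real_,
                                  whisker_hi = NA_real_, outliers = numeric(0))),
                     class = "plot_vi_stats"))
  }
  if (all(w == 1)) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    mu <- mean(x)
  } else {
    q <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
    mu <- sum(w * x) / sum(w)
  }
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(c(base, list(
    empty = FALSE, mean = mu, median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = if (any(inside)) min(x[inside]) else q[1],
    whisker_hi = if (any(inside)) max(x[inside]) else q[3],
    outliers = sort(x[!inside]))), class = "plot_vi_stats")
}

#' @export
print.plot_vi_stats <- function(x, ...) {
  if (x$empty) {
    cat("<plot_vi_stats> plot", x$plot_id, x$index_name, "- EMPTY (no canopy)\n")
  } else {
    cat(sprintf("<plot_vi_stats> plot %s %s: mean %.4f, median %.4f, IQR [%.4f, %.4f], %d outliers, n = %.1f\n",
                x$plot_id, x$index_name, x$mean, x$median, x$q1, x$q3,
                length(x$outliers), x$n_pixels))
  }
  invisible(x)
}

#' Whole-plot index means (heatmap values)
#'
#' One unmasked mean per plot rectangle, matching whole-field index maps.
#'
#' @param index numeric index matrix.
#' @param grid plot grid from [make_plot_grid()].
#' @return data.frame with \code{plot_id} and \code{mean}.
#' @export
vi_heatmap <- function(index, grid) {
  pr <- plot_rects(grid)
  pr$mean <- vapply(seq_len(nrow(pr)), function(i)
    mean(crop_rect(index, pr[i, ]), na.rm = TRUE), numeric(1))
  pr[, c("plot_id", "mean")]
}
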