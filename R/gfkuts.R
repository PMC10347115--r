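# GFKuts canopy segmentation: K-means initialization, GrabCut graph-cut
# refinement, guided-filter smoothing, 0.5 threshold -> binary canopy mask.

#' Pixel matrix of a raster
#'
#' Flattens a multiband raster to an n x bands matrix in column-major pixel
#' order (the order used throughout the segmentation stage).
#'
#' @param raster a \code{multiband_raster}.
#' @return numeric matrix with one row per pixel, one column per band.
#' @export
pixel_matrix <- function(raster) {
  d <- dim(raster$data)
  m <- matrix(raster$data, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- raster$bands
  m
}

# ---- K-means (Lloyd, k-means++ seeding, multi-restart) ----------------------

kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (k in seq_len(K)[-1]) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    centers[k, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
  }
  centers
}

# squared distances of all rows of x to each center (n x K)
dist2_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(sweep(-2 * cross, 2, rowSums(centers^2), "+"), 1, rowSums(x^2), "+")
}

lloyd_once <- function(x, K, max_iter, tol) {
  centers <- kmeanspp_init(x, K)
  trace <- numeric(0)
  labels <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    labels <- max.col(-d2)
    obj <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    trace <- c(trace, obj)
    new_centers <- centers
    for (k in seq_len(K)) {
      idx <- labels == k
      if (any(idx)) new_centers[k, ] <- colMeans(x[idx, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- dist2_to_centers(x, centers)
  labels <- max.col(-d2)
  obj <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(centers = centers, labels = labels, objective = obj,
       objective_trace = c(trace, obj))
}

#' K-means clustering of pixel band vectors
#'
#' Lloyd iterations from k-means++ seeding, repeated over several restarts;
#' the restart with the lowest within-cluster sum of squares is kept. The
#' per-iteration objective trace of the winning restart is returned (it is
#' non-increasing, a property asserted by the test suite).
#'
#' @param pixels n x bands numeric matrix (e.g. from [pixel_matrix()]).
#' @param K number of clusters (>= 2).
#' @param seed integer RNG seed.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param tol center-shift convergence tolerance.
#' @param restarts number of seeded restarts (default 5).
#' @param fit_subsample if non-NULL, centers are fit on this many randomly
#'   chosen pixels and all pixels are then assigned to the fitted centers
#'   (large-scene shortcut).
#' @return object of class \code{kmeans_state}: list with \code{centers},
#'   \code{labels}, \code{objective}, \code{objective_trace}, \code{K}.
#' @export
kmeans_cluster <- function(pixels, K, seed = 1, max_iter = 50, tol = 1e-8,
                           restarts = 5, fit_subsample = NULL) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= K, K >= 2)
  set.seed(seed)
  x <- pixels
  sub_idx <- NULL
  if (!is.null(fit_subsample) && fit_subsample < nrow(pixels)) {
    sub_idx <- sample.int(nrow(pixels), fit_subsample)
    x <- pixels[sub_idx, , drop = FALSE]
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd_once(x, K, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!is.null(sub_idx)) {
    d2 <- dist2_to_centers(pixels, best$centers)
    best$labels <- max.col(-d2)
    best$objective <- sum(d2[cbind(seq_len(nrow(pixels)), best$labels)])
    best$objective_trace <- best$objective
  }
  structure(c(best, list(K = K)), class = "kmeans_state")
}

# ---- Trimap from cluster NDVI ordering --------------------------------------

#' Initial trimap from K-means clusters
#'
#' Orders clusters by their mean NDVI: the highest-NDVI cluster becomes
#' sure-foreground (canopy), the lowest sure-background (soil), any
#' intermediate clusters are left unknown for GrabCut to resolve.
#'
#' @param kmeans a \code{kmeans_state} fit on the raster's pixels (in
#'   [pixel_matrix()] order).
#' @param raster the \code{multiband_raster} the clustering was run on; must
#'   carry \code{NIR} and \code{RED} bands.
#' @return integer matrix of the raster's shape with codes 0 = sure-BG,
#'   1 = sure-FG, 2 = unknown; attribute \code{cluster_ndvi} records the
#'   per-cluster mean NDVI.
#' @export
init_trimap <- function(kmeans, raster) {
  stopifnot(inherits(kmeans, "kmeans_state"), inherits(raster, "multiband_raster"))
  nir <- as.vector(get_band(raster, "NIR"))
  red <- as.vector(get_band(raster, "RED"))
  den <- nir + red
  ndvi <- ifelse(abs(den) < 1e-12, NA_real_, (nir - red) / den)
  if (all(is.na(ndvi))) stop("NDVI undefined everywhere; cannot order clusters")
  cl_ndvi <- vapply(seq_len(kmeans$K), function(k)
    mean(ndvi[kmeans$labels == k], na.rm = TRUE), numeric(1))
  occupied <- which(!is.nan(cl_ndvi))
  fg <- occupied[which.max(cl_ndvi[occupied])]
  bg <- occupied[which.min(cl_ndvi[occupied])]
  code <- rep(2L, kmeans$K)
  code[fg] <- 1L; code[bg] <- 0L
  d <- dim(raster$data)
  tm <- matrix(code[kmeans$labels], nrow = d[1])
  attr(tm, "cluster_ndvi") <- cl_ndvi
  tm
}

# ---- GrabCut ----------------------------------------------------------------

#' GrabCut configuration
#'
#' @param lambda boundary-term weight (>= 0, default 50).
#' @param n_gmm_components maximum Gaussian mixture components per region.
#' @param max_iterations GMM-refit / min-cut iterations.
#' @param connectivity pixel neighborhood, 4 or 8.
#' @param beta contrast scale of the boundary weights; \code{NULL} (default)
#'   sets the canonical \code{1 / (2 * mean squared neighbor color distance)}.
#' @param gmm_subsample pixels subsampled per region when fitting the GMMs.
#' @return list of class \code{grabcut_config}.
#' @export
grabcut_config <- function(lambda = 50, n_gmm_components = 5,
                           max_iterations = 5, connectivity = 8,
                           beta = NULL, gmm_subsample = 3000) {
  stopifnot(lambda >= 0, max_iterations >= 1, connectivity %in% c(4, 8))
  structure(list(lambda = lambda, n_gmm_components = n_gmm_components,
                 max_iterations = max_iterations, connectivity = connectivity,
                 beta = beta, gmm_subsample = gmm_subsample),
            class = "grabcut_config")
}

# neighbor pairs of an nr x nc lattice, column-major linear indices;
# returns matrix cols: i, j, invdist
neighbor_pairs <- function(nr, nc, connectivity = 8) {
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(-1, 1)))
  out <- vector("list", length(offs))
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    ok <- rows + dr >= 1 & rows + dr <= nr & cols + dc >= 1 & cols + dc <= nc
    i <- which(ok)
    j <- i + dr + dc * nr
    out[[k]] <- cbind(i = i, j = j,
                      invdist = 1 / sqrt(dr^2 + dc^2))
  }
  do.call(rbind, out)
}

# Fit a GMM to pixel vectors; robust fallback to a single regularized Gaussian.
fit_gmm <- function(x, n_components, subsample = 3000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(x) > subsample) x <- x[sample.int(nrow(x), subsample), , drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = seq_len(n_components),
                                    modelNames = "VVV", verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit$parameters)) {
    return(list(kind = "mclust", model = fit))
  }
  # degenerate data: single Gaussian with ridge-regularized covariance
  mu <- colMeans(x)
  S <- stats::cov(x) + diag(1e-6, ncol(x))
  list(kind = "gauss", mu = mu, S = S)
}

gmm_log_density <- function(gmm, x) {
  if (gmm$kind == "mclust") {
    d <- mclust::dens(modelName = gmm$model$modelName, data = x,
                      parameters = gmm$model$parameters, logarithm = TRUE)
    return(as.numeric(d))
  }
  p <- ncol(x)
  L <- chol(gmm$S)
  z <- forwardsolve(t(L), t(x) - gmm$mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * p * log(2 * pi)
}

# contrast-sensitive boundary weights for neighbor pairs (excluding lambda)
boundary_weights <- function(pix, pairs, beta = NULL) {
  d2 <- rowSums((pix[pairs[, "i"], , drop = FALSE] -
                 pix[pairs[, "j"], , drop = FALSE])^2)
  if (is.null(beta)) {
    m <- mean(d2)
    beta <- if (m > 0) 1 / (2 * m) else 0
  }
  exp(-beta * d2) * pairs[, "invdist"]
}

# total GrabCut energy of a labeling (1 = FG): data + lambda * boundary
grabcut_energy <- function(labels, Dfg, Dbg, pairs, w, lambda) {
  data_term <- sum(ifelse(labels == 1, Dfg, Dbg))
  cut <- labels[pairs[, "i"]] != labels[pairs[, "j"]]
  data_term + lambda * sum(w[cut])
}

# Min s-t cut over the unknown pixels with frozen region terms.
# Dfg/Dbg: per-pixel region costs (-log likelihood); labels of trimap==2
# pixels are optimized, sure pixels stay fixed.
graphcut_min <- function(Dfg, Dbg, trimap, pairs, w, lambda) {
  tri <- as.integer(trimap)
  unknown <- which(tri == 2L)
  labels <- ifelse(tri == 1L, 1L, ifelse(tri == 0L, 0L, 1L))
  if (!length(unknown)) return(labels)
  id <- integer(length(tri)); id[unknown] <- seq_along(unknown)
  n <- length(unknown)
  src <- n + 1L; snk <- n + 2L
  # t-links: cap(s->i) = cost of labeling BG, cap(i->t) = cost of labeling FG.
  # -log likelihoods may be negative; shift both by the per-node minimum
  # (the cut depends only on their difference, capacities must be >= 0)
  cap_s <- Dbg[unknown]
  cap_t <- Dfg[unknown]
  base_shift <- pmin(cap_s, cap_t)
  cap_s <- cap_s - base_shift
  cap_t <- cap_t - base_shift
  iu <- tri[pairs[, "i"]] == 2L
  ju <- tri[pairs[, "j"]] == 2L
  both <- iu & ju
  e_from <- id[pairs[both, "i"]]; e_to <- id[pairs[both, "j"]]
  e_cap <- lambda * w[both]
  # pairs with one sure endpoint fold into t-links of the unknown endpoint
  mix_i <- iu & !ju
  if (any(mix_i)) {
    ui <- id[pairs[mix_i, "i"]]
    sure_fg <- tri[pairs[mix_i, "j"]] == 1L
    cap_s <- cap_s + unname(tapply_add(n, ui[sure_fg], lambda * w[mix_i][sure_fg]))
    cap_t <- cap_t + unname(tapply_add(n, ui[!sure_fg], lambda * w[mix_i][!sure_fg]))
  }
  mix_j <- ju & !iu
  if (any(mix_j)) {
    uj <- id[pairs[mix_j, "j"]]
    sure_fg <- tri[pairs[mix_j, "i"]] == 1L
    cap_s <- cap_s + unname(tapply_add(n, uj[sure_fg], lambda * w[mix_j][sure_fg]))
    cap_t <- cap_t + unname(tapply_add(n, uj[!sure_fg], lambda * w[mix_j][!sure_fg]))
  }
  edges <- rbind(cbind(rep(src, n), seq_len(n)),
                 cbind(seq_len(n), rep(snk, n)),
                 cbind(e_from, e_to))
  caps <- c(cap_s, cap_t, e_cap)
  # igraph max-flow on a directed graph; n-links added in both directions
  if (length(e_from)) {
    edges <- rbind(edges, cbind(e_to, e_from))
    caps <- c(caps, e_cap)
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  fl <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  fg_side <- rep(FALSE, n)
  part1 <- as.integer(fl$partition1)
  fg_side[part1[part1 <= n]] <- TRUE
  labels[unknown] <- as.integer(fg_side)
  labels
}

# accumulate values into an n-vector at (possibly repeated) indices
tapply_add <- function(n, idx, val) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(val, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

#' GrabCut refinement of a trimap
#'
#' Iterates: fit per-region Gaussian mixture color models on the current
#' labeling, build an s-t graph whose terminal capacities are the negative
#' log-likelihoods and whose neighbor capacities are contrast-weighted Potts
#' terms, and solve the minimum cut. Sure trimap pixels never flip. The
#' energy \eqn{E(f) = R(f) + \lambda B(f)} is tracked per iteration and the
#' loop stops (reverting) if it would increase.
#'
#' @param raster a \code{multiband_raster}.
#' @param trimap integer matrix from [init_trimap()] (0 BG / 1 FG / 2 unknown).
#' @param config a [grabcut_config()].
#' @param seed RNG seed for the GMM subsampling.
#' @return list of class \code{grabcut_result}: \code{labels} (0/1 matrix),
#'   \code{energy_trace}, \code{iterations}.
#' @export
grabcut_refine <- function(raster, trimap, config = grabcut_config(), seed = 1) {
  stopifnot(inherits(raster, "multiband_raster"))
  tri <- as.integer(trimap)
  if (!any(tri == 1L) || !any(tri == 0L))
    stop("trimap needs at least one sure-FG and one sure-BG pixel")
  pix <- pixel_matrix(raster)
  d <- dim(raster$data)
  pairs <- neighbor_pairs(d[1], d[2], config$connectivity)
  w <- boundary_weights(pix, pairs, config$beta)
  labels <- ifelse(tri == 2L, 1L, tri)  # unknown starts as FG
  set.seed(seed)
  energy_trace <- numeric(0)
  prev_E <- Inf
  it_done <- 0
  for (it in seq_len(config$max_iterations)) {
    fg_px <- pix[labels == 1L, , drop = FALSE]
    bg_px <- pix[labels == 0L, , drop = FALSE]
    if (!nrow(fg_px) || !nrow(bg_px)) stop("a region became empty during GrabCut")
    gmm_fg <- fit_gmm(fg_px, config$n_gmm_components, config$gmm_subsample)
    gmm_bg <- fit_gmm(bg_px, config$n_gmm_components, config$gmm_subsample)
    Dfg <- -gmm_log_density(gmm_fg, pix)
    Dbg <- -gmm_log_density(gmm_bg, pix)
    new_labels <- graphcut_min(Dfg, Dbg, tri, pairs, w, config$lambda)
    E <- grabcut_energy(new_labels, Dfg, Dbg, pairs, w, config$lambda)
    if (E > prev_E + 1e-9) break  # refit increased the energy: keep previous
    energy_trace <- c(energy_trace, E)
    changed <- any(new_labels != labels)
    labels <- new_labels
    prev_E <- E
    it_done <- it
    if (!changed) break
  }
  structure(list(labels = matrix(labels, nrow = d[1]),
                 energy_trace = energy_trace, iterations = it_done),
            class = "grabcut_result")
}

# ---- Guided filter ----------------------------------------------------------

#' Guided filter configuration
#'
#' @param window_radius box-window radius in pixels (>= 1, default 4).
#' @param epsilon regularization (>= 0, default 1e-3).
#' @return list of class \code{guided_filter_config}.
#' @export
guided_filter_config <- function(window_radius = 4, epsilon = 1e-3) {
  stopifnot(window_radius >= 1, epsilon >= 0)
  structure(list(window_radius = window_radius, epsilon = epsilon),
            class = "guided_filter_config")
}

# box mean with window clipped at borders (summed-area table)
box_mean <- function(m, r) {
  box_sum(m, r) / box_sum(matrix(1, nrow(m), ncol(m)), r)
}

box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2, cumsum)
  hi <- pmin(seq_len(nr) + r, nr); lo <- seq_len(nr) - r - 1
  rows <- cs[hi, , drop = FALSE] -
    rbind(matrix(0, sum(lo < 1), nc), cs[lo[lo >= 1], , drop = FALSE])
  cs2 <- t(apply(rows, 1, cumsum))
  if (nc == 1) cs2 <- t(cs2)
  hi <- pmin(seq_len(nc) + r, nc); lo <- seq_len(nc) - r - 1
  cs2[, hi, drop = FALSE] -
    cbind(matrix(0, nr, sum(lo < 1)), cs2[, lo[lo >= 1], drop = FALSE])
}

#' Edge-preserving guided filter
#'
#' Expresses the output as a local linear function of the guidance image:
#' within each box window k, the coefficients
#' \code{a_k = cov(I, p) / (var(I) + eps)} and
#' \code{b_k = mean(p) - a_k mean(I)} solve the ridge-regularized local
#' least-squares fit; each output pixel averages (a, b) over every window
#' containing it, then applies \code{q_i = a I_i + b}.
#'
#' @param guidance single-band guidance image I (matrix).
#' @param input input image p (matrix, same shape).
#' @param config a [guided_filter_config()].
#' @return filtered matrix q.
#' @export
guided_filter <- function(guidance, input, config = guided_filter_config()) {
  if (!identical(unname(dim(guidance)), unname(dim(input))))
    stop("guidance and input must have the same shape")
  r <- config$window_radius; eps <- config$epsilon
  mI <- box_mean(guidance, r)
  mp <- box_mean(input, r)
  corrI <- box_mean(guidance * guidance, r)
  corrIp <- box_mean(guidance * input, r)
  varI <- pmax(corrI - mI * mI, 0)
  covIp <- corrIp - mI * mp
  a <- covIp / (varI + eps)
  a[!is.finite(a)] <- 0  # eps = 0 in a flat window: fall back to the box mean
  b <- mp - a * mI
  box_mean(a, r) * guidance + box_mean(b, r)
}

# ---- Full GFKuts pipeline ---------------------------------------------------

#' GFKuts parameters
#'
#' @param K K-means cluster count (default 3: canopy / soil / mixed).
#' @param kmeans_restarts,kmeans_max_iter,kmeans_fit_subsample K-means controls.
#' @param grabcut a [grabcut_config()].
#' @param guided a [guided_filter_config()].
#' @param threshold binarization threshold on the filtered soft mask.
#' @param min_canopy_ndvi if the highest cluster mean NDVI falls below this,
#'   the scene is declared canopy-free (all-zero mask, \code{no_canopy} flag).
#' @return list of class \code{gfkuts_params}.
#' @export
gfkuts_params <- function(K = 3, kmeans_restarts = 5, kmeans_max_iter = 30,
                          kmeans_fit_subsample = 200000,
                          grabcut = grabcut_config(),
                          guided = guided_filter_config(),
                          threshold = 0.5, min_canopy_ndvi = 0.3) {
  structure(list(K = K, kmeans_restarts = kmeans_restarts,
                 kmeans_max_iter = kmeans_max_iter,
                 kmeans_fit_subsample = kmeans_fit_subsample,
                 grabcut = grabcut, guided = guided, threshold = threshold,
                 min_canopy_ndvi = min_canopy_ndvi),
            class = "gfkuts_params")
}

gfkuts_segment_one <- function(raster, params, seed) {
  pix <- pixel_matrix(raster)
  km <- kmeans_cluster(pix, params$K, seed = seed,
                       max_iter = params$kmeans_max_iter,
                       restarts = params$kmeans_restarts,
                       fit_subsample = params$kmeans_fit_subsample)
  tm <- init_trimap(km, raster)
  cl_ndvi <- attr(tm, "cluster_ndvi")
  if (max(cl_ndvi, na.rm = TRUE) < params$min_canopy_ndvi) {
    m <- canopy_mask(matrix(0, nrow(tm), ncol(tm)), binary = TRUE)
    attr(m, "no_canopy") <- TRUE
    return(m)
  }
  labels <- if (any(tm == 2L)) {
    grabcut_refine(raster, tm, params$grabcut, seed = seed)$labels
  } else {
    matrix(as.integer(tm == 1L), nrow(tm))
  }
  soft <- guided_filter(get_band(raster, "NIR"), labels + 0, params$guided)
  m <- canopy_mask((soft >= params$threshold) + 0, binary = TRUE)
  attr(m, "no_canopy") <- FALSE
  m
}

#' GFKuts canopy segmentation
#'
#' Full pipeline: K-means clustering, NDVI-ordered trimap, GrabCut graph-cut
#' refinement, guided-filter smoothing with the NIR band as guidance, and a
#' 0.5 threshold producing the binary canopy mask. Deterministic for a fixed
#' seed. When a grid is supplied the field is segmented plot-by-plot (each
#' plot rectangle expanded by half the inter-plot gap), which keeps the graph
#' cut problems small on large scenes; pixels outside every expanded
#' rectangle are labeled background.
#'
#' @param raster a 5-band \code{multiband_raster}.
#' @param params a [gfkuts_params()].
#' @param grid optional plot grid from [make_plot_grid()] for tiled
#'   segmentation.
#' @param expand tile expansion in pixels when \code{grid} is used.
#' @param seed integer RNG seed.
#' @return binary \code{canopy_mask}; attribute \code{no_canopy} is TRUE when
#'   no cluster reached the canopy NDVI floor.
#' @export
gfkuts_segment <- function(raster, params = gfkuts_params(), grid = NULL,
                           expand = 4, seed = 1) {
  stopifnot(inherits(raster, "multiband_raster"))
  if (is.null(grid)) return(gfkuts_segment_one(raster, params, seed))
  d <- dim(raster$data)
  out <- matrix(0, d[1], d[2])
  any_canopy <- FALSE
  pr <- plot_rects(grid)
  for (i in seq_len(nrow(pr))) {
    r <- pr[i, ]
    x0 <- max(r$x0 - expand, 0); y0 <- max(r$y0 - expand, 0)
    x1 <- min(r$x1 + expand, d[2]); y1 <- min(r$y1 + expand, d[1])
    tile <- multiband_raster(raster$data[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE],
                             raster$bands)
    m <- gfkuts_segment_one(tile, params, seed = seed + r$plot_id)
    if (!isTRUE(attr(m, "no_canopy"))) any_canopy <- TRUE
    out[(y0 + 1):y1, (x0 + 1):x1] <- pmax(out[(y0 + 1):y1, (x0 + 1):x1],
                                          mask_matrix(m))
  }
  m <- canopy_mask(out, binary = TRUE)
  attr(m, "no_canopy") <- !any_canopy
  m
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b binary matrices / \code{canopy_mask}s of the same shape.
#' @return IoU in [0, 1]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- mask_matrix(unclass(a)) > 0.5; b <- mask_matrix(unclass(b)) > 0.5
  stopifnot(identical(unname(dim(a)), unname(dim(b))))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
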