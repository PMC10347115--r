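# K-means, trimap, GrabCut, guided filter, and the assembled segmentation.

test_that("k-means separates two well-separated pixel populations exactly", {
  px <- rbind(matrix(0.1, 20, 5), matrix(0.9, 30, 5))
  km <- kmeans_cluster(px, K = 2, seed = 1)
  expect_equal(length(unique(km$labels[1:20])), 1)
  expect_equal(length(unique(km$labels[21:50])), 1)
  expect_false(km$labels[1] == km$labels[50])
  expect_equal(sort(km$centers[, 1]), c(0.1, 0.9), tolerance = 1e-12)
  expect_equal(km$objective, 0, tolerance = 1e-12)
})

test_that("the Lloyd objective is non-increasing across iterations", {
  set.seed(3)
  for (rep in 1:5) {
    px <- matrix(runif(60 * 3), 60, 3)
    km <- kmeans_cluster(px, K = 3, seed = rep, restarts = 1)
    expect_monotone_nonincreasing(km$objective_trace)
  }
})

test_that("multi-restart k-means attains the exhaustive two-partition optimum on tiny inputs", {
  # brute-force oracle (helper-oracles.R): minimal within-cluster sum of
  # squares over every assignment of n <= 10 points into 2 non-empty clusters
  set.seed(11)
  for (rep in 1:4) {
    x <- matrix(runif(9 * 2), 9, 2)
    want <- brute_kmeans2(x)
    km <- kmeans_cluster(x, K = 2, seed = rep, restarts = 20)
    expect_equal(km$objective, want, tolerance = 1e-8)
  }
})

test_that("k-means agrees with the reference implementation on the attained objective", {
  set.seed(5)
  x <- matrix(runif(200 * 4), 200, 4)
  km <- kmeans_cluster(x, K = 3, seed = 2, restarts = 10)
  ref <- kmeans(x, centers = 3, nstart = 10, iter.max = 50,
                algorithm = "Lloyd")
  expect_equal(km$objective, ref$tot.withinss, tolerance = 0.02)
})

test_that("trimap orders clusters by NDVI: pure two-class scene has no unknown", {
  r <- two_region_raster()
  km <- kmeans_cluster(pixel_matrix(r), K = 2, seed = 1)
  tm <- init_trimap(km, r)
  expect_true(all(tm %in% c(0L, 1L)))
  # canopy columns (right half) are sure-FG
  expect_true(all(tm[, 6:10] == 1L))
  expect_true(all(tm[, 1:5] == 0L))
})

test_that("K = 3 with an intermediate population marks it unknown", {
  arr <- array(0, dim = c(6, 9, 5))
  # columns 1-3 soil, 4-6 mixed, 7-9 canopy; NDVI strictly increasing
  red <- c(0.30, 0.20, 0.05); nir <- c(0.33, 0.45, 0.60)
  for (k in 1:3) {
    cols <- (3 * k - 2):(3 * k)
    arr[, cols, 1] <- 0.1; arr[, cols, 2] <- 0.15
    arr[, cols, 3] <- red[k]; arr[, cols, 4] <- 0.3; arr[, cols, 5] <- nir[k]
  }
  r <- multiband_raster(arr, c("BLUE", "GREEN", "RED", "REG", "NIR"))
  km <- kmeans_cluster(pixel_matrix(r), K = 3, seed = 2)
  tm <- init_trimap(km, r)
  expect_true(all(tm[, 1:3] %in% c(0L, 1L, 2L)))
  expect_equal(sort(unique(as.vector(tm))), c(0L, 1L, 2L))
  expect_true(all(tm[, 4:6] == 2L))  # the intermediate block is unknown
})

test_that("trimap sure-FG is precise against the truth mask on a noisy scene", {
  s <- small_scene(n_plots = 4, seed = 17, noise_sd = 0.02)
  km <- kmeans_cluster(pixel_matrix(s$raster), K = 3, seed = 1)
  tm <- init_trimap(km, s$raster)
  fg <- tm == 1L
  precision <- sum(fg & unclass(s$truth_mask) == 1) / sum(fg)
  expect_gte(precision, 0.95)
})

test_that("with lambda = 0 GrabCut reduces to the per-pixel likelihood argmax", {
  set.seed(4)
  r <- two_region_raster(noise = 0.01, seed = 4)
  km <- kmeans_cluster(pixel_matrix(r), K = 2, seed = 1)
  tm <- init_trimap(km, r)
  tm[3:6, 4:7] <- 2L  # open an unknown window spanning the boundary
  res <- grabcut_refine(r, tm, grabcut_config(lambda = 0, max_iterations = 1),
                        seed = 2)
  # recompute the likelihoods the refinement used and compare pixelwise
  pix <- pixel_matrix(r)
  set.seed(2)
  gmm_fg <- ricecanopy:::fit_gmm(pix[tm != 0L, , drop = FALSE], 5, 3000)
  gmm_bg <- ricecanopy:::fit_gmm(pix[tm == 0L, , drop = FALSE], 5, 3000)
  Dfg <- -ricecanopy:::gmm_log_density(gmm_fg, pix)
  Dbg <- -ricecanopy:::gmm_log_density(gmm_bg, pix)
  unknown <- as.vector(tm) == 2L
  expect_equal(as.vector(res$labels)[unknown],
               as.integer(Dfg < Dbg)[unknown])
})

test_that("GrabCut energy is non-increasing and sure pixels never flip", {
  s <- small_scene(n_plots = 1, seed = 23, noise_sd = 0.03)
  km <- kmeans_cluster(pixel_matrix(s$raster), K = 3, seed = 1)
  tm <- init_trimap(km, s$raster)
  res <- grabcut_refine(s$raster, tm, grabcut_config(max_iterations = 4),
                        seed = 5)
  expect_monotone_nonincreasing(res$energy_trace)
  expect_true(all(res$labels[tm == 1L] == 1L))
  expect_true(all(res$labels[tm == 0L] == 0L))
})

test_that("the min-cut labeling attains the exhaustive minimum over <= 12 unknown pixels", {
  set.seed(9)
  for (rep in 1:3) {
    nr <- 4; nc <- 5
    arr <- array(runif(nr * nc * 5), dim = c(nr, nc, 5))
    r <- multiband_raster(arr, c("BLUE", "GREEN", "RED", "REG", "NIR"))
    pix <- pixel_matrix(r)
    tri <- matrix(0L, nr, nc)
    tri[, nc] <- 1L
    unknown_idx <- sample(which(tri == 0L & col(tri) < nc), 12)
    tri[unknown_idx] <- 2L
    # frozen region terms (arbitrary but fixed)
    Dfg <- runif(nr * nc, 0, 5)
    Dbg <- runif(nr * nc, 0, 5)
    pairs <- ricecanopy:::neighbor_pairs(nr, nc, 8)
    w <- ricecanopy:::boundary_weights(pix, pairs)
    lambda <- 2
    got <- ricecanopy:::graphcut_min(Dfg, Dbg, tri, pairs, w, lambda)
    E_got <- ricecanopy:::grabcut_energy(got, Dfg, Dbg, pairs, w, lambda)
    # exhaustive oracle over all 2^12 labelings of the unknown pixels
    base <- ifelse(as.vector(tri) == 1L, 1L, 0L)
    unk <- which(as.vector(tri) == 2L)
    E_min <- Inf
    for (code in 0:(2^length(unk) - 1)) {
      lab <- base
      lab[unk] <- as.integer(intToBits(code))[seq_along(unk)]
      E <- ricecanopy:::grabcut_energy(lab, Dfg, Dbg, pairs, w, lambda)
      if (E < E_min) E_min <- E
    }
    expect_equal(E_got, E_min, tolerance = 1e-9)
  }
})

test_that("guided filter: p = I with eps = 0 is exact; constant guidance gives the box mean", {
  set.seed(6)
  I <- matrix(runif(12 * 15), 12, 15)
  q <- guided_filter(I, I, guided_filter_config(3, 0))
  expect_lt(max(abs(q - I)), 1e-12)
  # constant guidance: a = 0 everywhere, so the output is the window
  # average of b = box-mean of p, i.e. the box mean applied twice
  const <- matrix(0.7, 12, 15)
  p <- matrix(runif(12 * 15), 12, 15)
  q2 <- guided_filter(const, p, guided_filter_config(3, 1e-3))
  bm2 <- ricecanopy:::box_mean(ricecanopy:::box_mean(p, 3), 3)
  expect_lt(max(abs(q2 - bm2)), 1e-10)
  expect_error(guided_filter(I, p[1:5, ]), "same shape")
})

test_that("guided filter matches the per-window least-squares brute force", {
  set.seed(7)
  n <- 9; r <- 2; eps <- 0.01
  I <- matrix(runif(n * n), n, n)
  p <- matrix(runif(n * n), n, n)
  q <- guided_filter(I, p, guided_filter_config(r, eps))
  # brute force: solve the ridge least squares in every window, then average
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    wi <- max(1, i - r):min(n, i + r); wj <- max(1, j - r):min(n, j + r)
    Iv <- as.vector(I[wi, wj]); pv <- as.vector(p[wi, wj])
    covIp <- mean(Iv * pv) - mean(Iv) * mean(pv)
    varI <- mean(Iv^2) - mean(Iv)^2
    a[i, j] <- covIp / (varI + eps)
    b[i, j] <- mean(pv) - a[i, j] * mean(Iv)
  }
  qb <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    wi <- max(1, i - r):min(n, i + r); wj <- max(1, j - r):min(n, j + r)
    qb[i, j] <- mean(a[wi, wj]) * I[i, j] + mean(b[wi, wj])
  }
  expect_lt(max(abs(q - qb)), 1e-10)
})

test_that("guided filter tends to pure box smoothing as eps grows", {
  set.seed(8)
  I <- matrix(runif(100), 10, 10)
  p <- matrix(runif(100), 10, 10)
  q <- guided_filter(I, p, guided_filter_config(2, 1e9))
  # eps -> Inf drives a -> 0 and b -> box-mean of p; the per-pixel window
  # average then yields the box mean applied twice
  bm2 <- ricecanopy:::box_mean(ricecanopy:::box_mean(p, 2), 2)
  expect_lt(max(abs(q - bm2)), 1e-6)
})

test_that("full GFKuts run: perfect recovery when noiseless, bit-identical re-runs", {
  s0 <- small_scene(n_plots = 2, seed = 31, noise_sd = 0)
  m0 <- gfkuts_segment(s0$raster, gfkuts_params(), grid = s0$grid, seed = 2)
  # interior pixels (eroded by the guided-filter radius + 1) match exactly
  r <- gfkuts_params()$guided$window_radius + 1
  tm <- unclass(s0$truth_mask)
  interior <- tm * 0
  d <- dim(tm)
  for (dy in -r:r) for (dx in -r:r) {
    shifted <- tm[pmin(pmax(seq_len(d[1]) + dy, 1), d[1]),
                  pmin(pmax(seq_len(d[2]) + dx, 1), d[2])]
    interior <- interior + (shifted == tm)
  }
  core <- interior == (2 * r + 1)^2  # pixels far from any class boundary
  expect_equal(unclass(m0)[core], tm[core])

  m0b <- gfkuts_segment(s0$raster, gfkuts_params(), grid = s0$grid, seed = 2)
  expect_identical(unclass(m0), unclass(m0b))
})

test_that("an all-soil scene is flagged as canopy-free", {
  set.seed(12)
  soil <- c(0.10, 0.14, 0.18, 0.22, 0.26)
  arr <- array(0, dim = c(40, 40, 5))
  for (b in 1:5) arr[, , b] <- soil[b] + matrix(rnorm(1600, 0, 0.01), 40)
  r <- multiband_raster(pmin(pmax(arr, 0), 1),
                        c("BLUE", "GREEN", "RED", "REG", "NIR"))
  m <- gfkuts_segment(r, gfkuts_params(), seed = 3)
  expect_true(isTRUE(attr(m, "no_canopy")) || mean(m) < 0.01)
})
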