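# Independent brute-force / closed-form oracles used by the unit and
# acceptance tests. These deliberately avoid the package's own code paths.

# exhaustive 2-partition within-cluster sum of squares for n <= 10 points
brute_kmeans2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code))[1:n]
    obj <- 0
    for (k in 0:1) {
      xk <- x[lab == k, , drop = FALSE]
      if (nrow(xk)) obj <- obj + sum(sweep(xk, 2, colMeans(xk))^2)
    }
    if (obj < best) best <- obj
  }
  best
}

# per-window ridge least squares + window averaging, solved window by window
brute_guided_filter <- function(I, p, r, eps) {
  n1 <- nrow(I); n2 <- ncol(I)
  a <- matrix(0, n1, n2); b <- matrix(0, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    wi <- max(1, i - r):min(n1, i + r); wj <- max(1, j - r):min(n2, j + r)
    Iv <- as.vector(I[wi, wj]); pv <- as.vector(p[wi, wj])
    covIp <- mean(Iv * pv) - mean(Iv) * mean(pv)
    varI <- mean(Iv^2) - mean(Iv)^2
    a[i, j] <- covIp / (varI + eps)
    b[i, j] <- mean(pv) - a[i, j] * mean(Iv)
  }
  q <- matrix(0, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    wi <- max(1, i - r):min(n1, i + r); wj <- max(1, j - r):min(n2, j + r)
    q[i, j] <- mean(a[wi, wj]) * I[i, j] + mean(b[wi, wj])
  }
  q
}

# scalar evaluation of all ten vegetation indices at a single pixel
scalar_vi_oracle <- function(B, G, R, RE, N, L = 0.5, eG = 2.5, C1 = 6,
                             C2 = 7.5, eL = 1, gamma = 1) {
  ndvi <- (N - R) / (N + R)
  rb <- R - gamma * (B - R)
  c(DVI = N - R,
    NDVI = ndvi,
    GNDVI = (N - G) / (N + G),
    SAVI = (1 + L) * (N - R) / (N + R + L),
    MSAVI = (2 * N + 1 - sqrt((2 * N + 1)^2 - 8 * (N - R))) / 2,
    CTVI = sign(ndvi + 0.5) * sqrt(abs(ndvi + 0.5)),
    SR = N / R,
    TVI = sqrt(ndvi + 0.5),
    EVI = eG * (N - R) / (N + C1 * R - C2 * B + eL),
    ARVI = (N - rb) / (N + rb))
}

# direct evaluation of the two printed pixel-to-ground formulas
ortho_oracle <- function(x, y, cx, cy, H, h, phi, X0, Y0) {
  c(X = (x - cx) * H / h - (y - cy) * tan(phi) * H / h + X0,
    Y = (y - cy) * H / h * cos(phi) + Y0)
}
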