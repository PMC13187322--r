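# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (loops, brute force) and never share code with the
# implementation paths they check.

# brute-force disc dilation: pixel in dilation iff any mask pixel lies
# within radius (Euclidean)
oracle_dilate <- function(mask, radius) {
  ny <- nrow(mask); nx <- ncol(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, ny, nx)
  if (!nrow(pts)) return(out)
  for (y in seq_len(ny))
    for (x in seq_len(nx))
      out[y, x] <- min((pts[, 1] - y)^2 + (pts[, 2] - x)^2) <= radius^2
  out
}

# explicit 2-D kernel convolution with symmetric padding (delta responses)
oracle_gaussian_delta <- function(n, sigma) {
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# brute-force moment-preserving threshold: per candidate level, solve the
# two-level fit preserving mean and variance via polyroot, keep the level
# minimising the third-moment mismatch
oracle_moments_threshold <- function(x) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  edges <- seq(lo, hi, length.out = 257)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), 256)
  counts <- tabulate(idx, 256)
  mids <- (edges[-257] + edges[-1]) / 2
  p <- counts / sum(counts)
  m1 <- sum(p * mids); m2 <- sum(p * mids^2); m3 <- sum(p * mids^3)
  best <- Inf; best_k <- 1L
  cum <- 0
  for (k in 1:255) {
    cum <- cum + p[k]
    p0 <- cum; p1 <- 1 - cum
    if (p0 <= 0 || p1 <= 0) next
    # p0*z0 + p1*z1 = m1 ; p0*z0^2 + p1*z1^2 = m2, z1 eliminated
    a2 <- p0 + p0^2 / p1
    a1 <- -2 * p0 * m1 / p1
    a0 <- m1^2 / p1 - m2
    roots <- Re(polyroot(c(a0, a1, a2)))
    z0 <- min(roots)
    z1 <- (m1 - p0 * z0) / p1
    err <- abs(p0 * z0^3 + p1 * z1^3 - m3)
    if (err < best) { best <- err; best_k <- k }
  }
  (mids[best_k] + mids[min(best_k + 1L, 256L)]) / 2
}

# Monte-Carlo propagation oracle (Gaussian resampling)
oracle_mc_propagate <- function(a, b, op, n = 1e5, seed = 42) {
  set.seed(seed)
  xa <- rnorm(n, a$value, a$sem)
  xb <- rnorm(n, b$value, b$sem)
  v <- if (op == "difference") xa - xb else xa / xb
  c(value = mean(v), sem = sd(v))
}

# finite-difference Hessian of a smoothed toy image at one pixel
oracle_hessian_lambda2 <- function(image, sigma, y, x) {
  sm <- gaussian_blur(image, sigma)
  ixx <- sm[y, x + 1] + sm[y, x - 1] - 2 * sm[y, x]
  iyy <- sm[y + 1, x] + sm[y - 1, x] - 2 * sm[y, x]
  ixy <- (sm[y + 1, x + 1] + sm[y - 1, x - 1] -
          sm[y - 1, x + 1] - sm[y + 1, x - 1]) / 4
  (ixx + iyy) / 2 - sqrt(((ixx - iyy) / 2)^2 + ixy^2)
}
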