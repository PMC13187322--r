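# Automatic histogram thresholds (256-bin): Otsu and the moment-preserving
# ("Moments") method of Tsai. Both operate on a 256-bin histogram spanning
# the data range, so the resulting masks are invariant to positive
# rescaling of the image.

hist256 <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values to threshold")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(list(counts = length(x), mids = lo, degenerate = TRUE))
  edges <- seq(lo, hi, length.out = 257L)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), 256L)
  list(counts = tabulate(idx, 256L), mids = (edges[-257] + edges[-1]) / 2,
       degenerate = FALSE)
}

#' Otsu threshold
#'
#' Maximises the between-class variance over a 256-bin histogram. Returns
#' the threshold value (midpoint between the optimal bin and the next); the
#' foreground is `image > threshold`.
#'
#' @param x numeric vector or matrix of intensities.
#' @return numeric threshold.
#' @export
threshold_otsu <- function(x) {
  h <- hist256(x)
  if (h$degenerate) return(h$mids[1])
  p <- h$counts / sum(h$counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- mu[256]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, -Inf)
  k <- which.max(bcv[-256])  # ties -> lowest index
  (h$mids[k] + h$mids[k + 1]) / 2
}

#' Moment-preserving (Tsai / ImageJ "Moments") threshold
#'
#' Selects the histogram level whose two-level reduction best preserves the
#' first three moments of the image: for each candidate level the below/
#' above fractions fix the two representative gray values that preserve the
#' mean and variance, and the level minimising the third-moment mismatch is
#' chosen.
#'
#' @param x numeric vector or matrix of intensities.
#' @return numeric threshold; the foreground is `x > threshold`.
#' @export
threshold_moments <- function(x) {
  h <- hist256(x)
  if (h$degenerate) return(h$mids[1])
  p <- h$counts / sum(h$counts)
  v <- h$mids
  m1 <- sum(p * v)
  m2 <- sum(p * v^2)
  m3 <- sum(p * v^3)
  s2 <- m2 - m1^2
  if (s2 <= 0) return(v[1])
  p0 <- cumsum(p)
  p1 <- 1 - p0
  ok <- p0 > 0 & p1 > 0
  z0 <- m1 - sqrt(s2 * p1 / p0)  # preserve m1, m2 given the split p0
  z1 <- m1 + sqrt(s2 * p0 / p1)
  err <- abs(p0 * z0^3 + p1 * z1^3 - m3)
  err[!ok] <- Inf
  k <- which.min(err)
  (v[k] + v[min(k + 1L, 256L)]) / 2
}

#' Apply a configured threshold method
#'
#' @param x numeric vector or matrix.
#' @param method `"otsu"`, `"moments"` or `"fixed"`.
#' @param value fixed threshold (required for `"fixed"`).
#' @return numeric threshold.
#' @export
auto_threshold <- function(x, method = c("otsu", "moments", "fixed"),
                           value = NULL) {
  method <- match.arg(method)
  switch(method,
         otsu = threshold_otsu(x),
         moments = threshold_moments(x),
         fixed = {
           if (is.null(value)) stop("fixed threshold requires a value")
           as.numeric(value)
         })
}
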