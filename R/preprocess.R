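# Shared preprocessing operators: Gaussian blur, rolling-ball background
# subtraction, membrane-maximum normalisation.

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with reflective boundary handling
#'
#' Separable Gaussian filter; `sigma_px = 0` returns the input unchanged.
#' Reflective padding keeps the total intensity conserved up to boundary
#' effects and avoids rim artefacts on shell-shaped membrane images.
#'
#' @param image numeric matrix.
#' @param sigma_px Gaussian sigma in pixels (>= 0).
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sigma_px) {
  stopifnot(is.matrix(image), is.numeric(sigma_px), length(sigma_px) == 1L)
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(image)
  cpp_conv_sep(image, gaussian_kernel(sigma_px))
}

# Structuring element of a ball (sphere cap heights) of the given radius.
ball_se <- function(radius) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- off$dy^2 + off$dx^2
  keep <- d2 <= radius^2
  list(dy = as.integer(off$dy[keep]), dx = as.integer(off$dx[keep]),
       h = sqrt(pmax(radius^2 - d2[keep], 0)))
}

# ImageJ-style shrink factor for large ball radii.
rb_shrink <- function(radius) {
  if (radius <= 10) 1L else if (radius <= 30) 2L else if (radius <= 100) 4L
  else 8L
}

block_min <- function(image, s) {
  ny <- nrow(image); nx <- ncol(image)
  ny2 <- ceiling(ny / s); nx2 <- ceiling(nx / s)
  # pad by edge replication to a multiple of s
  yi <- pmin(seq_len(ny2 * s), ny)
  xi <- pmin(seq_len(nx2 * s), nx)
  img <- image[yi, xi, drop = FALSE]
  out <- matrix(Inf, ny2, nx2)
  for (i in seq_len(s))
    for (j in seq_len(s))
      out <- pmin(out, img[seq(i, by = s, length.out = ny2),
                           seq(j, by = s, length.out = nx2), drop = FALSE])
  out
}

resize_bilinear <- function(image, ny, nx, s) {
  # inverse of block_min sampling: small-pixel centres sit at
  # original coordinate (i - 0.5) * s + 0.5 for block index i
  src_y <- ((seq_len(nrow(image)) - 0.5) * s) + 0.5
  src_x <- ((seq_len(ncol(image)) - 0.5) * s) + 0.5
  ty <- pmin(pmax(seq_len(ny), src_y[1]), src_y[length(src_y)])
  tx <- pmin(pmax(seq_len(nx), src_x[1]), src_x[length(src_x)])
  rows <- apply(image, 2, function(col) approx(src_y, col, ty)$y)
  t(apply(rows, 1, function(row) approx(src_x, row, tx)$y))
}

#' Rolling-ball background estimate
#'
#' Grayscale morphological opening with a ball structuring element: the
#' upper envelope of a ball of the given radius rolled beneath the
#' intensity surface. For radii above 10 px the image is shrunk by block
#' minimum (factor 2/4/8 as in the Fiji implementation), the ball rolled on
#' the reduced image, and the background bilinearly interpolated back; it
#' is finally clamped below the image.
#'
#' The ball height is calibrated to the image dynamic range (the 8-bit
#' convention: a radius-50 ball spans 50/255 of the range), which makes the
#' operator positively homogeneous — multiplying the image by a constant
#' scales the background by the same constant, so downstream enrichment
#' statistics are exactly scale invariant.
#'
#' @param image numeric matrix.
#' @param radius_px ball radius in pixels (>= 1).
#' @return background matrix, same shape, `<= image` everywhere.
#' @export
rolling_ball_background <- function(image, radius_px) {
  stopifnot(is.matrix(image))
  if (!is.numeric(radius_px) || radius_px < 1)
    stop("radius_px must be >= 1")
  zscale <- diff(range(image)) / 255
  s <- rb_shrink(radius_px)
  small <- if (s > 1L) block_min(image, s) else image
  se <- ball_se(max(radius_px / s, 1))
  h <- se$h * zscale
  er <- cpp_morph(small, se$dy, se$dx, h, TRUE)
  bg <- cpp_morph(er, se$dy, se$dx, h, FALSE)
  if (s > 1L) bg <- resize_bilinear(bg, nrow(image), ncol(image), s)
  pmin(bg, image)
}

#' Rolling-ball background subtraction
#'
#' Subtracts [rolling_ball_background()] and clamps at zero, the standard
#' confocal background correction (default radius 50 px).
#'
#' @inheritParams rolling_ball_background
#' @return corrected matrix, same shape, non-negative.
#' @export
subtract_background <- function(image, radius_px) {
  pmax(image - rolling_ball_background(image, radius_px), 0)
}

#' Normalise an image to its membrane maximum
#'
#' Divides the image by its maximum over the whole-membrane mask, so that
#' membrane intensities lie in `[0, 1]`. Enrichment-family statistics are
#' ratios and therefore unchanged by this step; it is applied for
#' comparability of exported intensity tables.
#'
#' @param image numeric matrix.
#' @param whole_membrane logical matrix, non-empty.
#' @return rescaled matrix.
#' @export
normalize_to_max <- function(image, whole_membrane) {
  stopifnot(is.matrix(image), is.logical(whole_membrane),
            all(dim(image) == dim(whole_membrane)))
  if (!any(whole_membrane)) stop("whole_membrane mask is empty")
  m <- max(image[whole_membrane])
  if (m <= 0) stop("membrane maximum is not positive")
  image / m
}
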