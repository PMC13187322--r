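# Binary mask algebra: disc dilation, connected components, hole filling,
# and the Hessian ridge (tubeness) filter.

assert_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  invisible(mask)
}

#' Dilate a binary mask with a disc structuring element
#'
#' A pixel belongs to the dilation iff its Euclidean distance to the
#' nearest mask pixel is `<= radius_px` (computed with an exact distance
#' transform). Radius 0 is the identity.
#'
#' @param mask logical matrix.
#' @param radius_px disc radius in pixels (>= 0).
#' @return logical matrix, a superset of `mask`.
#' @export
dilate_mask <- function(mask, radius_px) {
  assert_mask(mask)
  if (!is.numeric(radius_px) || radius_px < 0)
    stop("radius_px must be >= 0")
  if (radius_px == 0 || !any(mask)) return(mask)
  d2 <- cpp_edt_sq(mask)
  d2 <= radius_px^2 + 1e-9
}

#' Label connected components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8). Labels follow column-major scan
#'   order, so label numbering is deterministic.
#' @return integer matrix; 0 is background.
#' @export
label_mask <- function(mask, connectivity = 8) {
  assert_mask(mask)
  stopifnot(connectivity %in% c(4, 8))
  cpp_label(mask, as.integer(connectivity))
}

component_areas <- function(labels) {
  labs <- labels[labels > 0L]
  if (!length(labs)) return(integer(0))
  tabulate(labs)
}

#' Filter connected components by area
#'
#' @param mask logical matrix.
#' @param min_area,max_area inclusive area bounds in pixels.
#' @param connectivity 4 or 8.
#' @return logical matrix keeping only components within the bounds.
#' @export
filter_components <- function(mask, min_area = 1, max_area = Inf,
                              connectivity = 8) {
  labels <- label_mask(mask, connectivity)
  areas <- component_areas(labels)
  if (!length(areas)) return(mask & FALSE)
  keep <- which(areas >= min_area & areas <= max_area)
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

#' Keep the largest connected component
#'
#' Ties break to the lowest label index (first component in column-major
#' scan order), so the result is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return logical matrix with at most one component.
#' @export
largest_component <- function(mask, connectivity = 8) {
  labels <- label_mask(mask, connectivity)
  areas <- component_areas(labels)
  if (!length(areas)) return(mask & FALSE)
  labels == which.max(areas)
}

#' Fill internal holes of a binary mask
#'
#' Background components (complement connectivity 4 when the mask uses 8,
#' and vice versa) that do not touch the image border are filled.
#'
#' @param mask logical matrix.
#' @param connectivity foreground connectivity, 4 or 8.
#' @return logical matrix.
#' @export
fill_holes <- function(mask, connectivity = 8) {
  assert_mask(mask)
  bg_conn <- if (connectivity == 8) 4L else 8L
  labels <- cpp_label(!mask, bg_conn)
  ny <- nrow(mask); nx <- ncol(mask)
  border <- unique(c(labels[1, ], labels[ny, ], labels[, 1], labels[, nx]))
  border <- border[border > 0L]
  mask | (labels > 0L & !(labels %in% border))
}

#' Hessian ridge (tubeness) enhancement
#'
#' Scores elongated bright structures: the image is Gaussian-smoothed at
#' `scale_px`, the Hessian eigenvalues are computed per pixel, and the
#' score is `max(0, -lambda2) * scale_px^2` where `lambda2` is the more
#' negative eigenvalue. Bright ridges on dark background (membrane shells,
#' protrusions) score high; flat regions score zero.
#'
#' @param image numeric matrix.
#' @param scale_px filter scale in pixels (> 0).
#' @return non-negative matrix of ridge scores.
#' @export
enhance_tubeness <- function(image, scale_px = 1) {
  stopifnot(is.matrix(image))
  if (!is.numeric(scale_px) || scale_px <= 0)
    stop("scale_px must be > 0")
  sm <- gaussian_blur(image, scale_px)
  ny <- nrow(sm); nx <- ncol(sm)
  up <- sm[c(1, seq_len(ny - 1)), , drop = FALSE]
  dn <- sm[c(seq_len(ny - 1) + 1, ny), , drop = FALSE]
  lf <- sm[, c(1, seq_len(nx - 1)), drop = FALSE]
  rt <- sm[, c(seq_len(nx - 1) + 1, nx), drop = FALSE]
  ixx <- lf + rt - 2 * sm
  iyy <- up + dn - 2 * sm
  ul <- sm[c(1, seq_len(ny - 1)), c(1, seq_len(nx - 1)), drop = FALSE]
  ur <- sm[c(1, seq_len(ny - 1)), c(seq_len(nx - 1) + 1, nx), drop = FALSE]
  dl <- sm[c(seq_len(ny - 1) + 1, ny), c(1, seq_len(nx - 1)), drop = FALSE]
  dr <- sm[c(seq_len(ny - 1) + 1, ny), c(seq_len(nx - 1) + 1, nx),
           drop = FALSE]
  ixy <- (dr + ul - ur - dl) / 4
  lam2 <- (ixx + iyy) / 2 - sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  pmax(-lam2, 0) * scale_px^2
}
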