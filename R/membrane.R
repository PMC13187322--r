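# Membrane topography segmentation: inner body, neighbourhood, protrusions,
# main body membrane, whole membrane.

#' Membrane region masks
#'
#' Container for the per-frame membrane segmentation. Invariants (enforced
#' at construction): protrusions and body membrane are disjoint; the whole
#' membrane is exactly their union; protrusions avoid the inner body and
#' lie inside the neighbourhood; the inner body lies inside the
#' neighbourhood; an invalid result carries empty masks.
#'
#' @param inner_body,neighbourhood,protrusions,body_membrane,whole_membrane
#'   logical matrices of identical shape.
#' @param valid `FALSE` when inner-body detection failed for the frame.
#' @return An object of class `"membrane_masks"`.
#' @export
membrane_masks <- function(inner_body, neighbourhood, protrusions,
                           body_membrane, whole_membrane, valid = TRUE) {
  masks <- list(inner_body = inner_body, neighbourhood = neighbourhood,
                protrusions = protrusions, body_membrane = body_membrane,
                whole_membrane = whole_membrane)
  lapply(masks, assert_mask)
  d <- dim(inner_body)
  if (!all(vapply(masks, function(m) all(dim(m) == d), TRUE)))
    stop("all masks must share the same shape")
  if (!valid && any(vapply(masks, any, TRUE)))
    stop("invalid membrane_masks must have empty masks")
  if (valid) {
    if (any(protrusions & body_membrane))
      stop("protrusions and body membrane must be disjoint")
    if (!identical(whole_membrane, protrusions | body_membrane))
      stop("whole membrane must equal protrusions | body_membrane")
    if (any(protrusions & inner_body))
      stop("protrusions must avoid the inner body")
    if (any(protrusions & !neighbourhood))
      stop("protrusions must lie inside the neighbourhood")
    if (any(inner_body & !neighbourhood))
      stop("inner body must lie inside the neighbourhood")
  }
  structure(c(masks, list(valid = valid)), class = "membrane_masks")
}

empty_membrane_masks <- function(dim_yx) {
  e <- matrix(FALSE, dim_yx[1], dim_yx[2])
  membrane_masks(e, e, e, e, e, valid = FALSE)
}

#' @export
print.membrane_masks <- function(x, ...) {
  cat(sprintf(paste0("membrane_masks (%s): inner %d px, protrusions %d px, ",
                     "body membrane %d px\n"),
              if (x$valid) "valid" else "invalid",
              sum(x$inner_body), sum(x$protrusions), sum(x$body_membrane)))
  invisible(x)
}

#' Enhance dark holes of an image
#'
#' Dark regions fully enclosed by brighter surroundings (the dim cell
#' interior inside its bright membrane shell) are turned into bright
#' blobs. The default method fills grayscale holes by morphological
#' reconstruction (erosion-type, border-seeded) and returns
#' `filled - image`, which is zero outside enclosed basins. The
#' `"rolling_ball"` dialect instead background-subtracts the inverted
#' image with a ball of `radius_px` (the literal Fiji recipe); it only
#' isolates holes narrower than the ball.
#'
#' @param image numeric matrix.
#' @param radius_px ball radius for the `"rolling_ball"` method.
#' @param method `"fill"` (default) or `"rolling_ball"`.
#' @return non-negative matrix, high inside enclosed dark regions.
#' @export
enhance_dark_holes <- function(image, radius_px = 25,
                               method = c("fill", "rolling_ball")) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (method == "rolling_ball") {
    inv <- max(image) - image
    return(subtract_background(inv, radius_px))
  }
  hi <- max(image)
  inv <- hi - image
  ny <- nrow(inv); nx <- ncol(inv)
  marker <- matrix(0, ny, nx)
  marker[1, ] <- inv[1, ]; marker[ny, ] <- inv[ny, ]
  marker[, 1] <- inv[, 1]; marker[, nx] <- inv[, nx]
  rec <- cpp_reconstruct(marker, inv, 4L)
  inv - rec  # hole depth: > 0 only inside enclosed basins
}

#' Segment the inner cell body
#'
#' From the (channel-averaged, blurred) segmentation image: enhance dark
#' holes, threshold, filter components by minimum area, fill internal
#' holes, and keep the largest surviving component. Failure (high
#' intracellular signal, no enclosed dark interior) is reported through
#' the `success` flag, never an error; callers discard such frames.
#'
#' @param seg_image numeric matrix (already averaged and blurred).
#' @param cfg a [pipeline_config].
#' @return list(mask = logical matrix, success = logical).
#' @export
segment_inner_body <- function(seg_image, cfg = pipeline_config()) {
  stopifnot(is.matrix(seg_image))
  empty <- matrix(FALSE, nrow(seg_image), ncol(seg_image))
  rng <- diff(range(seg_image))
  if (rng <= 0) return(list(mask = empty, success = FALSE))
  enhanced <- enhance_dark_holes(seg_image, cfg$holes_radius_px,
                                 cfg$holes_method)
  if (max(enhanced) <= 1e-8 * rng)
    return(list(mask = empty, success = FALSE))
  thr <- auto_threshold(enhanced, cfg$membrane_threshold_method,
                        cfg$membrane_threshold_value)
  mask <- enhanced > thr
  mask <- filter_components(mask, min_area = cfg$inner_body_min_area_px,
                            connectivity = cfg$connectivity)
  if (!any(mask)) return(list(mask = empty, success = FALSE))
  mask <- fill_holes(mask, cfg$connectivity)
  list(mask = largest_component(mask, cfg$connectivity), success = TRUE)
}

#' Segment protrusions and the main body membrane
#'
#' Two parallel streams meet here: the inner body (from
#' [segment_inner_body()]) anchors the dilation-based region definitions,
#' and the tubeness-enhanced membrane image provides the thresholded
#' "neurite" structures. Protrusion candidates are the neurites minus the
#' `body_dilate_px`-dilated inner body, clipped to the
#' `neighbourhood_dilate_px` neighbourhood, with single-pixel objects
#' discarded. The main body membrane is the neurites minus inner body and
#' protrusions; the whole membrane is the union.
#'
#' The auto-threshold of the tubeness image is computed over its positive
#' support: the response is identically zero on flat regions by
#' construction, and including that empty background class would swamp the
#' histogram.
#'
#' @param seg_image numeric matrix (averaged, blurred segmentation image).
#' @param inner_body logical matrix from a successful [segment_inner_body()].
#' @param cfg a [pipeline_config].
#' @return A [membrane_masks] (invalid when `inner_body` is empty).
#' @export
segment_membrane <- function(seg_image, inner_body,
                             cfg = pipeline_config()) {
  stopifnot(is.matrix(seg_image))
  if (!any(inner_body)) return(empty_membrane_masks(dim(seg_image)))
  tub <- enhance_tubeness(seg_image, cfg$tubeness_scale_px)
  support <- tub[tub > 0]
  neurites <- if (length(support) < 2L) tub > 0 else {
    thr <- auto_threshold(support, cfg$membrane_threshold_method,
                          cfg$membrane_threshold_value)
    tub > thr
  }
  body_zone <- dilate_mask(inner_body, cfg$body_dilate_px)
  neighbourhood <- dilate_mask(inner_body, cfg$neighbourhood_dilate_px)
  candidates <- neurites & !body_zone & neighbourhood
  protrusions <- filter_components(candidates, min_area = 2,
                                   connectivity = cfg$connectivity)
  body_membrane <- neurites & !inner_body & !protrusions
  membrane_masks(inner_body = inner_body, neighbourhood = neighbourhood,
                 protrusions = protrusions, body_membrane = body_membrane,
                 whole_membrane = protrusions | body_membrane, valid = TRUE)
}
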