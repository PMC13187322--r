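# Target-cell segmentation and contact mask algebra.

#' Contact region masks
#'
#' Partition of each membrane region into its target-contacting and
#' non-contacting parts. Invariants (enforced): each partition is disjoint
#' and unions back to its full region; contacting parts lie inside the
#' target mask.
#'
#' @param target logical matrix (target-cell footprint).
#' @param protrusion_contact,protrusion_noncontact,body_contact,body_noncontact
#'   logical matrices of the same shape.
#' @return An object of class `"contact_masks"`.
#' @export
contact_masks <- function(target, protrusion_contact, protrusion_noncontact,
                          body_contact, body_noncontact) {
  masks <- list(target = target, protrusion_contact = protrusion_contact,
                protrusion_noncontact = protrusion_noncontact,
                body_contact = body_contact,
                body_noncontact = body_noncontact)
  lapply(masks, assert_mask)
  if (any(protrusion_contact & protrusion_noncontact) ||
      any(body_contact & body_noncontact))
    stop("contact and non-contact partitions must be disjoint")
  if (any(protrusion_contact & !target) || any(body_contact & !target))
    stop("contacting regions must lie inside the target mask")
  structure(masks, class = "contact_masks")
}

#' Segment the target cell across a time lapse
#'
#' The target channel is background-subtracted (rolling ball,
#' `pre_rolling_ball_radius_px`) and blurred (`seg_blur_sigma_px`); the
#' moment-preserving ("Moments") threshold is computed once from the
#' preprocessed last frame — where the target is fully present — and that
#' scalar is applied to every frame, so the per-frame masks still follow
#' target motion.
#'
#' @param stack a [frame_stack] with a `target` channel.
#' @param cfg a [pipeline_config].
#' @return list of logical matrices, one per frame.
#' @export
segment_target <- function(stack, cfg = pipeline_config()) {
  if (!"target" %in% names(stack$channel_roles))
    stop("stack has no target channel")
  nf <- n_frames(stack)
  prep <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- get_channel(stack, "target", f)
    if (cfg$pre_rolling_ball_radius_px > 0)
      img <- subtract_background(img, cfg$pre_rolling_ball_radius_px)
    prep[[f]] <- gaussian_blur(img, cfg$seg_blur_sigma_px)
  }
  thr <- threshold_moments(prep[[nf]])
  lapply(prep, function(img) img > thr)
}

#' Partition membrane regions by target contact
#'
#' `region_contact = region AND target`; `region_noncontact` is the
#' remainder, for both the protrusion and main-body-membrane regions.
#'
#' @param mm a valid [membrane_masks].
#' @param target logical matrix.
#' @return A [contact_masks].
#' @export
compute_contacts <- function(mm, target) {
  if (!inherits(mm, "membrane_masks") || !mm$valid)
    stop("compute_contacts requires valid membrane masks")
  assert_mask(target)
  pc <- mm$protrusions & target
  bc <- mm$body_membrane & target
  contact_masks(target = target,
                protrusion_contact = pc,
                protrusion_noncontact = mm$protrusions & !pc,
                body_contact = bc,
                body_noncontact = mm$body_membrane & !bc)
}

#' Detect the first frame of target contact (time zero)
#'
#' Returns the smallest frame index whose contacting membrane
#' (`protrusion_contact | body_contact`) has at least `min_contact_px`
#' pixels; frames with invalid membrane segmentation are skipped (they
#' were discarded upstream and carry no contact information).
#'
#' @param contacts list of [contact_masks] (or `NULL` for skipped frames),
#'   ordered by time.
#' @param cfg a [pipeline_config].
#' @return 1-based frame index, or `NA_integer_` if no contact occurs.
#' @export
detect_first_contact <- function(contacts, cfg = pipeline_config()) {
  if (length(contacts) == 0L) stop("empty contact sequence")
  for (f in seq_along(contacts)) {
    cm <- contacts[[f]]
    if (is.null(cm)) next
    if (sum(cm$protrusion_contact | cm$body_contact) >= cfg$min_contact_px)
      return(f)
  }
  NA_integer_
}

#' Contact-area fractions
#'
#' The areas occupied by protrusion and main-body-membrane contacts,
#' expressed as percentages of the total contact area (they sum to 100).
#' With no contact at all the fractions are undefined and reported as
#' missing values.
#'
#' @param cm a [contact_masks].
#' @return named numeric vector `c(protrusion_pct=, body_pct=)`.
#' @export
contact_area_fractions <- function(cm) {
  stopifnot(inherits(cm, "contact_masks"))
  ap <- sum(cm$protrusion_contact)
  ab <- sum(cm$body_contact)
  tot <- ap + ab
  if (tot == 0)
    return(c(protrusion_pct = NA_real_, body_pct = NA_real_))
  c(protrusion_pct = 100 * ap / tot, body_pct = 100 * ab / tot)
}
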