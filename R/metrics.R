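# Enrichment-family statistics: enrichment, relative enrichment, contact
# relative enrichment, membrane-bound and relative membrane-bound signal,
# with standard errors propagated from the pixel statistics.

region_mean_u <- function(image, mask) {
  v <- image[mask]
  n <- length(v)
  if (n == 0L) return(NULL)
  uval(mean(v), if (n > 1L) sd(v) / sqrt(n) else 0)
}

#' Enrichment of a protein in a membrane region
#'
#' Mean signal in the region divided by the mean signal over the whole
#' plasma membrane. By construction `enrichment(x, whole, whole) == 1` and
#' the value is invariant to multiplicative intensity rescaling.
#'
#' @param image numeric matrix.
#' @param region logical matrix; empty region yields `NA` (a region absent
#'   from a frame carries no signal information).
#' @param whole_membrane logical matrix, non-empty with positive mean.
#' @return numeric scalar (or `NA_real_` for an empty region).
#' @export
enrichment <- function(image, region, whole_membrane) {
  stopifnot(is.matrix(image))
  assert_mask(region); assert_mask(whole_membrane)
  if (!any(whole_membrane)) stop("whole_membrane mask is empty")
  mw <- mean(image[whole_membrane])
  if (!is.finite(mw) || mw <= 0) stop("membrane mean must be > 0")
  if (!any(region)) return(NA_real_)
  mean(image[region]) / mw
}

enrichment_u <- function(image, region, whole_membrane) {
  a <- region_mean_u(image, region)
  b <- region_mean_u(image, whole_membrane)
  if (is.null(a) || is.null(b)) return(NULL)
  if (b$value <= 0) stop("membrane mean must be > 0")
  propagate_ratio(a, b)
}

#' Relative enrichment
#'
#' A protein's enrichment divided by the enrichment of the evenly
#' distributed membrane reference (SNAP-CAAX) in the same region. A value
#' of 1 means no preferential localisation relative to the membrane
#' marker; above 1 indicates enhanced localisation in the region.
#'
#' @param protein_e enrichment of the protein (numeric or [uval]).
#' @param reference_e enrichment of the membrane reference (> 0).
#' @return same type as the inputs (numeric, or [uval] if either is one).
#' @export
relative_enrichment <- function(protein_e, reference_e) {
  if (is_uval(protein_e) || is_uval(reference_e)) {
    ref <- as_uval(reference_e)
    if (ref$value <= 0) stop("reference enrichment must be > 0")
    return(propagate_ratio(as_uval(protein_e), ref))
  }
  if (is.na(protein_e)) return(NA_real_)
  if (!is.finite(reference_e) || reference_e <= 0)
    stop("reference enrichment must be > 0")
  protein_e / reference_e
}

#' Relative enrichment at a contact
#'
#' Enrichment of the contacting part of a region divided by the enrichment
#' of its non-contacting part; the whole-membrane mean cancels, so this
#' equals the ratio of the two region means.
#'
#' @param image numeric matrix.
#' @param region_contact,region_noncontact logical matrices; an empty
#'   sub-mask yields `NA` for the frame/region.
#' @param whole_membrane logical matrix (kept for interface symmetry).
#' @return numeric scalar or `NA_real_`.
#' @export
contact_relative_enrichment <- function(image, region_contact,
                                        region_noncontact,
                                        whole_membrane = NULL) {
  stopifnot(is.matrix(image))
  assert_mask(region_contact); assert_mask(region_noncontact)
  if (!any(region_contact) || !any(region_noncontact)) return(NA_real_)
  mean(image[region_contact]) / mean(image[region_noncontact])
}

contact_relative_enrichment_u <- function(image, region_contact,
                                          region_noncontact) {
  a <- region_mean_u(image, region_contact)
  b <- region_mean_u(image, region_noncontact)
  if (is.null(a) || is.null(b) || b$value == 0) return(NULL)
  propagate_ratio(a, b)
}

#' Membrane-bound signal
#'
#' Difference of a protein's enrichment in the contacting minus the
#' non-contacting part of a region — the recruitment readout used for
#' cytoplasm-dominated proteins (ZAP-70). Computed per region class
#' (protrusion vs main body membrane) separately because their apparent
#' brightness differs.
#'
#' @inheritParams contact_relative_enrichment
#' @return numeric scalar or `NA_real_`.
#' @export
membrane_bound <- function(image, region_contact, region_noncontact,
                           whole_membrane) {
  ec <- enrichment(image, region_contact, whole_membrane)
  en <- enrichment(image, region_noncontact, whole_membrane)
  if (is.na(ec) || is.na(en)) return(NA_real_)
  ec - en
}

membrane_bound_u <- function(image, region_contact, region_noncontact,
                             whole_membrane) {
  a <- enrichment_u(image, region_contact, whole_membrane)
  b <- enrichment_u(image, region_noncontact, whole_membrane)
  if (is.null(a) || is.null(b)) return(NULL)
  propagate_difference(a, b)
}

#' Relative membrane-bound signal
#'
#' Membrane-bound signal divided by the mean membrane-reference
#' (SNAP-CAAX) enrichment, with ratio-propagated uncertainty. The
#' reference is computed in-run when the reference channel is present,
#' or supplied as `caax_reference_enrichment` in the configuration when
#' it is not (mirroring reuse of a reference dataset).
#'
#' @param mb membrane-bound signal ([uval] or numeric).
#' @param caax_reference reference enrichment ([uval] or numeric, value
#'   > 0).
#' @return A [uval]. A zero-valued `mb` keeps `sem = mb$sem /
#'   caax_reference$value` by the zero-numerator convention.
#' @export
relative_membrane_bound <- function(mb, caax_reference) {
  if (is.null(caax_reference))
    stop("no membrane-reference enrichment available: supply ",
         "caax_reference_enrichment in the pipeline configuration")
  ref <- as_uval(caax_reference)
  if (ref$value <= 0) stop("reference enrichment must be > 0")
  propagate_ratio(as_uval(mb), ref)
}

#' Aggregate a metric time course over a time window
#'
#' Mean and standard error across the frames whose time (relative to first
#' contact) lies in `[window_s[1], window_s[2]]`, both ends inclusive
#' (so the one-minute window `[0, 60]` includes a frame at exactly 60 s).
#' Frames with missing values are skipped and counted.
#'
#' @param tc a metric time course data frame (see [run_event()]), or any
#'   data frame with columns `t_s` and `value`.
#' @param metric,region,channel_role optional filters applied before
#'   aggregation when the corresponding columns are present.
#' @param window_s numeric length-2 window in seconds (default `c(0, 60)`).
#' @return A [uval] with attributes `n` (frames used) and `n_missing`
#'   (frames in the window with missing values).
#' @export
aggregate_window <- function(tc, metric = NULL, region = NULL,
                             channel_role = NULL, window_s = c(0, 60)) {
  stopifnot(is.data.frame(tc), length(window_s) == 2L)
  df <- tc
  if (!is.null(metric)) df <- df[df$metric == metric, , drop = FALSE]
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  if (!is.null(channel_role))
    df <- df[df$channel_role == channel_role, , drop = FALSE]
  df <- df[!is.na(df$t_s) & df$t_s >= window_s[1] & df$t_s <= window_s[2], ,
           drop = FALSE]
  if (nrow(df) == 0L) stop("no frames in the aggregation window")
  miss <- is.na(df$value)
  v <- df$value[!miss]
  if (!length(v)) stop("all frames in the window carry missing values")
  out <- uval(mean(v), if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0)
  attr(out, "n") <- length(v)
  attr(out, "n_missing") <- sum(miss)
  out
}
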