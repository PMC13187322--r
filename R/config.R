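#' Pipeline configuration
#'
#' All tunable parameters of the segmentation and quantification pipeline,
#' with defaults matching the analysis this package reimplements (70 nm
#' confocal pixels). Radii and areas are in pixels.
#'
#' @param pre_rolling_ball_radius_px rolling-ball radius for confocal
#'   background subtraction applied to every channel before analysis
#'   (default 50; 0 disables).
#' @param pre_blur_sigma_px Gaussian sigma of the noise-reduction blur
#'   applied with the background subtraction (default 1; 0 disables).
#' @param seg_blur_sigma_px Gaussian sigma of the blur applied to the
#'   averaged segmentation image and to the target channel (default 2).
#' @param body_dilate_px dilation of the inner body covering the main body
#'   membrane (default 9).
#' @param neighbourhood_dilate_px dilation of the inner body bounding the
#'   protrusion search zone (default 35).
#' @param tubeness_scale_px scale of the Hessian ridge (tubeness) filter
#'   (default 1).
#' @param membrane_threshold_method `"otsu"`, `"moments"` or `"fixed"`;
#'   used for the tubeness image and the dark-hole image.
#' @param membrane_threshold_value threshold used when the method is
#'   `"fixed"`.
#' @param holes_radius_px radius parameter of the dark-hole enhancement
#'   (used by the `"rolling_ball"` dialect; default 25).
#' @param holes_method `"fill"` (grayscale hole filling by morphological
#'   reconstruction, the default) or `"rolling_ball"` (background
#'   subtraction of the inverted image, the Fiji dialect).
#' @param inner_body_min_area_px minimum connected-component area for the
#'   inner body (default 5000, about a 4 um radius cell at 70 nm pixels).
#' @param cluster_threshold receptor clusters are pixels of the
#'   membrane-mean-normalised receptor image strictly above this value
#'   (default 2).
#' @param cluster_area_min_px,cluster_area_max_px inclusive area bounds for
#'   receptor clusters (defaults 5 and 100).
#' @param min_contact_px minimum contacting-membrane pixel count that
#'   counts as a detected contact (default 1).
#' @param segmentation_channels roles averaged into the segmentation image
#'   (default membrane reference + receptor; roles absent from a stack are
#'   dropped at run time).
#' @param caax_reference_enrichment optional [uval]: externally supplied
#'   mean membrane-reference enrichment used for relative membrane-bound
#'   signal when the reference channel is absent from the stack.
#' @param connectivity pixel connectivity for connected components, 4 or 8
#'   (default 8).
#' @param rng_seed seed recorded with the run (default 1).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(pre_rolling_ball_radius_px = 50,
                            pre_blur_sigma_px = 1,
                            seg_blur_sigma_px = 2,
                            body_dilate_px = 9,
                            neighbourhood_dilate_px = 35,
                            tubeness_scale_px = 1,
                            membrane_threshold_method = c("otsu", "moments",
                                                          "fixed"),
                            membrane_threshold_value = NULL,
                            holes_radius_px = 25,
                            holes_method = c("fill", "rolling_ball"),
                            inner_body_min_area_px = 5000,
                            cluster_threshold = 2,
                            cluster_area_min_px = 5,
                            cluster_area_max_px = 100,
                            min_contact_px = 1,
                            segmentation_channels = c("membrane_reference",
                                                      "receptor"),
                            caax_reference_enrichment = NULL,
                            connectivity = 8,
                            rng_seed = 1) {
  cfg <- list(
    pre_rolling_ball_radius_px = as.integer(pre_rolling_ball_radius_px),
    pre_blur_sigma_px = as.numeric(pre_blur_sigma_px),
    seg_blur_sigma_px = as.numeric(seg_blur_sigma_px),
    body_dilate_px = as.integer(body_dilate_px),
    neighbourhood_dilate_px = as.integer(neighbourhood_dilate_px),
    tubeness_scale_px = as.numeric(tubeness_scale_px),
    membrane_threshold_method = match.arg(membrane_threshold_method),
    membrane_threshold_value = membrane_threshold_value,
    holes_radius_px = as.integer(holes_radius_px),
    holes_method = match.arg(holes_method),
    inner_body_min_area_px = as.integer(inner_body_min_area_px),
    cluster_threshold = as.numeric(cluster_threshold),
    cluster_area_min_px = as.integer(cluster_area_min_px),
    cluster_area_max_px = as.integer(cluster_area_max_px),
    min_contact_px = as.integer(min_contact_px),
    segmentation_channels = as.character(segmentation_channels),
    caax_reference_enrichment =
      if (is.null(caax_reference_enrichment)) NULL
      else as_uval(caax_reference_enrichment),
    connectivity = as.integer(connectivity),
    rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(pre_rolling_ball_radius_px >= 0, pre_blur_sigma_px >= 0,
              seg_blur_sigma_px >= 0, body_dilate_px >= 0,
              neighbourhood_dilate_px >= 0, tubeness_scale_px > 0,
              holes_radius_px >= 1, inner_body_min_area_px >= 1,
              cluster_threshold > 0, cluster_area_min_px >= 1,
              cluster_area_min_px <= cluster_area_max_px,
              min_contact_px >= 1, connectivity %in% c(4L, 8L),
              length(segmentation_channels) >= 1)
    if (membrane_threshold_method == "fixed" &&
        is.null(membrane_threshold_value))
      stop("membrane_threshold_value required for fixed thresholding")
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) v <- "<unset>"
    if (is_uval(v)) v <- sprintf("%g +/- %g", v$value, v$sem)
    cat(sprintf("  %-28s %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Write a pipeline configuration to JSON
#' @param cfg a [pipeline_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (is_uval(x$caax_reference_enrichment))
    x$caax_reference_enrichment <- unclass(x$caax_reference_enrichment)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path JSON file written by [write_config()] (or hand-edited).
#' @return A [pipeline_config].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, x)
}

config_hash <- function(cfg) {
  # stable short fingerprint for provenance logs (no digest dependency)
  x <- unclass(cfg)
  if (is_uval(x$caax_reference_enrichment))
    x$caax_reference_enrichment <- unclass(x$caax_reference_enrichment)
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
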