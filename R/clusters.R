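# Receptor (CAR) cluster segmentation and per-cluster channel ratios.

#' Segment receptor clusters
#'
#' The receptor image is normalised by its mean intensity over the whole
#' plasma membrane; pixels strictly above `cluster_threshold` (default 2)
#' are labelled into connected components; components with area in
#' `[cluster_area_min_px, cluster_area_max_px]` (inclusive) are kept.
#' Each cluster is assigned to the protrusion or main-body-membrane region
#' by intersection ("AND") with the respective mask, choosing the region
#' with the larger overlap (ties go to the protrusion, the smaller
#' region); clusters overlapping neither are `"unassigned"` and excluded
#' from per-region statistics.
#'
#' Per-cluster mean *enrichment* is reported for the receptor and for any
#' `extra_channels`, each normalised by its own whole-membrane mean.
#'
#' @param receptor_image numeric matrix (preprocessed receptor channel).
#' @param mm a valid [membrane_masks].
#' @param cfg a [pipeline_config].
#' @param extra_channels optional named list of numeric matrices measured
#'   per cluster alongside the receptor (e.g. `protein`,
#'   `membrane_reference`).
#' @return An object of class `"cluster_set"`: list with `labels` (integer
#'   matrix, 0 = background; labels renumbered over kept clusters) and
#'   `table` (one row per cluster: `id`, `area_px`, `location`,
#'   `receptor_enrichment`, one `<name>_enrichment` column per extra
#'   channel).
#' @export
segment_clusters <- function(receptor_image, mm, cfg = pipeline_config(),
                             extra_channels = list()) {
  stopifnot(is.matrix(receptor_image))
  if (!inherits(mm, "membrane_masks") || !mm$valid)
    stop("segment_clusters requires valid membrane masks")
  mem_mean <- mean(receptor_image[mm$whole_membrane])
  if (!is.finite(mem_mean) || mem_mean <= 0)
    stop("mean receptor intensity over the whole membrane must be > 0")
  norm <- receptor_image / mem_mean
  bw <- norm > cfg$cluster_threshold   # strictly above
  labels <- label_mask(bw, cfg$connectivity)
  areas <- component_areas(labels)
  keep <- which(areas >= cfg$cluster_area_min_px &
                areas <= cfg$cluster_area_max_px)
  out_labels <- matrix(0L, nrow(labels), ncol(labels))
  norm_extra <- lapply(extra_channels, function(img) {
    m <- mean(img[mm$whole_membrane])
    if (!is.finite(m) || m <= 0) return(NULL)
    img / m
  })
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    px <- labels == keep[i]
    out_labels[px] <- i
    ovl_p <- sum(px & mm$protrusions)
    ovl_b <- sum(px & mm$body_membrane)
    location <- if (ovl_p == 0 && ovl_b == 0) "unassigned"
      else if (ovl_p >= ovl_b) "protrusion" else "body"
    row <- data.frame(id = i, area_px = areas[keep[i]], location = location,
                      receptor_enrichment = mean(norm[px]))
    for (nm in names(norm_extra)) {
      val <- if (is.null(norm_extra[[nm]])) NA_real_
        else mean(norm_extra[[nm]][px])
      row[[paste0(nm, "_enrichment")]] <- val
    }
    rows[[i]] <- row
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), area_px = integer(0),
               location = character(0), receptor_enrichment = numeric(0))
  structure(list(labels = out_labels, table = tab), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) (%s)\n", nrow(x$table),
              paste(sprintf("%s=%d", names(table(x$table$location)),
                            as.integer(table(x$table$location))),
                    collapse = ", ")))
  invisible(x)
}

#' Per-cluster channel ratio, averaged by membrane region
#'
#' Computes `numerator / denominator` per cluster (e.g. CD45 enrichment
#' over CAR enrichment, or membrane-bound ZAP-70 over CAR enrichment) and
#' returns the mean ratio per location. Clusters with a zero denominator
#' are flagged and excluded; their count is reported.
#'
#' @param clusters a `cluster_set` (or its `table`).
#' @param numerator,denominator column names of per-cluster metrics.
#' @return list with `means` (named numeric: `protrusion`, `body`; `NA`
#'   where a location has no clusters), `n` (cluster counts used) and
#'   `n_excluded` (zero-denominator clusters).
#' @export
cluster_channel_ratio <- function(clusters, numerator, denominator) {
  tab <- if (inherits(clusters, "cluster_set")) clusters$table else clusters
  stopifnot(is.data.frame(tab),
            numerator %in% names(tab), denominator %in% names(tab))
  bad <- !is.na(tab[[denominator]]) & tab[[denominator]] == 0
  tab <- tab[!bad & !is.na(tab[[denominator]]) & !is.na(tab[[numerator]]), ,
             drop = FALSE]
  ratio <- tab[[numerator]] / tab[[denominator]]
  means <- c(protrusion = NA_real_, body = NA_real_)
  n <- c(protrusion = 0L, body = 0L)
  for (loc in c("protrusion", "body")) {
    sel <- tab$location == loc
    n[[loc]] <- sum(sel)
    if (any(sel)) means[[loc]] <- mean(ratio[sel])
  }
  list(means = means, n = n, n_excluded = sum(bad))
}
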