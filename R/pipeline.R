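# End-to-end per-event pipeline and cross-event summaries.

preprocess_channel <- function(img, cfg) {
  if (cfg$pre_rolling_ball_radius_px > 0)
    img <- subtract_background(img, cfg$pre_rolling_ball_radius_px)
  if (cfg$pre_blur_sigma_px > 0)
    img <- gaussian_blur(img, cfg$pre_blur_sigma_px)
  img
}

metric_row <- function(frame, region, metric, value, channel_role) {
  # a region absent from a frame yields a missing value, never a zero
  u <- if (is.null(value)) uval(NA_real_, NA_real_)
    else if (is_uval(value)) value
    else uval(if (is.na(value)) NA_real_ else value, NA_real_)
  data.frame(frame = frame, region = region, metric = metric,
             value = u$value, sem = u$sem, channel_role = channel_role)
}

#' Run the full pipeline on one cell-cell interaction event
#'
#' Per frame: preprocess every channel (rolling-ball background
#' subtraction + blur), average the segmentation channels, segment the
#' inner body (frames where detection fails are discarded), segment the
#' membrane regions, segment the target and its contacts (when a target
#' channel is present), segment receptor clusters (when a receptor channel
#' is present), and compute the enrichment-family metrics with propagated
#' uncertainties. Time zero is the first frame with a detected contact.
#'
#' Without a target channel the event runs in resting-cell mode: only
#' enrichment and relative enrichment are computed and `t_s` is left `NA`.
#'
#' @param stack a [frame_stack].
#' @param cfg a [pipeline_config].
#' @param cell_id,replicate free-form labels stored with the event.
#' @return An object of class `"event_result"`: list with `timecourse`
#'   (data frame: frame, t_s, region, metric, value, sem, channel_role),
#'   `masks` (per-frame [membrane_masks]), `contacts`, `clusters`,
#'   `t0_frame`, `discarded_frames`, `contact_fractions`, `log`.
#' @export
run_event <- function(stack, cfg = pipeline_config(), cell_id = "cell",
                      replicate = "rep1") {
  stopifnot(inherits(stack, "frame_stack"))
  validate_config(cfg)
  nf <- n_frames(stack)
  roles <- names(stack$channel_roles)
  quant_roles <- setdiff(roles, "target")
  seg_roles <- intersect(cfg$segmentation_channels, roles)
  if (!length(seg_roles)) seg_roles <- quant_roles[1]

  prep <- vector("list", nf)       # per frame: named list of channel images
  masks <- vector("list", nf)
  discarded <- integer(0)
  for (f in seq_len(nf)) {
    prep[[f]] <- lapply(setNames(quant_roles, quant_roles), function(r)
      preprocess_channel(get_channel(stack, r, f), cfg))
    seg <- Reduce(`+`, prep[[f]][seg_roles]) / length(seg_roles)
    seg <- gaussian_blur(seg, cfg$seg_blur_sigma_px)
    ib <- segment_inner_body(seg, cfg)
    if (!ib$success) {
      discarded <- c(discarded, f)
      masks[[f]] <- empty_membrane_masks(dim(seg))
    } else {
      masks[[f]] <- segment_membrane(seg, ib$mask, cfg)
    }
  }
  if (length(discarded) == nf)
    stop("event rejected: inner-body detection failed in every frame")

  has_target <- "target" %in% roles
  contacts <- vector("list", nf)
  t0 <- NA_integer_
  if (has_target) {
    target_masks <- segment_target(stack, cfg)
    for (f in seq_len(nf))
      if (masks[[f]]$valid)
        contacts[[f]] <- compute_contacts(masks[[f]], target_masks[[f]])
    t0 <- detect_first_contact(contacts, cfg)
  }

  clusters <- vector("list", nf)
  if ("receptor" %in% roles) {
    for (f in seq_len(nf)) {
      if (!masks[[f]]$valid) next
      extra <- prep[[f]][setdiff(quant_roles, "receptor")]
      clusters[[f]] <- segment_clusters(prep[[f]]$receptor, masks[[f]],
                                        cfg, extra_channels = extra)
    }
  }

  interval <- stack$frame_interval_s
  rows <- list()
  fractions <- list()
  for (f in seq_len(nf)) {
    mm <- masks[[f]]
    if (!mm$valid) next
    cm <- contacts[[f]]
    for (role in quant_roles) {
      img <- prep[[f]][[role]]
      for (reg in c("protrusions", "body_membrane", "whole_membrane")) {
        regname <- c(protrusions = "protrusion", body_membrane = "body",
                     whole_membrane = "whole_membrane")[[reg]]
        e <- enrichment_u(img, mm[[reg]], mm$whole_membrane)
        rows <- c(rows, list(metric_row(f, regname, "enrichment", e, role)))
        if (role != "membrane_reference" &&
            "membrane_reference" %in% quant_roles) {
          ref <- enrichment_u(prep[[f]]$membrane_reference, mm[[reg]],
                              mm$whole_membrane)
          if (!is.null(e) && !is.null(ref) && ref$value > 0)
            rows <- c(rows, list(metric_row(
              f, regname, "relative_enrichment",
              relative_enrichment(e, ref), role)))
        }
      }
      if (!is.null(cm)) {
        for (side in c("protrusion", "body")) {
          rc <- cm[[paste0(side, "_contact")]]
          rn <- cm[[paste0(side, "_noncontact")]]
          cre <- contact_relative_enrichment_u(img, rc, rn)
          rows <- c(rows, list(metric_row(
            f, side, "contact_relative_enrichment", cre, role)))
          mb <- membrane_bound_u(img, rc, rn, mm$whole_membrane)
          rows <- c(rows, list(metric_row(f, side, "membrane_bound", mb,
                                          role)))
          if (!is.null(mb)) {
            ref <- if ("membrane_reference" %in% quant_roles)
              enrichment_u(prep[[f]]$membrane_reference, rc,
                           mm$whole_membrane)
            else cfg$caax_reference_enrichment
            if (!is.null(ref) && as_uval(ref)$value > 0)
              rows <- c(rows, list(metric_row(
                f, side, "relative_membrane_bound",
                relative_membrane_bound(mb, ref), role)))
          }
        }
      }
    }
    if (!is.null(cm)) {
      fr <- contact_area_fractions(cm)
      fractions <- c(fractions, list(data.frame(
        frame = f, region = c("protrusion", "body"),
        contact_area_px = c(sum(cm$protrusion_contact),
                            sum(cm$body_contact)),
        contact_pct = c(fr[["protrusion_pct"]], fr[["body_pct"]]))))
    }
  }
  tc <- do.call(rbind, rows)
  tc$t_s <- if (is.na(t0)) NA_real_ else (tc$frame - t0) * interval
  tc <- tc[, c("frame", "t_s", "region", "metric", "value", "sem",
               "channel_role")]
  fractions_df <- if (length(fractions)) {
    fd <- do.call(rbind, fractions)
    fd$t_s <- if (is.na(t0)) NA_real_ else (fd$frame - t0) * interval
    fd[, c("frame", "t_s", "region", "contact_area_px", "contact_pct")]
  } else NULL
  structure(list(
    timecourse = tc, masks = masks, contacts = contacts,
    clusters = clusters, t0_frame = t0, discarded_frames = discarded,
    contact_fractions = fractions_df,
    cell_id = cell_id, replicate = replicate,
    frame_interval_s = interval,
    log = list(config_hash = config_hash(cfg),
               discarded_frames = discarded,
               discard_rule = "inner-body detection failed",
               n_frames = nf, t0_frame = t0)),
    class = "event_result")
}

#' @export
print.event_result <- function(x, ...) {
  cat(sprintf(paste0("event_result '%s' (%s): %d frame(s), %d discarded, ",
                     "t0 = %s\n"),
              x$cell_id, x$replicate, x$log$n_frames,
              length(x$discarded_frames),
              ifelse(is.na(x$t0_frame), "none", x$t0_frame)))
  invisible(x)
}

paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  if (n < 2) return(list(t = NA_real_, p = NA_real_, n = n))
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, n = n))
    return(list(t = sign(mean(d)) * Inf, p = 0, n = n))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1), n = n)
}

unpaired_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    return(list(t = NA_real_, p = NA_real_, n = length(a) + length(b)))
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, n = length(a) + length(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                n = length(a) + length(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       n = length(a) + length(b))
}

#' Summarise events across cells and replicates
#'
#' Computes per-event window means of one metric (superplot-style), per-
#' replicate means, the overall mean with standard deviation, and — when at
#' least two events are available — a two-sided paired t test between the
#' two `regions` within events, or a two-sided unpaired t test between the
#' groups in `groups`. p values are reported without multiplicity
#' adjustment.
#'
#' @param events list of `event_result` objects.
#' @param metric metric name (e.g. `"relative_enrichment"`).
#' @param regions character vector of regions; with exactly two, a paired
#'   test compares them within events.
#' @param channel_role channel to summarise.
#' @param window_s aggregation window in seconds relative to first contact
#'   (ignored, with all frames used, for resting-mode events).
#' @param groups optional factor/character vector (one per event) for an
#'   unpaired between-group comparison of the first region.
#' @return list with `per_event`, `per_replicate`, `overall`, `tests`.
#' @export
summarise_events <- function(events, metric, regions = c("protrusion",
                                                         "body"),
                             channel_role = NULL, window_s = c(0, 60),
                             groups = NULL) {
  stopifnot(is.list(events), length(events) >= 1)
  per_event <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    tc <- ev$timecourse
    if (is.null(channel_role)) {
      cand <- setdiff(unique(tc$channel_role), "membrane_reference")
      channel_role <- if (length(cand)) cand[1] else
        unique(tc$channel_role)[1]
    }
    for (reg in regions) {
      sel <- tc[tc$metric == metric & tc$region == reg &
                tc$channel_role == channel_role, , drop = FALSE]
      if (!nrow(sel)) next
      if (all(is.na(sel$t_s))) {
        v <- sel$value[!is.na(sel$value)]
        if (!length(v)) next
        u <- uval(mean(v), if (length(v) > 1) sd(v) / sqrt(length(v))
                  else 0)
      } else {
        u <- tryCatch(aggregate_window(sel, window_s = window_s),
                      error = function(e) NULL)
        if (is.null(u)) next
      }
      per_event[[length(per_event) + 1L]] <- data.frame(
        event = i, cell_id = ev$cell_id, replicate = ev$replicate,
        region = reg, mean = u$value, sem = u$sem)
    }
  }
  if (!length(per_event)) stop("no events carry the requested metric")
  per_event <- do.call(rbind, per_event)
  per_replicate <- aggregate(mean ~ replicate + region, per_event, mean)
  overall <- aggregate(mean ~ region, per_event,
                       function(v) c(mean = mean(v), sd = sd(v),
                                     n = length(v)))
  overall <- do.call(data.frame, overall)
  names(overall) <- c("region", "mean", "sd", "n")

  tests <- list()
  if (length(regions) == 2) {
    w <- split(per_event, per_event$region)
    if (all(regions %in% names(w))) {
      a <- w[[regions[1]]]; b <- w[[regions[2]]]
      common <- intersect(a$event, b$event)
      if (length(common) >= 2) {
        tests$paired <- c(list(comparison = paste(regions,
                                                  collapse = " vs ")),
                          paired_t(a$mean[match(common, a$event)],
                                   b$mean[match(common, b$event)]))
      } else {
        warning("fewer than two paired events: paired test skipped")
      }
    }
  }
  if (!is.null(groups)) {
    g <- groups[per_event$event[per_event$region == regions[1]]]
    v <- per_event$mean[per_event$region == regions[1]]
    lev <- unique(g)
    if (length(lev) == 2) {
      tests$unpaired <- c(list(comparison = paste(lev, collapse = " vs ")),
                          unpaired_t(v[g == lev[1]], v[g == lev[2]]))
    }
  }
  list(per_event = per_event, per_replicate = per_replicate,
       overall = overall, tests = tests, metric = metric,
       channel_role = channel_role, window_s = window_s)
}

#' Write an event's metric table and sidecar to disk
#'
#' Tidy CSV (one metric record per row) plus a JSON sidecar with time
#' zero, the configuration hash, and frame-validity counts; mask TIFFs and
#' the contact-area CSV are written alongside.
#'
#' @param event an `event_result`.
#' @param dir output directory.
#' @param write_masks also export per-frame region masks as 8-bit TIFFs.
#' @return `dir`, invisibly.
#' @export
write_event <- function(event, dir, write_masks = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(event$timecourse, file.path(dir, "metrics.csv"),
            row.names = FALSE)
  if (!is.null(event$contact_fractions))
    write.csv(event$contact_fractions,
              file.path(dir, "contact_fractions.csv"), row.names = FALSE)
  stats_rows <- list()
  for (f in seq_along(event$masks)) {
    mm <- event$masks[[f]]
    if (!mm$valid) next
    for (reg in c("inner_body", "protrusions", "body_membrane",
                  "whole_membrane"))
      stats_rows <- c(stats_rows, list(data.frame(
        frame = f, region = reg, area_px = sum(mm[[reg]]))))
  }
  if (length(stats_rows))
    write.csv(do.call(rbind, stats_rows),
              file.path(dir, "region_areas.csv"), row.names = FALSE)
  cl_rows <- list()
  for (f in seq_along(event$clusters)) {
    cs <- event$clusters[[f]]
    if (is.null(cs) || !nrow(cs$table)) next
    tab <- cs$table
    tab$frame <- f
    cl_rows <- c(cl_rows, list(tab))
  }
  if (length(cl_rows)) {
    all_names <- unique(unlist(lapply(cl_rows, names)))
    cl_rows <- lapply(cl_rows, function(tb) {
      tb[setdiff(all_names, names(tb))] <- NA
      tb[all_names]
    })
    write.csv(do.call(rbind, cl_rows), file.path(dir, "clusters.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(cell_id = event$cell_id, replicate = event$replicate,
         t0_frame = event$t0_frame,
         frame_interval_s = event$frame_interval_s,
         discarded_frames = event$discarded_frames,
         n_frames = event$log$n_frames,
         config_hash = event$log$config_hash),
    file.path(dir, "event.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (write_masks) {
    for (reg in c("inner_body", "protrusions", "body_membrane",
                  "whole_membrane"))
      write_mask_tiff(lapply(event$masks, function(mm) mm[[reg]]),
                      file.path(dir, paste0("mask_", reg, ".tif")))
  }
  invisible(dir)
}
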