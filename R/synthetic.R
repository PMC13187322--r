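# Ground-truthed synthetic fluorescence scenes: a convex cell body with a
# thin bright membrane shell, tubular protrusions, an approaching target
# cell, per-region channel enrichment factors, contact-site receptor
# clusters, and Poisson + Gaussian noise.

local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic substream seed per (frame, channel); kept below 2^31
stream_seed <- function(seed, frame, channel) {
  as.integer((as.numeric(seed) * 7919 + frame * 104729 + channel * 1299709)
             %% 2147483629)
}

#' Per-channel region factors for synthetic scenes
#'
#' Membrane factors (`body_membrane`, `protrusion`) are *target enrichment
#' levels*: the mean intensity of the region relative to the whole-membrane
#' mean. The renderer compensates the factor-1 regions so that each
#' requested enrichment is met exactly in the noiseless limit (feasible
#' only while `factor x membrane-area-fraction < 1`). Contact factors
#' (`protrusion_contact`, `body_contact`) are multiplicative on their
#' parent region once the target is in contact, so a contact factor f
#' yields a contact relative enrichment of exactly f by construction.
#' `cytoplasm` and `background` are plain intensities in units of the
#' whole-membrane mean.
#'
#' @param body_membrane,protrusion target enrichments (default 1).
#' @param protrusion_contact,body_contact contact modulation factors
#'   (default 1 = no modulation).
#' @param cytoplasm,background intensities relative to the membrane mean.
#' @return named list of factors.
#' @export
channel_factors <- function(body_membrane = 1, protrusion = 1,
                            protrusion_contact = 1, body_contact = 1,
                            cytoplasm = 0.1, background = 0.02) {
  f <- list(body_membrane = body_membrane, protrusion = protrusion,
            protrusion_contact = protrusion_contact,
            body_contact = body_contact, cytoplasm = cytoplasm,
            background = background)
  stopifnot(all(vapply(f, function(x) is.numeric(x) && x >= 0, TRUE)))
  f
}

#' Parameters of a synthetic scene
#'
#' Defaults describe a resting-to-engaging T cell at 70 nm pixels: an
#' 85-px-radius (about 6 um) cell body with a 3-px membrane shell, six
#' straight 3-px-wide protrusions of 12-28 px (about 1-2 um), a half-plane
#' target approaching at 3 px/frame that first touches the membrane at
#' `onset_frame`, and shot noise at `photon_scale = 100` (membrane SNR of
#' about 10, since the membrane baseline is 1 intensity unit).
#'
#' @param field_size_px square field edge (default 512).
#' @param pixel_size_nm physical pixel pitch (default 70).
#' @param body_radius_px inner-body radius (default 85).
#' @param shell_thickness_px membrane shell thickness (default 3).
#' @param n_protrusions number of protrusions (default 6).
#' @param protrusion_length_px length-2 range, sampled uniformly
#'   (default `c(12, 28)`).
#' @param protrusion_width_px capsule width (default 3).
#' @param body_margin_px radial margin separating protrusions from the
#'   main body membrane in the truth masks; matches the pipeline's
#'   `body_dilate_px` convention (default 9). The rendered intensity
#'   follows the physical structure (a whole protrusion carries the
#'   protrusion factor, root included); the masks follow the analysis
#'   convention.
#' @param neighbourhood_margin_px truth neighbourhood radius margin
#'   (default 35).
#' @param protrusion_angles optional numeric vector of protrusion angles
#'   (radians); overrides random placement, e.g. evenly spaced angles.
#' @param target `NULL` for a resting scene, or
#'   `list(speed_px_per_frame =, onset_frame =)`: a half-plane entering
#'   from the right whose first membrane overlap happens exactly at
#'   `onset_frame`.
#' @param channels named list of [channel_factors()], one per role
#'   (membrane_reference factors must all be 1: a uniform marker).
#' @param clusters `list(count =, amplitude =, radius_px =, delay_frames =,
#'   areas_px =, placement =)`: `count` discs (or exact pixel areas
#'   `areas_px`) of `amplitude` x membrane mean added to the receptor
#'   channel `delay_frames` after first contact, centred on contacting
#'   membrane pixels (`placement = "contact"`) or anywhere on the membrane
#'   (`"membrane"`).
#' @param noise `list(photon_scale =, read_sigma =)`: intensities are
#'   Poisson-resampled at `photon_scale` photons per intensity unit
#'   (use `Inf` for no shot noise) plus Gaussian read noise.
#' @param psf_sigma_px Gaussian optics blur of the render (default 1; 0
#'   disables).
#' @param n_frames,frame_interval_s time-lapse length and frame interval.
#' @param seed integer seed; scenes are bit-reproducible given the seed.
#' @return An object of class `"scene_params"`.
#' @export
scene_params <- function(field_size_px = 512, pixel_size_nm = 70,
                         body_radius_px = 85, shell_thickness_px = 3,
                         n_protrusions = 6,
                         protrusion_length_px = c(12, 28),
                         protrusion_width_px = 3,
                         body_margin_px = 9, neighbourhood_margin_px = 35,
                         protrusion_angles = NULL,
                         target = list(speed_px_per_frame = 3,
                                       onset_frame = 5),
                         channels = list(
                           membrane_reference = channel_factors(),
                           receptor = channel_factors(),
                           target = channel_factors()),
                         clusters = list(count = 0, amplitude = 3,
                                         radius_px = 2, delay_frames = 1,
                                         areas_px = NULL,
                                         placement = "contact"),
                         noise = list(photon_scale = 100, read_sigma = 0.01),
                         psf_sigma_px = 1, n_frames = 12,
                         frame_interval_s = 4, seed = 1) {
  p <- list(field_size_px = as.integer(field_size_px),
            pixel_size_nm = pixel_size_nm,
            body_radius_px = body_radius_px,
            shell_thickness_px = shell_thickness_px,
            n_protrusions = as.integer(n_protrusions),
            protrusion_length_px = as.numeric(protrusion_length_px),
            protrusion_width_px = protrusion_width_px,
            body_margin_px = body_margin_px,
            neighbourhood_margin_px = neighbourhood_margin_px,
            protrusion_angles = protrusion_angles,
            target = target, channels = channels,
            clusters = modifyList(list(count = 0, amplitude = 3,
                                       radius_px = 2, delay_frames = 1,
                                       areas_px = NULL,
                                       placement = "contact"), clusters),
            noise = modifyList(list(photon_scale = 100, read_sigma = 0.01),
                               noise),
            psf_sigma_px = psf_sigma_px, n_frames = as.integer(n_frames),
            frame_interval_s = frame_interval_s, seed = as.integer(seed))
  with(p, {
    stopifnot(field_size_px >= 64, body_radius_px > 0,
              shell_thickness_px > 0, n_protrusions >= 0,
              length(protrusion_length_px) == 2,
              all(protrusion_length_px > 0),
              protrusion_length_px[1] <= protrusion_length_px[2],
              protrusion_width_px > 0, body_margin_px >= 0,
              neighbourhood_margin_px >= body_margin_px,
              psf_sigma_px >= 0, n_frames >= 1, frame_interval_s > 0,
              noise$photon_scale > 0, noise$read_sigma >= 0)
    tip <- body_radius_px + shell_thickness_px + protrusion_length_px[2]
    if (tip > field_size_px / 2 - 2)
      stop("protrusion length exceeds the field")
    if (!is.null(target)) {
      stopifnot(target$speed_px_per_frame >= 1)
      if (target$onset_frame < 1 || target$onset_frame > n_frames)
        stop("target onset frame lies beyond the time lapse")
    }
    if (!"membrane_reference" %in% names(channels))
      stop("a membrane_reference channel is required")
    cf <- channels$membrane_reference
    if (any(abs(c(cf$body_membrane, cf$protrusion, cf$protrusion_contact,
                  cf$body_contact) - 1) > 1e-12))
      stop("membrane_reference factors must all be 1 (uniform marker)")
  })
  structure(p, class = "scene_params")
}

# pixels within width/2 of the segment p0 -> p1 (capsule), given coordinate
# matrices xm, ym
capsule_mask <- function(xm, ym, p0, p1, width) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  t <- ((xm - p0[1]) * vx + (ym - p0[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- xm - (p0[1] + t * vx)
  dy <- ym - (p0[2] + t * vy)
  dx^2 + dy^2 <= (width / 2)^2
}

# exact-pixel-area blob: the `area` pixels nearest to the centre
# (deterministic tie-break on angle then index)
blob_pixels <- function(center, area, field) {
  r <- ceiling(sqrt(area / pi)) + 2
  ys <- max(1, round(center[2]) - r):min(field, round(center[2]) + r)
  xs <- max(1, round(center[1]) - r):min(field, round(center[1]) + r)
  g <- expand.grid(y = ys, x = xs)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2
  ord <- order(d2, atan2(g$y - center[2], g$x - center[1]), g$y)
  g <- g[ord[seq_len(min(area, nrow(g)))], ]
  cbind(g$y, g$x)
}

solve_membrane_raw <- function(fac, area_prot, area_body) {
  e <- c(protrusion = fac$protrusion, body = fac$body_membrane)
  A <- c(protrusion = area_prot, body = area_body)
  spec <- abs(e - 1) > 1e-12 & A > 0
  if (!any(spec)) return(e * 0 + 1)
  if (all(spec | A == 0)) {
    m <- sum(A * e) / sum(A)
    if (abs(m - 1) > 1e-9)
      stop("requested enrichments are inconsistent: area-weighted mean ",
           "must be 1 when every region is constrained")
    return(e)
  }
  base <- (sum(A) - sum(A[spec] * e[spec])) / sum(A[!spec])
  if (base <= 0)
    stop("requested enrichment infeasible: factor x membrane-area ",
         "fraction must be < 1")
  raw <- e
  raw[!spec] <- base
  raw
}

#' Generate a synthetic scene with ground truth
#'
#' Renders each channel as background + cytoplasm + membrane shell with
#' per-region factors (+ receptor clusters after contact), blurs with the
#' optics PSF, and applies Poisson + Gaussian noise with an independent
#' substream per (frame, channel). Returns the truth masks (built through
#' the validating [membrane_masks()]/[contact_masks()] constructors), the
#' true first-contact frame, and the analytic expected enrichments.
#'
#' @param params a [scene_params()].
#' @return list with elements `scene` (class `"synthetic_scene"`) and
#'   `stack` (a [frame_stack]).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  n <- p$field_size_px
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  xm <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ym <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  d <- sqrt((xm - cx)^2 + (ym - cy)^2)
  inner <- d < p$body_radius_px
  ring <- !inner & d <= p$body_radius_px + p$shell_thickness_px

  geometry <- local_seed(stream_seed(p$seed, 0L, 0L), {
    if (!is.null(p$protrusion_angles)) {
      angles <- as.numeric(p$protrusion_angles)
      lengths <- runif(length(angles), p$protrusion_length_px[1],
                       p$protrusion_length_px[2])
    } else {
      angles <- numeric(0)
      lengths <- numeric(0)
      min_sep <- (p$protrusion_width_px + 6) / p$body_radius_px
      tries <- 0L
      while (length(angles) < p$n_protrusions && tries < 2000L) {
        tries <- tries + 1L
        a <- runif(1, 0, 2 * pi)
        gap <- abs(((angles - a + pi) %% (2 * pi)) - pi)
        if (length(angles) == 0L || min(gap) >= min_sep) {
          angles <- c(angles, a)
          lengths <- c(lengths, runif(1, p$protrusion_length_px[1],
                                      p$protrusion_length_px[2]))
        }
      }
      if (length(angles) < p$n_protrusions)
        stop("could not place non-overlapping protrusions")
    }
    list(angles = angles, lengths = lengths)
  })

  capsules <- matrix(FALSE, n, n)
  for (i in seq_along(geometry$angles)) {
    a <- geometry$angles[i]
    r1 <- p$body_radius_px + p$shell_thickness_px + geometry$lengths[i]
    p0 <- c(cx + p$body_radius_px * cos(a), cy + p$body_radius_px * sin(a))
    p1 <- c(cx + r1 * cos(a), cy + r1 * sin(a))
    capsules <- capsules | capsule_mask(xm, ym, p0, p1,
                                        p$protrusion_width_px)
  }
  membrane_all <- (ring | capsules) & !inner
  body_zone <- d < p$body_radius_px + p$body_margin_px
  neighbourhood <- d < p$body_radius_px + p$neighbourhood_margin_px
  protrusions <- membrane_all & !body_zone & neighbourhood
  body_mem <- membrane_all & !protrusions
  whole <- protrusions | body_mem
  mm_truth <- membrane_masks(inner, neighbourhood, protrusions, body_mem,
                             whole, valid = TRUE)
  area_p <- sum(protrusions); area_b <- sum(body_mem)

  # target trajectory: first membrane overlap exactly at onset_frame
  has_target <- !is.null(p$target)
  x_right <- if (any(whole)) max(xm[whole]) else n
  target_fp <- vector("list", p$n_frames)
  for (f in seq_len(p$n_frames)) {
    if (has_target) {
      x0 <- x_right + p$target$speed_px_per_frame * (p$target$onset_frame - f)
      target_fp[[f]] <- xm >= x0
    } else target_fp[[f]] <- matrix(FALSE, n, n)
  }
  first_contact <- if (has_target) as.integer(p$target$onset_frame)
    else NA_integer_

  # cluster nucleation
  cl <- p$clusters
  cluster_px <- list()
  cluster_truth <- data.frame()
  appearance <- if (identical(cl$placement, "contact")) {
    if (has_target) first_contact + cl$delay_frames else NA_integer_
  } else 1L + cl$delay_frames
  areas_req <- if (!is.null(cl$areas_px)) as.integer(cl$areas_px)
    else rep(ceiling(pi * cl$radius_px^2), cl$count)
  n_clusters <- length(areas_req)
  if (n_clusters > 0 && !is.na(appearance) && appearance <= p$n_frames) {
    # keep centres away from the protrusion/body boundary circle so the
    # planted location is unambiguous ground truth
    unambiguous <- abs(d - (p$body_radius_px + p$body_margin_px)) > 4
    pool_mask <- if (identical(cl$placement, "contact"))
      whole & unambiguous & target_fp[[min(appearance, p$n_frames)]]
    else whole & unambiguous
    pool <- which(pool_mask, arr.ind = TRUE)  # (y, x)
    if (nrow(pool) == 0L) stop("no membrane pixels available for clusters")
    min_sep <- 2 * ceiling(sqrt(max(areas_req) / pi)) + 3
    centers <- local_seed(stream_seed(p$seed, 0L, 1L), {
      acc <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(acc) < n_clusters && tries < 5000L) {
        tries <- tries + 1L
        cand <- pool[sample.int(nrow(pool), 1L), ]
        if (nrow(acc) == 0L ||
            min(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2)) >=
            min_sep)
          acc <- rbind(acc, cand)
      }
      if (nrow(acc) < n_clusters)
        stop("could not place well-separated clusters; enlarge the scene")
      acc
    })
    for (i in seq_len(n_clusters)) {
      px <- blob_pixels(c(centers[i, 2], centers[i, 1]), areas_req[i], n)
      cluster_px[[i]] <- px
      sel <- matrix(FALSE, n, n); sel[px] <- TRUE
      ovl_p <- sum(sel & protrusions); ovl_b <- sum(sel & body_mem)
      cluster_truth <- rbind(cluster_truth, data.frame(
        id = i, area_px = nrow(px),
        location = if (ovl_p == 0 && ovl_b == 0) "unassigned"
          else if (ovl_p >= ovl_b) "protrusion" else "body",
        y = centers[i, 1], x = centers[i, 2],
        appearance_frame = appearance))
    }
  }

  roles <- setNames(seq_along(p$channels), names(p$channels))
  arr <- array(0, dim = c(p$n_frames, length(p$channels), n, n))
  expected <- list()
  contacts_truth <- vector("list", p$n_frames)

  # flux regions: a protrusion carries its factor along its whole length
  # (root included); the ring outside the capsules carries the body factor.
  # The enrichment solve uses the flux areas inside the membrane masks.
  capM <- capsules & !inner
  ringM <- ring & !capsules
  a_cap <- sum(capM & whole)
  a_ring <- sum(ringM & whole)

  for (f in seq_len(p$n_frames)) {
    fp <- target_fp[[f]]
    pc <- protrusions & fp; bc <- body_mem & fp
    contacts_truth[[f]] <- compute_contacts(mm_truth, fp)
    for (ci in seq_along(p$channels)) {
      role <- names(p$channels)[ci]
      fac <- p$channels[[ci]]
      if (role == "target") {
        S <- matrix(fac$background, n, n)
        S[fp] <- 1
      } else {
        raw <- solve_membrane_raw(fac, a_cap, a_ring)
        S <- matrix(fac$background, n, n)
        S[inner] <- fac$cytoplasm
        S[ringM] <- raw[["body"]]
        S[capM] <- raw[["protrusion"]]
        S[capM & fp] <- raw[["protrusion"]] * fac$protrusion_contact
        S[ringM & fp] <- raw[["body"]] * fac$body_contact
        # expected values by direct measurement of the clean render
        mem_mean_true <- mean(S[whole])
        regs <- list(protrusion = protrusions, body = body_mem,
                     whole_membrane = whole,
                     protrusion_contact = pc,
                     protrusion_noncontact = protrusions & !pc,
                     body_contact = bc, body_noncontact = body_mem & !bc)
        vals <- vapply(regs, function(m)
          if (any(m)) mean(S[m]) else NA_real_, 0)
        expected[[length(expected) + 1L]] <- data.frame(
          frame = f, channel_role = role, region = names(regs),
          raw = unname(vals), enrichment = unname(vals) / mem_mean_true)
        if (role == "receptor" && length(cluster_px) &&
            !is.na(appearance) && f >= appearance) {
          mem_mean <- mean(S[whole])
          for (px in cluster_px) S[px] <- S[px] + cl$amplitude * mem_mean
        }
      }
      Sb <- if (p$psf_sigma_px > 0) gaussian_blur(S, p$psf_sigma_px) else S
      noisy <- local_seed(stream_seed(p$seed, f, ci), {
        out <- if (is.finite(p$noise$photon_scale))
          rpois(length(Sb), pmax(Sb, 0) * p$noise$photon_scale) /
            p$noise$photon_scale
        else Sb
        out <- out + rnorm(length(Sb), 0, p$noise$read_sigma)
        matrix(out, n, n)
      })
      arr[f, ci, , ] <- pmax(noisy, 0)
    }
  }

  stack <- frame_stack(arr, roles, pixel_size_nm = p$pixel_size_nm,
                       frame_interval_s = p$frame_interval_s)
  scene <- structure(list(
    params = p, membrane = mm_truth, contacts = contacts_truth,
    target_footprints = target_fp, first_contact_frame = first_contact,
    expected = do.call(rbind, expected), clusters = cluster_truth,
    geometry = geometry), class = "synthetic_scene")
  list(scene = scene, stack = stack)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scene: %d frame(s), first contact %s, ",
                     "%d protrusion(s), %d cluster(s)\n"),
              x$params$n_frames,
              ifelse(is.na(x$first_contact_frame), "never",
                     x$first_contact_frame),
              x$params$n_protrusions, nrow(x$clusters)))
  invisible(x)
}

#' Analytic expected metric time course of a synthetic scene
#'
#' Computes the expected value of every enrichment-family metric from the
#' truth masks and planted factors alone (no pipeline involvement) — the
#' recovery oracle for pipeline validation. Relative enrichment equals the
#' plain enrichment because the membrane reference is uniform.
#'
#' @param scene a `"synthetic_scene"`.
#' @return data frame with columns `frame`, `t_s`, `channel_role`,
#'   `region`, `metric`, `value`.
#' @export
truth_metrics <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ex <- scene$expected
  t0 <- scene$first_contact_frame
  interval <- scene$params$frame_interval_s
  rows <- list()
  push <- function(frame, role, region, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      frame = frame,
      t_s = if (is.na(t0)) NA_real_ else (frame - t0) * interval,
      channel_role = role, region = region, metric = metric, value = value)
  }
  for (i in seq_len(nrow(ex))) {
    r <- ex[i, ]
    if (r$region %in% c("protrusion", "body", "whole_membrane")) {
      push(r$frame, r$channel_role, r$region, "enrichment", r$enrichment)
      if (r$region != "whole_membrane")
        push(r$frame, r$channel_role, r$region, "relative_enrichment",
             r$enrichment)
    }
  }
  # contact metrics from the raw values (sub-masks must be non-empty)
  for (f in unique(ex$frame)) {
    for (role in unique(ex$channel_role)) {
      sub <- ex[ex$frame == f & ex$channel_role == role, ]
      g <- function(reg, col = "raw") sub[[col]][sub$region == reg]
      ga <- function(reg) {
        cm <- scene$contacts[[f]]
        sum(cm[[reg]])
      }
      for (side in c("protrusion", "body")) {
        rc <- paste0(side, "_contact"); rn <- paste0(side, "_noncontact")
        if (ga(rc) > 0 && ga(rn) > 0) {
          push(f, role, side, "contact_relative_enrichment",
               g(rc) / g(rn))
          sube <- sub$enrichment
          names(sube) <- sub$region
          push(f, role, side, "membrane_bound",
               sube[[rc]] - sube[[rn]])
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a synthetic scene to disk
#'
#' Emits the stack TIFF (the layout [read_stack()] consumes), truth masks
#' as 8-bit multi-page TIFFs, and the parameters plus ground truth as
#' JSON.
#'
#' @param sim result of [generate_scene()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(sim$stack, file.path(dir, "stack.tif"))
  mm <- sim$scene$membrane
  write_mask_tiff(list(mm$inner_body, mm$protrusions, mm$body_membrane,
                       mm$whole_membrane),
                  file.path(dir, "truth_membrane.tif"))
  write_mask_tiff(sim$scene$target_footprints,
                  file.path(dir, "truth_target.tif"))
  meta <- list(params = unclass(sim$scene$params),
               first_contact_frame = sim$scene$first_contact_frame,
               channel_roles = as.list(sim$stack$channel_roles),
               clusters = sim$scene$clusters)
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
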