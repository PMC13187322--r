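# Shared fixtures, generated in code: small synthetic scenes and a fast
# configuration for 192-256 px test fields.

test_config <- function(...) {
  pipeline_config(...)
}

# a compact resting cell: 256 px field, 60 px body
small_scene_params <- function(seed = 1, ...) {
  defaults <- list(field_size_px = 256, body_radius_px = 60,
                   n_frames = 1, target = NULL, seed = seed)
  do.call(scene_params, modifyList(defaults, list(...)))
}

# noiseless, unblurred render (analytic signal field)
clean_noise <- list(photon_scale = Inf, read_sigma = 0)

# a synthetic annulus: bright ring of the given radius/thickness on a dark
# background, used for inner-body oracles
annulus_image <- function(n = 200, radius = 71, thickness = 3, high = 100,
                          low = 0) {
  cx <- (n + 1) / 2
  xm <- matrix(rep(seq_len(n), each = n), n, n)
  ym <- matrix(rep(seq_len(n), times = n), n, n)
  d <- sqrt((xm - cx)^2 + (ym - cx)^2)
  img <- matrix(low, n, n)
  img[d >= radius & d <= radius + thickness] <- high
  img
}

disc_mask <- function(n, radius) {
  cx <- (n + 1) / 2
  xm <- matrix(rep(seq_len(n), each = n), n, n)
  ym <- matrix(rep(seq_len(n), times = n), n, n)
  sqrt((xm - cx)^2 + (ym - cx)^2) < radius
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
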