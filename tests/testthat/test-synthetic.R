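test_that("scene generation is deterministic given the seed", {
  p <- small_scene_params(seed = 61, n_frames = 2,
                          target = list(speed_px_per_frame = 3,
                                        onset_frame = 1))
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$scene$membrane$protrusions,
                   b$scene$membrane$protrusions)
  c <- generate_scene(small_scene_params(seed = 62, n_frames = 2))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("noise-free limit renders the analytic signal field", {
  p <- small_scene_params(seed = 63, noise = clean_noise, psf_sigma_px = 0)
  sim <- generate_scene(p)
  img <- get_channel(sim$stack, "membrane_reference", 1)
  mm <- sim$scene$membrane
  # uniform marker: membrane pixels all equal, cytoplasm/background at
  # their configured levels
  expect_equal(unique(img[mm$whole_membrane]), 1)
  expect_equal(unique(img[mm$inner_body]), 0.1)
  expect_equal(max(abs(img[!mm$whole_membrane & !mm$inner_body] - 0.02)), 0)
})

test_that("planted factors give exact truth enrichments", {
  p <- small_scene_params(
    seed = 64, noise = clean_noise, psf_sigma_px = 0,
    channels = list(membrane_reference = channel_factors(),
                    protein = channel_factors(protrusion = 2)))
  sim <- generate_scene(p)
  img <- get_channel(sim$stack, "protein", 1)
  mm <- sim$scene$membrane
  e <- enrichment(img, mm$protrusions, mm$whole_membrane)
  expect_equal(e, 2, tolerance = 1e-6)
  tm <- truth_metrics(sim$scene)
  expect_equal(tm$value[tm$metric == "relative_enrichment" &
                        tm$region == "protrusion" &
                        tm$channel_role == "protein"], 2)
  # infeasible factor x area fraction errors clearly
  expect_error(generate_scene(small_scene_params(
    seed = 64, channels = list(membrane_reference = channel_factors(),
                               protein = channel_factors(protrusion = 9)))),
    "infeasible")
})

test_that("contact factors plant exact contact relative enrichments", {
  p <- small_scene_params(
    seed = 65, n_frames = 6, noise = clean_noise, psf_sigma_px = 0,
    target = list(speed_px_per_frame = 4, onset_frame = 3),
    channels = list(membrane_reference = channel_factors(),
                    protein = channel_factors(protrusion_contact = 0.5,
                                              body_contact = 0.8),
                    target = channel_factors()))
  sim <- generate_scene(p)
  tm <- truth_metrics(sim$scene)
  cre <- tm[tm$metric == "contact_relative_enrichment" &
            tm$channel_role == "protein", ]
  # protrusion contacts are pure capsule flux: the planted factor exactly.
  # Body contacts can mix in capsule-root pixels (which carry the
  # protrusion modulation), so the truth value lies between the factors.
  expect_true(all(abs(cre$value[cre$region == "protrusion"] - 0.5) < 1e-12))
  expect_true(all(cre$value[cre$region == "body"] >= 0.5 - 1e-12 &
                  cre$value[cre$region == "body"] <= 0.8 + 1e-12))

  # with all protrusions away from the target, the ring is the only
  # contact and the body factor is exact
  pb <- small_scene_params(
    seed = 65, n_frames = 4, noise = clean_noise, psf_sigma_px = 0,
    protrusion_angles = c(pi / 2, pi, 3 * pi / 2),
    target = list(speed_px_per_frame = 4, onset_frame = 2),
    channels = list(membrane_reference = channel_factors(),
                    protein = channel_factors(protrusion_contact = 0.5,
                                              body_contact = 0.8),
                    target = channel_factors()))
  simb <- generate_scene(pb)
  tmb <- truth_metrics(simb$scene)
  creb <- tmb[tmb$metric == "contact_relative_enrichment" &
              tmb$channel_role == "protein", ]
  expect_true(all(abs(creb$value[creb$region == "body"] - 0.8) < 1e-12))
  expect_equal(sim$scene$first_contact_frame, 3L)
  # measured on the clean render through the truth masks
  f <- 5
  img <- get_channel(sim$stack, "protein", f)
  cm <- sim$scene$contacts[[f]]
  expect_equal(contact_relative_enrichment(img, cm$protrusion_contact,
                                           cm$protrusion_noncontact),
               0.5, tolerance = 1e-9)
})

test_that("truth masks satisfy the full invariant suite", {
  p <- small_scene_params(seed = 66, n_frames = 3,
                          target = list(speed_px_per_frame = 5,
                                        onset_frame = 2),
                          clusters = list(count = 3, amplitude = 3,
                                          radius_px = 2, delay_frames = 1))
  sim <- generate_scene(p)
  mm <- sim$scene$membrane
  expect_s3_class(mm, "membrane_masks")   # constructor enforced invariants
  expect_true(mm$valid)
  for (cm in sim$scene$contacts)
    expect_s3_class(cm, "contact_masks")
  expect_equal(nrow(sim$scene$clusters), 3)
  expect_true(all(sim$scene$clusters$location %in% c("protrusion", "body")))
})

test_that("uniform factors yield truth enrichment 1 everywhere", {
  sim <- generate_scene(small_scene_params(seed = 67))
  tm <- truth_metrics(sim$scene)
  expect_true(all(abs(tm$value[tm$metric == "enrichment" &
                               tm$region == "whole_membrane"] - 1) < 1e-12))
  ref <- tm[tm$channel_role == "membrane_reference" &
            tm$metric == "enrichment", ]
  expect_true(all(abs(ref$value - 1) < 1e-12))
})

test_that("pipeline error decreases as photon_scale grows", {
  errs <- numeric(0)
  for (ps in c(10, 1000)) {
    p <- small_scene_params(
      seed = 68, noise = list(photon_scale = ps, read_sigma = 0),
      channels = list(membrane_reference = channel_factors(),
                      protein = channel_factors(protrusion = 2)))
    sim <- generate_scene(p)
    ev <- run_event(sim$stack, test_config())
    tc <- ev$timecourse
    v <- tc$value[tc$metric == "relative_enrichment" &
                  tc$region == "protrusion" & tc$channel_role == "protein"]
    errs <- c(errs, abs(mean(v) - 2))
  }
  expect_lt(errs[2], errs[1] + 0.02)  # no degradation with more photons
})

test_that("invalid parameters error as specified", {
  expect_error(scene_params(field_size_px = 256, body_radius_px = 110,
                            protrusion_length_px = c(30, 40)),
               "exceeds the field")
  expect_error(scene_params(target = list(speed_px_per_frame = 2,
                                          onset_frame = 40), n_frames = 10),
               "beyond the time lapse")
  expect_error(scene_params(channels = list(
    membrane_reference = channel_factors(protrusion = 2))), "uniform")
})
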