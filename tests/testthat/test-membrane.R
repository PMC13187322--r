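test_that("inner body of a bright annulus is the enclosed disc", {
  img <- gaussian_blur(annulus_image(200, radius = 71), 2)
  cfg <- test_config()
  res <- segment_inner_body(img, cfg)
  expect_true(res$success)
  truth <- disc_mask(200, 71)
  expect_gte(jaccard(res$mask, truth), 0.95)
})

test_that("inner-body detection fails gracefully where it should", {
  cfg <- test_config()
  # uniformly bright disc: no enclosed dark interior
  img <- matrix(0, 200, 200)
  img[disc_mask(200, 71)] <- 100
  res <- segment_inner_body(gaussian_blur(img, 2), cfg)
  expect_false(res$success)
  expect_false(any(res$mask))
  # all-zero image
  res0 <- segment_inner_body(matrix(0, 64, 64), cfg)
  expect_false(res0$success)
  expect_false(any(res0$mask))
})

test_that("planted protrusions are recovered as distinct components", {
  p <- small_scene_params(seed = 21, n_protrusions = 8, noise = clean_noise,
                          psf_sigma_px = 0)
  sim <- generate_scene(p)
  cfg <- test_config(pre_rolling_ball_radius_px = 0, pre_blur_sigma_px = 0)
  seg <- gaussian_blur((get_channel(sim$stack, "membrane_reference", 1) +
                        get_channel(sim$stack, "receptor", 1)) / 2,
                       cfg$seg_blur_sigma_px)
  ib <- segment_inner_body(seg, cfg)
  expect_true(ib$success)
  mm <- segment_membrane(seg, ib$mask, cfg)
  lab <- label_mask(mm$protrusions, cfg$connectivity)
  expect_equal(max(lab), 8)
  # protrusion pixels sit at least body_dilate_px - 1 outside the inner body
  d2 <- protrusionQuant:::cpp_edt_sq(mm$inner_body)
  expect_true(all(sqrt(d2[mm$protrusions]) >= cfg$body_dilate_px - 1))
})

test_that("single-pixel specks never survive; ridge-free images are benign", {
  cfg <- test_config()
  img <- gaussian_blur(annulus_image(200, radius = 60), 2)
  ib <- segment_inner_body(img, cfg)
  mm <- segment_membrane(img, ib$mask, cfg)
  # every protrusion component (if any) has area >= 2
  lab <- label_mask(mm$protrusions)
  if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 2))
  # empty inner body -> invalid masks
  mm0 <- segment_membrane(img, img > Inf, cfg)
  expect_false(mm0$valid)
  expect_false(any(mm0$whole_membrane))
})

test_that("membrane mask invariants hold across random synthetic frames", {
  set.seed(22)
  for (i in 1:6) {
    p <- small_scene_params(seed = 100 + i,
                            n_protrusions = sample(3:8, 1),
                            body_radius_px = sample(50:62, 1))
    sim <- generate_scene(p)
    cfg <- test_config()
    ev <- run_event(sim$stack, cfg)
    for (mm in ev$masks) {
      if (!mm$valid) {
        expect_false(any(mm$whole_membrane))
        next
      }
      expect_false(any(mm$protrusions & mm$body_membrane))
      expect_identical(mm$whole_membrane, mm$protrusions | mm$body_membrane)
      expect_false(any(mm$protrusions & mm$inner_body))
      expect_true(all(mm$neighbourhood[mm$protrusions]))
      expect_true(all(mm$neighbourhood[mm$inner_body]))
    }
  }
})

test_that("segmentation is invariant to positive intensity scaling", {
  p <- small_scene_params(seed = 23)
  sim <- generate_scene(p)
  cfg <- test_config(pre_rolling_ball_radius_px = 0)
  seg <- gaussian_blur((get_channel(sim$stack, "membrane_reference", 1) +
                        get_channel(sim$stack, "receptor", 1)) / 2,
                       cfg$seg_blur_sigma_px)
  run <- function(img) {
    ib <- segment_inner_body(img, cfg)
    segment_membrane(img, ib$mask, cfg)
  }
  mm1 <- run(seg)
  mm2 <- run(seg * 13.7)
  expect_identical(mm1$protrusions, mm2$protrusions)
  expect_identical(mm1$whole_membrane, mm2$whole_membrane)
})

test_that("protrusion recovery: recall exact, precision at 1-px tolerance", {
  # SNR 10 scenes; see the methods vignette for why precision is scored
  # against the 1-px-dilated truth (the blur chain widens a 3-px ridge)
  hits <- 0
  for (i in 1:3) {
    p <- small_scene_params(seed = 200 + i)
    sim <- generate_scene(p)
    cfg <- test_config()
    ev <- run_event(sim$stack, cfg)
    mm <- ev$masks[[1]]
    truth <- sim$scene$membrane$protrusions
    recall <- sum(mm$protrusions & truth) / sum(truth)
    tol_truth <- dilate_mask(truth, 1)
    precision <- sum(mm$protrusions & tol_truth) / sum(mm$protrusions)
    expect_gte(recall, 0.8)
    expect_gte(precision, 0.8)
  }
})
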