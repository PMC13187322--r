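test_that("target threshold comes from the last frame and tracks motion", {
  # two-level toy: background 10, object 100 appearing only late
  nf <- 4
  arr <- array(10, dim = c(nf, 1, 40, 40))
  arr[3, 1, , 21:40] <- 100
  arr[4, 1, , 11:40] <- 100
  st <- frame_stack(arr, c(target = 1))
  cfg <- test_config(pre_rolling_ball_radius_px = 0, seg_blur_sigma_px = 0)
  masks <- segment_target(st, cfg)
  expect_false(any(masks[[1]]))              # absent early
  expect_equal(sum(masks[[3]]), 40 * 20)     # exact object masks
  expect_equal(sum(masks[[4]]), 40 * 30)     # follows motion
  expect_error(segment_target(frame_stack(arr, c(protein = 1)), cfg),
               "target")
})

test_that("all-background stacks yield empty target masks", {
  arr <- array(5, dim = c(2, 1, 30, 30))
  st <- frame_stack(arr, c(target = 1))
  cfg <- test_config(pre_rolling_ball_radius_px = 0, seg_blur_sigma_px = 0)
  masks <- segment_target(st, cfg)
  expect_false(any(vapply(masks, any, TRUE)))
})

test_that("contact partition arithmetic is exact", {
  e <- matrix(FALSE, 30, 30)
  prot <- e; prot[10, 1:30] <- TRUE; prot[12, 1:30] <- TRUE;
  prot[14, 1:30] <- TRUE; prot[16, 1:30] <- TRUE  # 120 px
  body <- e; body[20:21, 1:20] <- TRUE
  inner <- e
  mm <- membrane_masks(inner, dilate_mask(prot | body, 30), prot, body,
                       prot | body, valid = TRUE)
  target <- e; target[, 1:18] <- TRUE; target[10, 19] <- TRUE
  # half-plane overlapping 4*18 + 1 = 73 of 120 protrusion pixels
  cm <- compute_contacts(mm, target)
  expect_equal(sum(cm$protrusion_contact), 73)
  expect_equal(sum(cm$protrusion_noncontact), 47)
  expect_identical(cm$protrusion_contact | cm$protrusion_noncontact, prot)
  expect_false(any(cm$protrusion_contact & cm$protrusion_noncontact))
  expect_true(all(cm$target[cm$body_contact]))

  # target covering the whole field / disjoint target
  cm_all <- compute_contacts(mm, !e | TRUE)
  expect_identical(cm_all$protrusion_contact, prot)
  expect_false(any(cm_all$protrusion_noncontact))
  cm_none <- compute_contacts(mm, e)
  expect_false(any(cm_none$protrusion_contact))
  expect_false(any(cm_none$body_contact))
})

test_that("first-contact detection: planted onset, edge cases, monotonicity", {
  p <- small_scene_params(seed = 31, n_frames = 10,
                          target = list(speed_px_per_frame = 3,
                                        onset_frame = 7))
  sim <- generate_scene(p)
  cfg <- test_config()
  ev <- run_event(sim$stack, cfg)
  expect_equal(ev$t0_frame, 7L)
  expect_equal(sim$scene$first_contact_frame, 7L)

  # truth-mask route: onset exact by construction, and raising
  # min_contact_px never yields an earlier frame
  prev <- -Inf
  for (mc in c(1, 5, 20, 100)) {
    f <- detect_first_contact(sim$scene$contacts,
                              test_config(min_contact_px = mc))
    if (!is.na(f)) expect_gte(f, prev)
    if (!is.na(f)) prev <- f
  }
  expect_equal(detect_first_contact(sim$scene$contacts, cfg), 7L)

  # contact from frame 1 and never-contact
  p1 <- small_scene_params(seed = 32, n_frames = 3,
                           target = list(speed_px_per_frame = 2,
                                         onset_frame = 1))
  sim1 <- generate_scene(p1)
  expect_equal(detect_first_contact(sim1$scene$contacts, cfg), 1L)
  p2 <- small_scene_params(seed = 33, n_frames = 3)
  sim2 <- generate_scene(p2)
  expect_true(is.na(detect_first_contact(sim2$scene$contacts, cfg)))
  expect_error(detect_first_contact(list(), cfg), "empty")
})

test_that("contact-area fractions sum to 100 or are missing", {
  e <- matrix(FALSE, 10, 10)
  prot <- e; prot[1, 1:6] <- TRUE
  body <- e; body[5, 1:9] <- TRUE
  mm <- membrane_masks(e, dilate_mask(prot | body, 9), prot, body,
                       prot | body, valid = TRUE)
  tg <- e; tg[1, 1:3] <- TRUE; tg[5, 1:7] <- TRUE
  fr <- contact_area_fractions(compute_contacts(mm, tg))
  expect_equal(fr[["protrusion_pct"]], 100 * 3 / 10)
  expect_equal(fr[["body_pct"]], 100 * 7 / 10)
  expect_equal(sum(fr), 100, tolerance = 1e-9)

  tg2 <- e; tg2[1, 1:4] <- TRUE
  fr2 <- contact_area_fractions(compute_contacts(mm, tg2))
  expect_equal(unname(fr2), c(100, 0))

  fr3 <- contact_area_fractions(compute_contacts(mm, e))
  expect_true(all(is.na(fr3)))
})
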