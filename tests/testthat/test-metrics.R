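toy_masks <- function() {
  whole <- matrix(FALSE, 6, 6)
  whole[2, 1:6] <- TRUE; whole[4, 1:6] <- TRUE   # 12 membrane px
  region <- matrix(FALSE, 6, 6)
  region[2, 1:4] <- TRUE                          # 4 px
  list(whole = whole, region = region)
}

test_that("enrichment: toy arithmetic, identity, scale invariance", {
  m <- toy_masks()
  img <- matrix(0, 6, 6)
  img[m$whole] <- 2.5                 # membrane mean 5 with the region at 10
  img[m$region] <- 10
  img[4, 1:6] <- (12 * 5 - 4 * 10) / 8  # fix membrane mean at exactly 5
  expect_equal(mean(img[m$whole]), 5)
  expect_equal(enrichment(img, m$region, m$whole), 2)
  expect_equal(enrichment(img, m$whole, m$whole), 1)
  expect_equal(enrichment(img * 3, m$region, m$whole), 2)

  u <- matrix(7, 6, 6)
  expect_equal(enrichment(u, m$region, m$whole), 1)
  expect_true(is.na(enrichment(img, m$region & FALSE, m$whole)))
  expect_error(enrichment(img, m$region, m$whole & FALSE), "empty")
  expect_error(enrichment(img * 0, m$region, m$whole), "> 0")
})

test_that("membrane-max normalisation leaves enrichment unchanged", {
  m <- toy_masks()
  set.seed(14)
  img <- matrix(rexp(36) + 0.1, 6, 6)
  norm <- normalize_to_max(img, m$whole)
  expect_equal(enrichment(norm, m$region, m$whole),
               enrichment(img, m$region, m$whole), tolerance = 1e-12)
  expect_equal(max(norm[m$whole]), 1)
})

test_that("relative enrichment is the ratio to the reference", {
  expect_equal(relative_enrichment(1.5, 1.2), 1.25)
  expect_equal(relative_enrichment(1.07, 1.07), 1)
  expect_error(relative_enrichment(1.5, 0), "> 0")
  r <- relative_enrichment(uval(1.5, 0.1), uval(1.2, 0))
  expect_equal(r$value, 1.25)
})

test_that("contact metrics: ratios, differences, missing sub-masks", {
  m <- toy_masks()
  rc <- matrix(FALSE, 6, 6); rc[2, 1:3] <- TRUE
  rn <- matrix(FALSE, 6, 6); rn[2, 4:6] <- TRUE
  img <- matrix(1, 6, 6)
  img[rc] <- 12; img[rn] <- 8
  expect_equal(contact_relative_enrichment(img, rc, rn), 1.5)
  expect_equal(contact_relative_enrichment(matrix(4, 6, 6), rc, rn), 1)
  expect_true(is.na(contact_relative_enrichment(img, rc & FALSE, rn)))

  # enrichments 1.8 and 1.2 -> membrane-bound 0.6
  extra <- matrix(FALSE, 6, 6); extra[6, 1:6] <- TRUE
  whole <- rc | rn | extra
  img2 <- matrix(0, 6, 6)
  img2[rc] <- 1.8; img2[rn] <- 1.2; img2[extra] <- 0.5  # membrane mean 1
  expect_equal(mean(img2[whole]), 1)
  expect_equal(membrane_bound(img2, rc, rn, whole), 0.6)
  expect_equal(membrane_bound(matrix(2, 6, 6), rc, rn, whole), 0)
})

test_that("relative membrane-bound follows ratio propagation", {
  r <- relative_membrane_bound(uval(0.6, 0.5), uval(1.2, 0.1))
  expect_equal(r$value, 0.5)
  expect_equal(r$sem, 0.5 * sqrt((0.5 / 0.6)^2 + (0.1 / 1.2)^2))
  # unit reference is the identity
  r1 <- relative_membrane_bound(uval(0.6, 0.5), uval(1, 0))
  expect_equal(r1$value, 0.6)
  expect_equal(r1$sem, 0.5)
  # zero-valued numerator convention
  r0 <- relative_membrane_bound(uval(0, 0.4), uval(1.25, 0.2))
  expect_equal(r0$value, 0)
  expect_equal(r0$sem, 0.4 / 1.25)
  expect_error(relative_membrane_bound(uval(1, 0), NULL), "configuration")
})

test_that("window aggregation: arithmetic, inclusivity, missing frames", {
  tc <- data.frame(t_s = c(0, 4, 8), value = c(1, 2, 3))
  u <- aggregate_window(tc, window_s = c(0, 60))
  expect_equal(u$value, 2)
  expect_equal(u$sem, sd(1:3) / sqrt(3))
  expect_equal(round(u$sem, 3), 0.577)

  const <- data.frame(t_s = seq(0, 56, 4), value = 1.3)
  uc <- aggregate_window(const)
  expect_equal(uc$value, 1.3)
  expect_equal(uc$sem, 0)

  # t = 60 s frame included (inclusive window), pre-contact excluded
  tc2 <- data.frame(t_s = c(-4, 0, 60, 64), value = c(99, 1, 3, 99))
  u2 <- aggregate_window(tc2, window_s = c(0, 60))
  expect_equal(u2$value, 2)
  expect_equal(attr(u2, "n"), 2)

  # missing values skipped and counted
  tc3 <- data.frame(t_s = c(0, 4, 8), value = c(1, NA, 3))
  u3 <- aggregate_window(tc3)
  expect_equal(u3$value, 2)
  expect_equal(attr(u3, "n_missing"), 1)
  expect_error(aggregate_window(tc3, window_s = c(1000, 2000)), "window")
})

test_that("4 s and 15 s events pool in a common 2-minute window", {
  tc4 <- data.frame(t_s = seq(0, 120, 4), value = 2)
  tc15 <- data.frame(t_s = seq(0, 120, 15), value = 3)
  u4 <- aggregate_window(tc4, window_s = c(0, 120))
  u15 <- aggregate_window(tc15, window_s = c(0, 120))
  expect_equal(attr(u4, "n"), 31)
  expect_equal(attr(u15, "n"), 9)
  expect_equal(mean(c(u4$value, u15$value)), 2.5)
})

test_that("metrics are invariant to multiplicative rescaling end to end", {
  sim <- generate_scene(small_scene_params(seed = 51))
  cfg <- test_config(pre_rolling_ball_radius_px = 0)
  ev1 <- run_event(sim$stack, cfg)
  stack2 <- sim$stack
  stack2$data <- stack2$data * 41.7
  ev2 <- run_event(stack2, cfg)
  v1 <- ev1$timecourse$value
  v2 <- ev2$timecourse$value
  expect_equal(v1, v2, tolerance = 1e-9)
})
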