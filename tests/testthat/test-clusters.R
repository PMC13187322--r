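make_cluster_frame <- function() {
  # ring cell with one protrusion arm; membrane mean will be ~1
  e <- matrix(FALSE, 80, 80)
  inner <- disc_mask(80, 20)
  ring <- disc_mask(80, 23) & !inner
  prot <- e; prot[40, 64:75] <- TRUE; prot[41, 64:75] <- TRUE
  body <- ring
  mm <- membrane_masks(inner, dilate_mask(inner, 35), prot, body,
                       prot | body, valid = TRUE)
  img <- matrix(0.02, 80, 80)
  img[inner] <- 0.1
  img[body] <- 1
  img[prot] <- 1
  list(mm = mm, img = img)
}

test_that("threshold is strictly above, area bounds are inclusive", {
  fx <- make_cluster_frame()
  mem_mean <- mean(fx$img[fx$mm$whole_membrane])
  # a pixel at exactly 2x the membrane mean is excluded
  img <- fx$img
  img[10, 10] <- 2 * mem_mean
  cs <- segment_clusters(img, fx$mm, test_config())
  expect_equal(nrow(cs$table), 0)

  # 4-px component rejected, 5-px kept (areas recomputed after planting)
  img4 <- fx$img; img4[30, 10:13] <- 10
  img5 <- fx$img; img5[30, 10:14] <- 10
  n4 <- nrow(segment_clusters(img4, fx$mm, test_config())$table)
  n5 <- nrow(segment_clusters(img5, fx$mm, test_config())$table)
  expect_equal(n4, 0)
  expect_equal(n5, 1)

  # uniform image: nothing exceeds 2x its own mean
  u <- matrix(3, 80, 80)
  expect_equal(nrow(segment_clusters(u, fx$mm, test_config())$table), 0)
})

test_that("cluster location assignment follows the larger overlap", {
  fx <- make_cluster_frame()
  img <- fx$img
  img[40:41, 65:68] <- 10          # 8 px on the protrusion arm
  img[18:20, 39:41] <- 10          # 9 px blob on the top of the ring
  img[70, 10:16] <- 10             # 7 px off-membrane
  cs <- segment_clusters(img, fx$mm, test_config())
  tab <- cs$table
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$location, c("protrusion", "body", "unassigned"))
  expect_gt(tab$receptor_enrichment[tab$location == "protrusion"], 2)
})

test_that("cluster detection is scale-invariant and area-monotone", {
  fx <- make_cluster_frame()
  img <- fx$img
  img[40:41, 65:68] <- 10
  img[18:20, 39:41] <- 10
  a <- segment_clusters(img, fx$mm, test_config())
  b <- segment_clusters(img * 117, fx$mm, test_config())
  expect_identical(a$labels, b$labels)
  expect_equal(a$table$receptor_enrichment, b$table$receptor_enrichment)

  wide <- test_config(cluster_area_min_px = 5, cluster_area_max_px = 100)
  tight <- test_config(cluster_area_min_px = 8, cluster_area_max_px = 9)
  expect_gte(nrow(segment_clusters(img, fx$mm, wide)$table),
             nrow(segment_clusters(img, fx$mm, tight)$table))
})

test_that("per-cluster channel ratios group by location and flag zeros", {
  tab <- data.frame(id = 1:5, area_px = 10,
                    location = c("protrusion", "protrusion", "body",
                                 "body", "protrusion"),
                    cd45_enrichment = c(0.5, 0.7, 0.9, 1.1, 0.6),
                    receptor_enrichment = c(2, 2, 2, 2, 0))
  out <- cluster_channel_ratio(tab, "cd45_enrichment",
                               "receptor_enrichment")
  expect_equal(out$n_excluded, 1)
  expect_equal(out$means[["protrusion"]], mean(c(0.5, 0.7) / 2))
  expect_equal(out$means[["body"]], mean(c(0.9, 1.1) / 2))

  # identical channels give ratio 1 everywhere
  tab2 <- data.frame(id = 1:2, area_px = 10,
                     location = c("protrusion", "body"),
                     a_enrichment = c(1.4, 2.2), b_enrichment = c(1.4, 2.2))
  out2 <- cluster_channel_ratio(tab2, "a_enrichment", "b_enrichment")
  expect_equal(unname(out2$means), c(1, 1))

  # no clusters at a location -> missing value
  tab3 <- tab2[tab2$location == "body", ]
  out3 <- cluster_channel_ratio(tab3, "a_enrichment", "b_enrichment")
  expect_true(is.na(out3$means[["protrusion"]]))
})

test_that("planted factor ratios are recovered at cluster sites", {
  # CD45-like exclusion 0.5 and CAR enrichment 2.0 inside clusters:
  # the per-cluster ratio of normalised means is ~0.25 at SNR 10
  fx <- make_cluster_frame()
  set.seed(40)
  receptor <- fx$img; cd45 <- fx$img
  mem_mean <- mean(fx$img[fx$mm$whole_membrane])
  spots <- list(c(40, 41, 65, 69), c(18, 20, 39, 41))
  for (s in spots) {
    px <- expand.grid(y = s[1]:s[2], x = s[3]:s[4])
    sel <- cbind(px$y, px$x)
    receptor[sel] <- 2.0 * mem_mean
    cd45[sel] <- 0.5 * mem_mean
  }
  noisy <- function(img) matrix(rpois(length(img), img * 100) / 100,
                                nrow(img), ncol(img))
  cfg <- test_config(cluster_threshold = 1.5)
  cs <- segment_clusters(noisy(receptor), fx$mm, cfg,
                         extra_channels = list(cd45 = noisy(cd45)))
  expect_gte(nrow(cs$table), 1)
  ratio <- cs$table$cd45_enrichment / cs$table$receptor_enrichment
  expect_true(all(abs(ratio / 0.25 - 1) < 0.10))
})
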