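make_timing_tree <- function() {
  # AB divides at 41 (daughters born 41); ABa 41..80 divides into
  # ABal/ABar at 81; ABal divides at 101, ABar at 111
  build_lineage(manual_recording(list(
    list(cell = "AB", frames = 1:40),
    list(cell = "ABa", frames = 41:80),
    list(cell = "ABp", frames = 41:130),
    list(cell = "ABal", frames = 81:100),
    list(cell = "ABar", frames = 81:110),
    list(cell = "ABala", frames = 101:130),
    list(cell = "ABalp", frames = 101:130),
    list(cell = "ABara", frames = 111:130),
    list(cell = "ABarp", frames = 111:130)
  ), frame_interval_min = 1.5))
}

test_that("cycle lengths are frame differences in minutes with censoring", {
  tree <- make_timing_tree()
  cyc <- cycle_lengths(tree)
  get <- function(cell) cyc[cyc$cell == cell, ]
  # born frame 41, daughters at 81: 40 frames x 1.5 = 60 min
  expect_false(get("ABal")$censored)
  expect_equal(get("ABal")$cycle_length_min, 30)
  expect_equal(get("ABar")$cycle_length_min, 45)
  # the first two rounds are always excluded
  expect_equal(get("ABa")$censor_reason, "early-round-excluded")
  expect_equal(get("AB")$censor_reason, "early-round-excluded")
  # alive at cutoff without daughters
  expect_equal(get("ABala")$censor_reason, "undivided-at-cutoff")
  expect_equal(get("ABara")$censor_reason, "undivided-at-cutoff")
})

test_that("ADS is the absolute daughter cycle difference, symmetric", {
  tree <- make_timing_tree()
  ads <- compute_ads(tree, "ABa")
  # ABal cycle 30, ABar cycle 45
  expect_equal(ads$ads_min, 15)
  expect_equal(ads$signed_ads_min, -15)
  expect_equal(ads$ads_min, abs(ads$signed_ads_min))
  expect_error(compute_ads(tree, "ABala"), "not divided")
  pm <- pair_measures(tree)
  expect_equal(sum(abs(pm$signed_ads_min), na.rm = TRUE),
               sum(pm$ads_min, na.rm = TRUE))
})

test_that("equal division frames give zero ADS", {
  tree <- build_lineage(manual_recording(list(
    list(cell = "ABa", frames = 1:10),
    list(cell = "ABal", frames = 11:30),
    list(cell = "ABar", frames = 11:30),
    list(cell = "ABala", frames = 31:40),
    list(cell = "ABalp", frames = 31:40),
    list(cell = "ABara", frames = 31:40),
    list(cell = "ABarp", frames = 31:40)
  )))
  expect_equal(compute_ads(tree, "ABa")$ads_min, 0)
})

test_that("ADS is invariant to frame shifts and scales with time", {
  tabs <- wt_tables()
  pm1 <- tabs[[1]]$pairs
  # uniform rescaling: recompute with doubled frame interval
  pm2 <- pair_measures(tabs[[1]]$tree, frame_interval_min = 3,
                       cutoff_frame = attr(tabs[[1]]$cycles, "cutoff_frame"))
  ok <- !pm1$censored
  expect_equal(pm2$ads_min[ok], 2 * pm1$ads_min[ok])
})

test_that("correlation matrix matches a hand-rolled Pearson oracle", {
  tabs <- wt_tables()
  cts <- lapply(tabs[1:4], `[[`, "cycles")
  cm <- correlation_matrix(cts)
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm, t(cm))
  # oracle: explicit covariance/variance ratio on shared cells
  a <- cts[[1]][!cts[[1]]$censored, ]
  b <- cts[[2]][!cts[[2]]$censored, ]
  shared <- intersect(a$cell, b$cell)
  x <- a$cycle_length_min[match(shared, a$cell)]
  y <- b$cycle_length_min[match(shared, b$cell)]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm[1, 2], oracle, tolerance = 1e-12)
  # affine invariance: clone with all lengths x 1.1
  clone <- cts[[1]]
  clone$cycle_length_min <- clone$cycle_length_min * 1.1
  cm2 <- correlation_matrix(list(cts[[1]], clone))
  expect_equal(cm2[1, 2], 1, tolerance = 1e-12)
})

test_that("complete-linkage Manhattan clustering merges as enumerated", {
  # 3 rows with pairwise L1 distances d12 = 1, d13 = 5, d23 = 5 (up to
  # small asymmetry): first merge must be (1,2), final height 5
  m <- rbind(c(1.0, 0.5, 0.1),
             c(1.0, 0.5, 1.1),
             c(1.0, 5.0, 0.6))
  cl <- cluster_embryos(m)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  expect_equal(max(cl$hclust$height), 5)
  expect_setequal(cl$order, 1:3)
  # identical rows merge at height zero first
  m2 <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9))
  cl2 <- cluster_embryos(m2)
  expect_equal(cl2$hclust$height[1], 0)
  expect_error(cluster_embryos(m[1, , drop = FALSE]), "at least 2")
})

test_that("generation SD profile is zero without noise, filtered by min_n", {
  tpl <- default_template()
  coh <- simulate_cohort(tpl, noise_model(sigma0 = 0, kappa = 0, rho = 0),
                         n = 4, seed = 5)
  cts <- lapply(cohort_tables(coh), `[[`, "cycles")
  prof <- generation_sd_profile(cts, min_n = 3)
  expect_true(all(prof$mean_sd_min < 1e-6))
  # a cell present in fewer than min_n embryos is excluded
  cts2 <- cts
  cts2[[1]] <- rbind(cts2[[1]],
                     data.frame(cell = "ABprvvv", founder = "ABp",
                                generation = 9, cycle_length_min = 50,
                                censored = FALSE, censor_reason = NA))
  prof2 <- generation_sd_profile(cts2, min_n = 3)
  expect_false(9 %in% prof2$generation)
})
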