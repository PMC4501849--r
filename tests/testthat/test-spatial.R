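test_that("the last four-cell frame is found or reported missing", {
  rec <- wt_cohort()[[1]]
  f4 <- last_four_cell_frame(rec)
  tree <- build_lineage(rec)
  aba_div <- tree$last_frame[tree$name == "ABa"]
  expect_lte(f4, aba_div)
  expect_equal(cell_count_at(rec, f4), 4L)
  expect_gt(cell_count_at(rec, f4 + 1L), 4L)
  # recording starting at 6 cells has no four-cell frame
  six <- manual_recording(list(
    list(cell = "ABal", frames = 1:5), list(cell = "ABar", frames = 1:5),
    list(cell = "ABpl", frames = 1:5), list(cell = "ABpr", frames = 1:5),
    list(cell = "EMS", frames = 1:5), list(cell = "P2", frames = 1:5)
  ))
  expect_error(last_four_cell_frame(six), "no four-cell")
})

test_that("axis normalization is rigid-motion invariant and bounded", {
  rec <- wt_cohort()[[1]]
  nz <- normalize_axes(rec)
  rot <- nz$transform$rotation
  expect_lt(max(abs(rot %*% t(rot) - diag(3))), 1e-9)
  expect_equal(det(rot), 1, tolerance = 1e-9)
  xyz <- as.matrix(nz$recording$observations[, c("x", "y", "z")])
  expect_true(all(xyz >= -1 - 1e-12 & xyz <= 1 + 1e-12))
  expect_equal(nz$recording$observations$time_min[
    nz$recording$observations$frame == nz$transform$reference_frame][1], 0)
  set.seed(55)
  for (i in 1:5) {
    moved <- rigid_motion(rec, random_rotation(), rnorm(3, 0, 100))
    nz2 <- normalize_axes(moved)
    xyz2 <- as.matrix(nz2$recording$observations[, c("x", "y", "z")])
    expect_lt(max(abs(xyz - xyz2)), 1e-9)
  }
})

test_that("canonical four-cell geometry yields canonical axes", {
  rec <- canonical_recording()
  tf <- normalize_axes(rec)$transform
  expect_equal(tf$rotation["AP", ], c(1, 0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unname(abs(tf$rotation["LR", 2])), 1, tolerance = 1e-12)
})

test_that("division angles reproduce the analytic cases", {
  tf <- normalize_axes(canonical_recording())$transform
  # separation along A-P: in plane AP-LR and AP-DV, normal to LR-DV
  a1 <- division_angles(canonical_recording(c(2, 0, 0)), "ABa", tf)
  expect_equal(unname(a1), c(0, 0, 90), tolerance = 1e-6)
  # (1,1,0)/sqrt(2) in (AP, LR, DV) components -> 0, 45, 45
  a2 <- division_angles(canonical_recording(c(2, -2, 0)), "ABa", tf)
  expect_equal(unname(a2), c(0, 45, 45), tolerance = 1e-6)
  # scale invariance
  a3 <- division_angles(canonical_recording(c(20, -20, 0)), "ABa", tf)
  expect_equal(a2, a3, tolerance = 1e-9)
  # squared direction cosines against the three normals sum to one
  rec <- wt_cohort()[[2]]
  tf2 <- normalize_axes(rec)$transform
  ang <- division_angles(rec, "ABplpa", tf2)
  expect_equal(sum(sin(ang * pi / 180)^2), 1, tolerance = 1e-9)
})

test_that("trajectories concatenate the ancestor chain", {
  rec <- wt_cohort()[[1]]
  tr <- trajectory(rec, "ABplpapa", start = "ABp")
  expect_equal(tr$cell[1], "ABp")
  expect_equal(tr$cell[nrow(tr)], "ABplpapa")
  expect_true(all(diff(tr$frame) == 1))
  obs <- rec$observations
  chain_len <- sum(obs$cell %in% c("ABp", "ABpl", "ABplp", "ABplpa",
                                   "ABplpap", "ABplpapa"))
  expect_equal(nrow(tr), chain_len)
  expect_error(trajectory(rec, "ABplpapa", start = "ABar"),
               "not an observed ancestor")
  # a single-cell path is constant-position for the static placement model
  one <- trajectory(rec, "ABpl", start = "ABpl")
  expect_equal(length(unique(one$x)), 1L)
})

test_that("positional deviation separates shifted cells from wild type", {
  coh <- fixture("norm_coh", {
    lapply(wt_cohort(), function(r) normalize_axes(r)$recording)
  })
  cell <- "ABplpapa"
  pd_self <- position_deviation(coh[[1]], coh[-1], cell)
  expect_gte(pd_self$p, 0.01)
  # wild-type leave-one-out p-values center near 0.5
  ps <- vapply(seq_along(coh), function(i) {
    position_deviation(coh[[i]], coh[-i], cell)$p
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
  # a shift of about five wild-type positional SDs is detected
  shifted <- simulate_embryo(default_template(), seed = 606,
                             perturb = perturbation(position_shift = list(
                               cell = "ABplpa", shift = c(0.7, 0.5, 0.3))))
  sn <- normalize_axes(shifted)$recording
  pd_shift <- position_deviation(sn, coh, cell)
  expect_lt(pd_shift$p, 0.05)
  expect_error(position_deviation(coh[[1]], coh[-1], "Z9"), "")
})

test_that("Box-Cox lambda maximizes the profile likelihood", {
  expect_error(boxcox_lambda_mle(c(rep(1, 20), 0)), "positive")
  expect_error(boxcox_lambda_mle(rlnorm(5)), "n >= 10")
  set.seed(71)
  x <- rlnorm(60, 1, 0.8)
  lam <- boxcox_lambda_mle(x)
  # the profile log-likelihood at the optimum beats a surrounding grid
  llf <- function(l) {
    y <- boxcox_transform(x, l)
    (l - 1) * sum(log(x)) - length(x) / 2 * log(mean((y - mean(y))^2))
  }
  grid <- seq(-2, 2, by = 0.05)
  expect_gte(llf(lam), max(vapply(grid, llf, 1)) - 1e-6)
  skip_if_not_installed("MASS")
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.001), plotit = FALSE)
  expect_lt(abs(lam - bc$x[which.max(bc$y)]), 2e-3)
})

test_that("angle deviation transforms, de-noises and scores as specified", {
  set.seed(81)
  wt <- pmin(pmax(rnorm(60, 40, 6), 1), 89)
  ad0 <- angle_deviation(wt, mean(wt))
  expect_gt(ad0$p, 0.5)
  # a perturbed angle placed exactly at transformed z = 2.576
  lam <- ad0$reference$lambda
  y_target <- ad0$reference$mean + 2.576 * ad0$reference$sd
  x_target <- if (abs(lam) < 1e-8) exp(y_target)
  else (y_target * lam + 1)^(1 / lam)
  ad1 <- angle_deviation(wt, x_target)
  expect_equal(ad1$p, 0.01, tolerance = 1e-2)
  # an injected far outlier is removed; lambda is fitted before removal
  y <- boxcox_transform(pmax(wt, 0.1), boxcox_lambda_mle(pmax(wt, 0.1)))
  spike_y <- mean(y) + 8 * sd(y)
  spike_x <- if (abs(lam) < 1e-8) exp(spike_y)
  else (spike_y * lam + 1)^(1 / lam)
  wt_spiked <- c(wt, spike_x)
  ad2 <- angle_deviation(wt_spiked, mean(wt))
  expect_gte(ad2$reference$n_outliers, 1L)
  expect_equal(ad2$reference$lambda,
               boxcox_lambda_mle(pmax(wt_spiked, 0.1)), tolerance = 1e-9)
})
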