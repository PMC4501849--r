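test_that("templates are deterministic and carry the designated pairs", {
  t1 <- make_template(seed = 3)
  t2 <- make_template(seed = 3)
  expect_identical(t1, t2)
  t3 <- make_template(seed = 4)
  expect_false(identical(t1, t3))
  expect_setequal(intersect(attr(t1, "async_pairs")$parent, t1$name),
                  default_async_pairs()$parent)
  expect_error(make_template(rounds = 3), "rounds")
  # founder skeleton present
  expect_true(all(c("AB", "P1", "EMS", "P2", "MS", "E", "C", "P3",
                    "D", "P4", "Z2", "Z3") %in% t1$name))
})

test_that("simulated embryos are reproducible and reach the 350-cell stage", {
  tpl <- default_template()
  r1 <- simulate_embryo(tpl, seed = 11)
  r2 <- simulate_embryo(tpl, seed = 11)
  expect_identical(r1$observations, r2$observations)
  r3 <- simulate_embryo(tpl, seed = 12)
  expect_false(identical(r1$observations, r3$observations))
  # 350 concurrent cells before frame 240
  sc <- speed_curve(r1)
  expect_gte(max(sc$count), 350)
  expect_lte(min(sc$frame[sc$count >= 350]), 240)
  expect_true(validate_recording(r1)$id == r1$id)
})

test_that("realized cycle lengths sit on the 1.5-minute frame grid", {
  tree <- build_lineage(wt_cohort()[[3]])
  cyc <- cycle_lengths(tree)
  v <- cyc$cycle_length_min[!cyc$censored]
  expect_true(all(abs(v / 1.5 - round(v / 1.5)) < 1e-9))
  expect_true(all(v > 0))
})

test_that("collapsing a pair's asynchrony floors its ADS at one frame", {
  tpl <- default_template()
  rec <- simulate_embryo(tpl, seed = 21,
                         perturb = perturbation(
                           ads_factor = c(ABplpp = 0),
                           variance_inflation = 1e-12))
  tree <- build_lineage(rec)
  ads <- compute_ads(tree, "ABplpp")
  expect_lte(ads$ads_min, 1.5)
})

test_that("a global slowdown scales cycles and preserves correlation", {
  tpl <- default_template()
  wt <- simulate_embryo(tpl, seed = 31)
  slow <- simulate_embryo(tpl, seed = 31,
                          perturb = perturbation(slowdown = 1.3))
  cw <- cycle_lengths(build_lineage(wt))
  cs <- cycle_lengths(build_lineage(slow))
  shared <- intersect(cw$cell[!cw$censored], cs$cell[!cs$censored])
  ratio <- cs$cycle_length_min[match(shared, cs$cell)] /
    cw$cycle_length_min[match(shared, cw$cell)]
  expect_equal(median(ratio), 1.3, tolerance = 0.02)
  cm <- correlation_matrix(list(cw, cs))
  expect_gte(cm[1, 2], 0.99)
})

test_that("per-cell noise SD is recovered across many embryos", {
  tpl <- default_template()
  nm <- noise_model(rho = 0) # shared-speed component off: SD is sigma(c)
  coh <- simulate_cohort(tpl, nm, n = 150, seed = 41)
  cts <- lapply(coh, function(r) {
    cycle_lengths(build_lineage(r), cutoff_frame = cutoff_frame_350(r))
  })
  pooled <- do.call(rbind, lapply(cts, function(tb) tb[!tb$censored, ]))
  counts <- table(pooled$cell)
  keep <- names(counts)[counts >= 140]
  # mid-generations: late cells near the cutoff are truncation-biased
  info <- pooled[pooled$cell %in% keep & pooled$generation %in% 4:7, ]
  sds <- tapply(info$cycle_length_min, info$cell, sd)
  gens <- tapply(info$generation, info$cell, unique)
  expected <- sqrt((nm$sigma0 + nm$kappa * gens)^2 + 2 * 1.5^2 / 12)
  rel_err <- abs(sds - expected) / expected
  expect_lt(mean(rel_err), 0.10)
  expect_lt(max(rel_err), 0.30)
})

test_that("screen datasets replay identically and carry the truth table", {
  tpl <- default_template()
  specs <- list(
    null_gene = perturbation(),
    collapse = perturbation(ads_factor = c(P3 = 0.2))
  )
  d1 <- simulate_screen_dataset(tpl, gene_specs = specs, replicates = 2,
                                seed = 51, wt_n = 2)
  d2 <- simulate_screen_dataset(tpl, gene_specs = specs, replicates = 2,
                                seed = 51, wt_n = 2)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$perturbed$collapse[[1]]$observations,
                   d2$perturbed$collapse[[1]]$observations)
  expect_equal(nrow(d1$truth), length(specs))
  expect_true("null_gene" %in% d1$truth$gene)
  man <- attr(d1$wildtype, "manifest")
  expect_equal(nrow(man), 2L)
})

test_that("arrest before the four-cell stage is rejected", {
  expect_error(
    simulate_embryo(default_template(), seed = 61,
                    perturb = perturbation(arrest_frame = 5)),
    "four-cell"
  )
})
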