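single_pair_ref <- function(mean = 10, sd = 1) {
  ref <- wt_reference(data.frame(parent = "pairA", n = 91,
                                 mean_ads_min = mean, sd_ads_min = sd))
  ref$monitored <- "pairA"
  ref
}

test_that("QC applies the 300-cell and 350-by-240 rules", {
  wt <- wt_cohort()[[1]]
  expect_true(qc_embryo(wt)$pass)
  # arrest well before 300 cells
  arrested <- simulate_embryo(default_template(),
                              perturb = perturbation(arrest_cell_count = 200),
                              seed = 77)
  qa <- qc_embryo(arrested)
  expect_false(qa$pass)
  expect_true("under-300-at-last-editable" %in% qa$reasons)
  # strong slowdown: never reaches 350 cells within the 240-frame movie
  slow <- simulate_embryo(default_template(),
                          perturb = perturbation(slowdown = 2.0),
                          seed = 78)
  qs <- qc_embryo(slow)
  expect_false(qs$pass)
  expect_true("under-350-at-frame-240" %in% qs$reasons)
})

test_that("hit calling applies reduction, direction and replication rules", {
  ref <- single_pair_ref(10, 1)
  mk <- function(a) draw_pair_table(a)
  # reductions 60/55%, z = -6/-5.5: both alphas in two replicates
  r <- call_hits(list(mk(4.0), mk(4.5), mk(9.0)), ref, gene = "g1")
  expect_equal(r$hits$hit_level, "0.01")
  expect_equal(r$hits$n_flag05, 2L)
  # 6.0 is significant but only a 40% reduction: no flags at all
  r2 <- call_hits(list(mk(6.0), mk(9.0), mk(9.0)), ref, gene = "g2")
  expect_equal(r2$hits$hit_level, "none")
  expect_equal(r2$hits$n_flag05, 0L)
  # a single flagged replicate is not enough
  r3 <- call_hits(list(mk(4.0), mk(9.0), mk(9.0)), ref)
  expect_equal(r3$hits$hit_level, "none")
  # censored replicates never flag
  cens <- mk(4.0); cens$censored <- TRUE
  r4 <- call_hits(list(cens, mk(4.0), mk(9.0)), ref)
  expect_equal(r4$hits$hit_level, "none")
  # no QC-passing replicates: unscreenable
  r5 <- call_hits(list(), ref, gene = "g5")
  expect_equal(r5$status, "unscreenable")
})

test_that("hit calling is replicate-order invariant and monotone", {
  ref <- single_pair_ref(10, 1)
  mk <- function(a) draw_pair_table(a)
  reps <- list(mk(4.0), mk(4.6), mk(9.2))
  r_fwd <- call_hits(reps, ref)
  r_rev <- call_hits(rev(reps), ref)
  expect_equal(r_fwd$hits$hit_level, r_rev$hits$hit_level)
  # removing a non-flagged replicate never upgrades the hit level
  r_drop <- call_hits(reps[1:2], ref)
  lv <- c(none = 0, "0.05" = 1, "0.01" = 2)
  expect_lte(lv[[r_drop$hits$hit_level]], lv[[r_fwd$hits$hit_level]])
})

test_that("0.01 hits are always 0.05 hits under random screens", {
  ref <- single_pair_ref(10, 2)
  set.seed(17)
  for (i in 1:50) {
    reps <- lapply(rnorm(3, runif(1, 2, 10), 2), draw_pair_table)
    h <- call_hits(reps, ref)$hits
    expect_gte(h$n_flag05, h$n_flag01)
    if (h$hit_level == "0.01") expect_gte(h$n_flag05, 2L)
  }
})

test_that("buffering flags inflated variance and skips thin generations", {
  set.seed(61)
  wt <- lapply(1:20, function(i) draw_cycle_table())
  pert <- lapply(1:3, function(i) draw_cycle_table(sd = 4)) # variance x4
  out <- buffering_test(pert, wt)
  expect_true(out$flag)
  expect_lt(out$min_p, 0.01)
  # a generation with < 3 cells on one side is skipped
  wt2 <- lapply(wt, function(tb) {
    rbind(tb, draw_cycle_table(n_cells = 5, generation = 8, prefix = "ABy"))
  })
  pert2 <- lapply(pert, function(tb) {
    rbind(tb, draw_cycle_table(n_cells = 0, generation = 8, prefix = "ABy"))
  })
  pert2[[1]] <- rbind(pert2[[1]],
                      draw_cycle_table(n_cells = 2, generation = 8,
                                       prefix = "ABy"))
  out2 <- buffering_test(pert2, wt2)
  g8 <- out2$table[out2$table$generation == 8, ]
  expect_true(g8$skipped)
  expect_true(is.na(g8$p))
  # absolute-deviation variant runs
  out3 <- buffering_test(pert, wt, absolute = TRUE)
  expect_true(is.finite(out3$min_p))
})

test_that("buffering detects the capacitor phenotype in full simulations", {
  tabs <- wt_tables()
  wt_cts <- lapply(tabs, `[[`, "cycles")
  tpl <- default_template()
  pert <- simulate_cohort(tpl, n = 3, seed = 303, target_gene = "buf",
                          perturb = perturbation(variance_inflation = 4))
  pert_cts <- lapply(cohort_tables(pert), `[[`, "cycles")
  expect_true(buffering_test(pert_cts, wt_cts)$flag)
  # an unperturbed triple is (almost always) not flagged at 0.01
  null3 <- simulate_cohort(tpl, n = 3, seed = 304, target_gene = "null")
  null_cts <- lapply(cohort_tables(null3), `[[`, "cycles")
  expect_false(buffering_test(null_cts, wt_cts)$flag)
})

test_that("marker expression calls lost, reduced and unchanged states", {
  tpl <- default_template()
  wt <- wt_cohort()[1:4]
  ko <- simulate_embryo(tpl, seed = 505, target_gene = "ko",
                        perturb = perturbation(
                          expression_knockout = c("ABalpa", "MSaa")))
  ec <- expression_change(ko, wt, "MSaa")
  expect_lt(ec$ratio, 0.2)
  expect_equal(ec$call, "lost")
  same <- expression_change(wt[[1]], wt, "MSaa")
  expect_equal(same$call, "unchanged")
  expect_equal(same$ratio, 1, tolerance = 0.15)
  half <- wt[[1]]
  half$observations$intensity <- half$observations$intensity / 2
  hc <- expression_change(half, wt, "MSaa")
  expect_equal(hc$call, "reduced")
  expect_equal(hc$ratio, 0.5, tolerance = 0.1)
  noint <- wt[[1]]
  noint$observations$intensity <- NA_real_
  expect_error(expression_change(noint, wt, "MSaa"), "no intensity")
})
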