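ref_from_draws <- function(pair_tables, cycle_tables = NULL) {
  if (is.null(cycle_tables)) {
    cycle_tables <- lapply(seq_along(pair_tables), function(i) {
      data.frame(cell = "ABal", founder = "ABa", generation = 3,
                 cycle_length_min = 30, censored = FALSE)
    })
  }
  build_pair_reference(list(pair_tables = pair_tables,
                            cycle_tables = cycle_tables))
}

test_that("pair reference recovers designated asynchronies from a cohort", {
  tabs <- wt_tables()
  ref <- build_pair_reference(
    list(pair_tables = lapply(tabs, `[[`, "pairs"),
         cycle_tables = lapply(tabs, `[[`, "cycles"))
  )
  truth <- default_async_pairs()
  got <- ref$pairs[match(truth$parent, ref$pairs$parent), ]
  expect_false(anyNA(got$mean_ads_min))
  se <- got$sd_ads_min / sqrt(got$n)
  expect_true(all(abs(got$mean_ads_min - truth$offset_min) <= 3.5 * se +
                    0.75))
  # permutation invariance in cohort order
  ref2 <- build_pair_reference(
    list(pair_tables = rev(lapply(tabs, `[[`, "pairs")),
         cycle_tables = rev(lapply(tabs, `[[`, "cycles")))
  )
  expect_equal(ref$pairs, ref2$pairs)
})

test_that("pairs below min_n are skipped and reported", {
  set.seed(9)
  tables <- lapply(1:10, function(i) {
    tb <- draw_pair_table(rnorm(1, 10, 1), parent = "pairA")
    if (i <= 5) {
      tb <- rbind(tb, draw_pair_table(rnorm(1, 8, 1), parent = "pairB"))
    }
    tb
  })
  ref <- ref_from_draws(tables)
  expect_equal(ref$pairs$parent, "pairA")
  expect_true("pairB" %in% ref$skipped$parent)
  expect_equal(ref$skipped$n[ref$skipped$parent == "pairB"], 5L)
})

test_that("normality flags hold their level on Gaussian ADS draws", {
  set.seed(21)
  n_pairs <- 200
  tables <- lapply(1:30, function(i) {
    data.frame(parent = paste0("pr", seq_len(n_pairs)),
               ads_min = rnorm(n_pairs, 10, 1.5), censored = FALSE)
  })
  ref <- ref_from_draws(tables)
  expect_equal(nrow(ref$pairs), n_pairs)
  expect_gte(mean(ref$pairs$normal_pass), 0.90)
  expect_lte(mean(ref$pairs$normal_pass), 1.00)
})

test_that("asynchronous-pair selection is strictly over the threshold", {
  ref <- wt_reference(data.frame(
    parent = c("a", "b", "c"), n = 20,
    mean_ads_min = c(5.0, 5.1, 4.9), sd_ads_min = 1
  ))
  ref <- select_async_pairs(ref, 5.0)
  expect_equal(ref$monitored, "b")
})

test_that("fate categories attach to known pairs and warn on unknown", {
  ref <- wt_reference(data.frame(
    parent = c("ABplpapp", "MSaa"), n = 20,
    mean_ads_min = c(12, 8), sd_ads_min = 1
  ))
  ann <- data.frame(parent = c("ABplpapp", "NOPE"),
                    category = c("different-fate", "same-fate"))
  expect_warning(ref2 <- assign_pair_categories(ref, ann), "NOPE")
  expect_equal(ref2$pairs$category,
               c("different-fate", "unassigned"))
  expect_equal(nrow(ref2$pairs), nrow(ref$pairs))
})

test_that("tail probabilities match the analytic normal quantiles", {
  expect_equal(tail_probability(10, 2, 10, "lower"), 0.5)
  expect_equal(tail_probability(10, 2, 10 - 1.96 * 2, "two"), 0.05,
               tolerance = 1e-3)
  expect_equal(tail_probability(10, 2, 10 - 2.576 * 2, "two"), 0.01,
               tolerance = 1e-2)
  # monotone decreasing in |x - mean|
  xs <- seq(10, 4, by = -0.5)
  ps <- vapply(xs, function(x) tail_probability(10, 2, x, "two"), 1)
  expect_true(all(diff(ps) < 0))
  expect_warning(p0 <- tail_probability(10, 0, 10), "degenerate")
  expect_equal(p0, 1)
  expect_warning(p1 <- tail_probability(10, 0, 9), "degenerate")
  expect_equal(p1, 0)
})

test_that("the 95 percent interval has nominal coverage under the model", {
  set.seed(33)
  x <- rnorm(1e4, 10, 2)
  cover <- mean(vapply(x, function(v) tail_probability(10, 2, v, "two"),
                       1) > 0.05)
  expect_equal(cover, 0.95, tolerance = 0.02)
})
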