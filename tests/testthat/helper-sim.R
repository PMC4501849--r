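# Shared simulated fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_template <- function() fixture("tpl", make_template())

# a modest wild-type cohort used across tests
wt_cohort <- function(n = 12, seed = 101) {
  fixture(sprintf("coh_%d_%d", n, seed),
          simulate_cohort(default_template(), n = n, seed = seed))
}

cohort_tables <- function(cohort) {
  lapply(cohort, function(rec) {
    tree <- build_lineage(rec)
    cf <- cutoff_frame_350(rec)
    list(tree = tree,
         cycles = cycle_lengths(tree, cutoff_frame = cf),
         pairs = pair_measures(tree, cutoff_frame = cf))
  })
}

wt_tables <- function(n = 12, seed = 101) {
  fixture(sprintf("tabs_%d_%d", n, seed), cohort_tables(wt_cohort(n, seed)))
}

# hand-built recording: explicit observation rows
manual_recording <- function(rows, ...) {
  obs <- do.call(rbind, lapply(rows, function(r) {
    data.frame(cell = r$cell, frame = r$frames,
               x = if (is.null(r$x)) 0 else r$x,
               y = if (is.null(r$y)) 0 else r$y,
               z = if (is.null(r$z)) 0 else r$z,
               stringsAsFactors = FALSE)
  }))
  embryo_recording(obs, id = "manual", ...)
}

# direct-draw pair table for one pair (screen operating characteristics)
draw_pair_table <- function(ads, parent = "pairA") {
  data.frame(parent = parent, ads_min = ads, censored = FALSE,
             stringsAsFactors = FALSE)
}

# direct-draw cycle table from the timing noise model (buffering tests)
draw_cycle_table <- function(n_cells = 30, mean = 30, sd = 2,
                             generation = 7, prefix = "ABx") {
  data.frame(cell = paste0(prefix, seq_len(n_cells), recycle0 = TRUE),
             founder = rep("ABa", n_cells),
             generation = rep(generation, n_cells),
             cycle_length_min = stats::rnorm(n_cells, mean, sd),
             censored = rep(FALSE, n_cells), stringsAsFactors = FALSE)
}

# independent reference for the K-squared test: scipy.stats.normaltest via
# the system python
scipy_normaltest <- function(samples) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".txt")
  writeLines(
    paste0("[", paste(vapply(samples, function(s) {
      paste0("[", paste(sprintf("%.17g", s), collapse = ","), "]")
    }, character(1)), collapse = ","), "]"),
    infile
  )
  script <- paste(
    "import json,sys",
    "import numpy as np",
    "from scipy import stats",
    sprintf("samples = json.load(open(%s))", deparse(infile)),
    sprintf("out = open(%s, 'w')", deparse(outfile)),
    "for s in samples:",
    "    k2, p = stats.normaltest(np.array(s))",
    "    out.write('%.17g %.17g\\n' % (k2, p))",
    "out.close()",
    sep = "\n"
  )
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) {
    stop("python/scipy reference call failed")
  }
  vals <- utils::read.table(outfile)
  names(vals) <- c("statistic", "p_value")
  vals
}

# a hand-built embryo on canonical axes: four-cell frame 1, ABa divides
# at frame 2 into daughters separated along a chosen vector
canonical_recording <- function(v = c(2, 0, 0)) {
  # small symmetric z offsets keep the axes exact while giving the
  # dorso-ventral direction a nonzero extent for the [-1, 1] scaling
  obs <- rbind(
    data.frame(cell = c("ABa", "ABp", "EMS", "P2"), frame = 1L,
               x = c(-10, 0, 0, 10), y = c(0, 5, -5, 0),
               z = c(0.2, -0.2, -0.2, 0.2)),
    data.frame(cell = c("ABp", "EMS", "P2"), frame = 2L,
               x = c(0, 0, 10), y = c(5, -5, 0), z = c(-0.2, -0.2, 0.2)),
    data.frame(cell = c("ABal", "ABar"), frame = 2L,
               x = -10 + c(-v[1], v[1]) / 2, y = c(-v[2], v[2]) / 2,
               z = c(-v[3], v[3]) / 2)
  )
  embryo_recording(obs, id = "canon")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_motion <- function(rec, rotation, translation) {
  xyz <- as.matrix(rec$observations[, c("x", "y", "z")])
  moved <- xyz %*% t(rotation) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  rec$observations$x <- moved[, 1]
  rec$observations$y <- moved[, 2]
  rec$observations$z <- moved[, 3]
  rec
}
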