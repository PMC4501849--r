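## Cycle-length extraction with censoring, the ADS statistic, and cohort
## reproducibility summaries.

#' Per-cell cycle lengths with censoring
#'
#' A divided cell's cycle length is (daughters' birth frame - own birth
#' frame) x frame interval. Cells are censored (with a reason) when their
#' timing cannot be quantified: the first two rounds of division (AB, P1,
#' ABa, ABp, EMS, P2 -- imaging starts at the two- to four-cell stage),
#' cells not observed from their birth (roots other than the early set),
#' cells scored as dead, and cells that had not divided by the cutoff.
#'
#' @param tree A `lineage_tree`.
#' @param frame_interval_min Minutes per frame; defaults to the tree's.
#' @param cutoff_frame Analysis cutoff; defaults to the tree's last curated
#'   frame (see [cutoff_frame_350()] for the 350-cell rule).
#' @return Data frame: `cell`, `founder`, `generation`, `cycle_length_min`,
#'   `censored`, `censor_reason`.
#' @export
cycle_lengths <- function(tree, frame_interval_min = NULL,
                          cutoff_frame = NULL) {
  if (is.null(frame_interval_min)) {
    frame_interval_min <- attr(tree, "frame_interval_min")
  }
  if (is.null(cutoff_frame)) {
    cutoff_frame <- attr(tree, "last_curated_frame")
  }
  if (cutoff_frame > attr(tree, "last_curated_frame")) {
    stop("cutoff_frame beyond last curated frame")
  }
  idx <- stats::setNames(seq_len(nrow(tree)), tree$name)
  roots <- attr(tree, "roots")

  n <- nrow(tree)
  len <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  divided <- !is.na(tree$daughter1)
  div_frame <- rep(NA_integer_, n)
  div_frame[divided] <- tree$birth_frame[idx[tree$daughter1[divided]]]

  early <- tree$name %in% c(.EARLY_EXCLUDED, "P0")
  unobserved_birth <- tree$name %in% roots & !early
  dead <- tree$died
  undivided <- !divided | (divided & div_frame > cutoff_frame)

  reason[undivided] <- "undivided-at-cutoff"
  reason[dead] <- "dead"
  reason[unobserved_birth] <- "not-observed-from-birth"
  reason[early] <- "early-round-excluded"

  ok <- is.na(reason)
  len[ok] <- (div_frame[ok] - tree$birth_frame[ok]) * frame_interval_min

  out <- data.frame(
    cell = tree$name, founder = tree$founder, generation = tree$generation,
    cycle_length_min = len, censored = !ok, censor_reason = reason,
    stringsAsFactors = FALSE
  )
  attr(out, "id") <- attr(tree, "id")
  attr(out, "cutoff_frame") <- cutoff_frame
  out
}

#' Analysis cutoff at the 350-cell stage
#'
#' The frame at which the embryo first reaches `n_cells` concurrent cells,
#' or the last curated frame if never reached.
#'
#' @param rec An `embryo_recording`.
#' @param n_cells Cell-count threshold (default 350).
#' @return Integer frame.
#' @export
cutoff_frame_350 <- function(rec, n_cells = 350L) {
  sc <- speed_curve(rec)
  hit <- sc$frame[sc$count >= n_cells]
  if (length(hit)) min(hit) else rec$last_curated_frame
}

#' ADS of one sister pair
#'
#' Asynchrony of division between sister cells: the absolute difference of
#' the two daughters' cycle lengths (equivalently of their division times,
#' since sisters are born together). The signed variant orders daughters
#' lexicographically (anterior/left/dorsal letters sort first).
#'
#' @param tree A `lineage_tree`.
#' @param parent Name of a divided cell.
#' @param frame_interval_min Minutes per frame; defaults to the tree's.
#' @param cycles Optional precomputed [cycle_lengths()] table.
#' @return One-row data frame: `parent`, `daughter1`, `daughter2`,
#'   `ads_min`, `signed_ads_min`, `censored`.
#' @export
compute_ads <- function(tree, parent, frame_interval_min = NULL,
                        cycles = NULL) {
  i <- match(parent, tree$name)
  if (is.na(i)) {
    stop("cell '", parent, "' not in tree")
  }
  if (is.na(tree$daughter1[i])) {
    stop("cell '", parent, "' has not divided")
  }
  if (is.null(cycles)) {
    cycles <- cycle_lengths(tree, frame_interval_min)
  }
  d <- sort(c(tree$daughter1[i], tree$daughter2[i]))
  ci <- match(d, cycles$cell)
  cens <- any(cycles$censored[ci])
  signed <- if (cens) NA_real_ else
    cycles$cycle_length_min[ci[1]] - cycles$cycle_length_min[ci[2]]
  data.frame(
    parent = parent, daughter1 = d[1], daughter2 = d[2],
    ads_min = abs(signed), signed_ads_min = signed, censored = cens,
    stringsAsFactors = FALSE
  )
}

#' ADS of every divided pair in a tree
#'
#' @param tree A `lineage_tree`.
#' @param frame_interval_min Minutes per frame; defaults to the tree's.
#' @param cutoff_frame Cutoff passed to [cycle_lengths()].
#' @return Data frame with one row per parent with two daughters, columns
#'   as in [compute_ads()].
#' @export
pair_measures <- function(tree, frame_interval_min = NULL,
                          cutoff_frame = NULL) {
  cycles <- cycle_lengths(tree, frame_interval_min, cutoff_frame)
  divided <- !is.na(tree$daughter1)
  if (!any(divided)) {
    return(data.frame(parent = character(), daughter1 = character(),
                      daughter2 = character(), ads_min = numeric(),
                      signed_ads_min = numeric(), censored = logical()))
  }
  d1 <- pmin(tree$daughter1[divided], tree$daughter2[divided])
  d2 <- pmax(tree$daughter1[divided], tree$daughter2[divided])
  i1 <- match(d1, cycles$cell)
  i2 <- match(d2, cycles$cell)
  cens <- cycles$censored[i1] | cycles$censored[i2]
  signed <- ifelse(cens, NA_real_,
                   cycles$cycle_length_min[i1] - cycles$cycle_length_min[i2])
  out <- data.frame(
    parent = tree$name[divided], daughter1 = d1, daughter2 = d2,
    ads_min = abs(signed), signed_ads_min = signed, censored = cens,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "id") <- attr(tree, "id")
  out
}

#' Pairwise Pearson correlation of cycle lengths across embryos
#'
#' Entry (i, j) is the Pearson r over the cells uncensored in both embryos;
#' entries with fewer than `min_shared` shared cells are `NA`.
#'
#' @param cohort List of [cycle_lengths()] tables.
#' @param min_shared Minimum shared uncensored cells (default 3).
#' @return Square symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(cohort, min_shared = 3L) {
  if (length(cohort) < 2L) {
    stop("need at least 2 embryos")
  }
  cells <- sort(unique(unlist(lapply(cohort, function(tb) {
    tb$cell[!tb$censored]
  }))))
  mat <- vapply(cohort, function(tb) {
    v <- rep(NA_real_, length(cells))
    ok <- !tb$censored
    v[match(tb$cell[ok], cells)] <- tb$cycle_length_min[ok]
    v
  }, numeric(length(cells)))
  n <- ncol(mat)
  r <- matrix(NA_real_, n, n)
  ids <- vapply(seq_along(cohort), function(i) {
    id <- attr(cohort[[i]], "id")
    if (is.null(id)) paste0("embryo_", i) else id
  }, character(1))
  dimnames(r) <- list(ids, ids)
  for (i in seq_len(n)) {
    r[i, i] <- 1
    for (j in seq_len(n)[-seq_len(i)]) {
      shared <- stats::complete.cases(mat[, c(i, j)])
      if (sum(shared) >= min_shared) {
        r[i, j] <- r[j, i] <- stats::cor(mat[shared, i], mat[shared, j])
      }
    }
  }
  r
}

#' Cluster embryos by their correlation profiles
#'
#' Agglomerative complete-linkage clustering on Manhattan (L1) distances
#' between the rows of the correlation matrix, as used for cohort
#' reproducibility heat maps. Missing entries are imputed by the row mean
#' of observed off-diagonal values (count reported).
#'
#' @param mat Square matrix from [correlation_matrix()].
#' @return List: `hclust` (the tree), `order` (leaf order),
#'   `n_imputed` (imputed entries).
#' @export
cluster_embryos <- function(mat) {
  if (nrow(mat) < 2L) {
    stop("need at least 2 embryos to cluster")
  }
  n_imputed <- sum(is.na(mat))
  if (n_imputed) {
    for (i in seq_len(nrow(mat))) {
      miss <- is.na(mat[i, ])
      mat[i, miss] <- mean(mat[i, !miss][-i], na.rm = TRUE)
    }
    mat <- (mat + t(mat)) / 2
  }
  hc <- stats::hclust(stats::dist(mat, method = "manhattan"),
                      method = "complete")
  list(hclust = hc, order = hc$order, n_imputed = n_imputed)
}

#' Generation-wise standard-deviation profile of cycle lengths
#'
#' For every cell uncensored in at least `min_n` embryos, the SD of its
#' cycle length across embryos; summarised per generation as the mean of
#' the per-cell SDs.
#'
#' @param cohort List of [cycle_lengths()] tables (>= 3 embryos).
#' @param min_n Minimum embryos per cell (default 3).
#' @return Data frame: `generation`, `mean_sd_min`, `n_cells`.
#' @export
generation_sd_profile <- function(cohort, min_n = 3L) {
  if (length(cohort) < 3L) {
    stop("need at least 3 embryos")
  }
  pooled <- do.call(rbind, lapply(cohort, function(tb) {
    tb[!tb$censored, c("cell", "generation", "cycle_length_min")]
  }))
  counts <- table(pooled$cell)
  keep <- names(counts)[counts >= min_n]
  pooled <- pooled[pooled$cell %in% keep, ]
  per_cell <- stats::aggregate(
    cycle_length_min ~ cell + generation, data = pooled, FUN = stats::sd
  )
  out <- stats::aggregate(
    cycle_length_min ~ generation, data = per_cell, FUN = mean
  )
  names(out)[2] <- "mean_sd_min"
  out$n_cells <- stats::aggregate(
    cell ~ generation, data = per_cell, FUN = length
  )$cell
  out[order(out$generation), ]
}
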