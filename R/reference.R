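## Multi-embryo wild-type reference: per-pair ADS distributions with
## normality flags, per-cell timing statistics, asynchronous-pair selection
## and normal-model tail probabilities.

#' Construct a wild-type reference from component tables
#'
#' Low-level constructor; most users call [build_pair_reference()].
#'
#' @param pairs Data frame with at least `parent`, `n`, `mean_ads_min`,
#'   `sd_ads_min`; optional `k2_stat`, `k2_p`, `normal_pass`, `category`.
#' @param cells Optional per-cell cycle statistics data frame.
#' @param monitored Character vector of monitored pair parents.
#' @param skipped Data frame of pairs excluded for insufficient n.
#' @param provenance List of cohort metadata.
#' @return A `wt_reference` object.
#' @export
wt_reference <- function(pairs, cells = NULL, monitored = character(),
                         skipped = NULL, provenance = list()) {
  stopifnot(all(c("parent", "n", "mean_ads_min", "sd_ads_min") %in%
                  names(pairs)))
  for (col in c("k2_stat", "k2_p")) {
    if (!col %in% names(pairs)) pairs[[col]] <- NA_real_
  }
  if (!"normal_pass" %in% names(pairs)) pairs$normal_pass <- NA
  if (!"category" %in% names(pairs)) pairs$category <- "unassigned"
  structure(
    list(pairs = pairs, cells = cells, monitored = monitored,
         skipped = skipped, provenance = provenance),
    class = "wt_reference"
  )
}

#' @export
print.wt_reference <- function(x, ...) {
  cat(sprintf(
    "<wt_reference> %d pairs (%d monitored), %d cohort embryos\n",
    nrow(x$pairs), length(x$monitored),
    if (is.null(x$provenance$n_embryos)) NA_integer_ else x$provenance$n_embryos
  ))
  invisible(x)
}

#' Build the wild-type pair reference from a cohort
#'
#' For every parent with at least `min_n` uncensored ADS values across the
#' cohort: mean, SD and the D'Agostino K-squared normality test of its ADS
#' distribution. Pairs failing normality are retained but flagged -- the
#' screen proceeds with the normal model regardless, and reports can caveat
#' non-normal pairs. Per-cell cycle-length statistics are computed
#' alongside.
#'
#' @param cohort List of `embryo_recording` objects (wild type), or a list
#'   with elements `pair_tables` and `cycle_tables` (precomputed
#'   per-embryo [pair_measures()] / [cycle_lengths()] outputs).
#' @param alpha Normality significance level (default 0.05).
#' @param min_n Minimum uncensored embryos per pair (default 8, the K2
#'   validity floor).
#' @param cutoff Function mapping a recording to its analysis cutoff frame
#'   (default [cutoff_frame_350()]).
#' @return A `wt_reference`.
#' @export
build_pair_reference <- function(cohort, alpha = 0.05, min_n = 8L,
                                 cutoff = cutoff_frame_350) {
  if (is.list(cohort) && !is.null(cohort$pair_tables)) {
    pair_tables <- cohort$pair_tables
    cycle_tables <- cohort$cycle_tables
  } else {
    trees <- lapply(cohort, build_lineage)
    cuts <- vapply(cohort, cutoff, numeric(1))
    cycle_tables <- Map(function(tr, cf) cycle_lengths(tr, cutoff_frame = cf),
                        trees, cuts)
    pair_tables <- Map(function(tr, cf) pair_measures(tr, cutoff_frame = cf),
                       trees, cuts)
  }
  if (length(pair_tables) < min_n) {
    stop("cohort of ", length(pair_tables),
         " embryos is below min_n = ", min_n)
  }

  pooled <- do.call(rbind, lapply(seq_along(pair_tables), function(i) {
    tb <- pair_tables[[i]]
    ok <- !tb$censored
    data.frame(parent = tb$parent[ok], ads = tb$ads_min[ok],
               stringsAsFactors = FALSE)
  }))
  counts <- table(pooled$parent)
  keep <- sort(names(counts)[counts >= min_n])
  low <- sort(names(counts)[counts < min_n])
  skipped <- data.frame(
    parent = low,
    n = as.integer(counts[low]),
    reason = rep("insufficient-uncensored-embryos", length(low)),
    stringsAsFactors = FALSE
  )

  by_parent <- split(pooled$ads, pooled$parent)
  pairs <- do.call(rbind, lapply(keep, function(p) {
    v <- by_parent[[p]]
    k2 <- tryCatch(dagostino_k2(v), error = function(e) NULL)
    data.frame(
      parent = p, n = length(v),
      mean_ads_min = mean(v), sd_ads_min = stats::sd(v),
      k2_stat = if (is.null(k2)) NA_real_ else k2$statistic,
      k2_p = if (is.null(k2)) NA_real_ else k2$p_value,
      normal_pass = if (is.null(k2)) NA else k2$p_value > alpha,
      category = "unassigned",
      stringsAsFactors = FALSE
    )
  }))

  cell_pool <- do.call(rbind, lapply(cycle_tables, function(tb) {
    tb[!tb$censored, c("cell", "founder", "generation", "cycle_length_min")]
  }))
  cells <- do.call(rbind, lapply(split(cell_pool, cell_pool$cell), function(d) {
    data.frame(cell = d$cell[1], founder = d$founder[1],
               generation = d$generation[1], n = nrow(d),
               mean_cycle_min = mean(d$cycle_length_min),
               sd_cycle_min = stats::sd(d$cycle_length_min),
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL

  wt_reference(
    pairs = pairs, cells = cells, skipped = skipped,
    provenance = list(n_embryos = length(pair_tables), alpha = alpha,
                      min_n = min_n)
  )
}

#' Select asynchronous pairs for monitoring
#'
#' Pairs whose wild-type mean ADS is strictly greater than the threshold
#' ("over 5 min": a mean of exactly 5.0 is excluded).
#'
#' @param ref A `wt_reference`.
#' @param threshold_min Threshold in minutes (default 5).
#' @return The `wt_reference` with its `monitored` field set.
#' @export
select_async_pairs <- function(ref, threshold_min = 5.0) {
  stopifnot(inherits(ref, "wt_reference"))
  ref$monitored <- ref$pairs$parent[ref$pairs$mean_ads_min > threshold_min]
  ref$provenance$async_threshold_min <- threshold_min
  ref
}

#' Attach fate categories to monitored pairs
#'
#' @param ref A `wt_reference`.
#' @param annotation Data frame with columns `parent` and `category`
#'   (values among `different-fate`, `same-fate`, `blast-vs-terminal`).
#' @return The `wt_reference` with categories attached; unannotated pairs
#'   stay `unassigned`. Annotations naming unknown parents raise a warning.
#' @export
assign_pair_categories <- function(ref, annotation) {
  stopifnot(inherits(ref, "wt_reference"),
            all(c("parent", "category") %in% names(annotation)))
  unknown <- setdiff(annotation$parent, ref$pairs$parent)
  if (length(unknown)) {
    warning("annotation names pair(s) absent from the reference: ",
            paste(unknown, collapse = ", "))
  }
  i <- match(ref$pairs$parent, annotation$parent)
  hit <- !is.na(i)
  ref$pairs$category[hit] <- annotation$category[i[hit]]
  ref
}

#' Normal-model tail probability
#'
#' @param mean,sd Normal parameters (`sd > 0`; `sd == 0` degenerates to
#'   p = 1 at the mean and 0 elsewhere, with a warning).
#' @param x Observed value.
#' @param side One of `"lower"`, `"upper"`, `"two"` (two-sided =
#'   2 x min(lower, upper)).
#' @return Tail probability.
#' @export
tail_probability <- function(mean, sd, x, side = c("two", "lower", "upper")) {
  side <- match.arg(side)
  if (sd < 0) {
    stop("sd must be non-negative")
  }
  if (sd == 0) {
    warning("degenerate reference distribution (sd = 0)")
    return(if (x == mean) 1 else 0)
  }
  lower <- stats::pnorm(x, mean, sd)
  upper <- stats::pnorm(x, mean, sd, lower.tail = FALSE)
  switch(side,
    lower = lower,
    upper = upper,
    two = min(1, 2 * min(lower, upper))
  )
}
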