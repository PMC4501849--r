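## RNAi-screen statistics: embryo QC, ADS-reduction hit calling with the
## two-replicate rule, variance-buffering detection, and tissue-marker
## expression comparison.

#' Quality control of a perturbed embryo recording
#'
#' Fails if the embryo has fewer than 300 cells at its last editable
#' (curated) frame, and -- when the recording extends to frame 240 -- if it
#' failed to reach 350 cells by frame 240. Earlier-terminated curations are
#' judged by the 300-cell clause alone.
#'
#' @param rec An `embryo_recording`.
#' @param min_cells_last Cell-count floor at the last frame (default 300).
#' @param min_cells_240 Cell count required by `qc_frame` (default 350).
#' @param qc_frame Frame for the second clause (default 240).
#' @return List: `id`, `pass`, `reasons` (character vector).
#' @export
qc_embryo <- function(rec, min_cells_last = 300L, min_cells_240 = 350L,
                      qc_frame = 240L) {
  if (nrow(rec$observations) == 0L) {
    stop("empty recording")
  }
  reasons <- character()
  last <- rec$last_curated_frame
  if (cell_count_at(rec, last) < min_cells_last) {
    reasons <- c(reasons, "under-300-at-last-editable")
  }
  if (last >= qc_frame) {
    sc <- speed_curve(rec)
    max_by_240 <- max(sc$count[sc$frame <= qc_frame])
    if (max_by_240 < min_cells_240) {
      reasons <- c(reasons, "under-350-at-frame-240")
    }
  }
  list(id = rec$id, pass = length(reasons) == 0L, reasons = reasons)
}

#' Call ADS-reduction hits for one gene
#'
#' Per replicate and monitored pair, a flag at level alpha requires: an
#' uncensored ADS; ADS at most (1 - reduction) x wild-type mean (the >= 50
#' percent reduction criterion); ADS below the wild-type mean (explicit
#' direction); and a normal-model tail probability below alpha. A pair is
#' a hit at 0.01 if at least `min_replicates` replicates carry the 0.01
#' flag, else at 0.05 by the same rule, else not a hit.
#'
#' @param replicates List of per-replicate pair tables ([pair_measures()]
#'   output, or any data frame with `parent`, `ads_min`, `censored`).
#' @param ref A `wt_reference` with monitored pairs selected.
#' @param gene Gene name (metadata).
#' @param pairs Pairs to score; defaults to `ref$monitored`.
#' @param reduction Required fractional reduction (default 0.5).
#' @param alphas Significance levels (default 0.05 and 0.01).
#' @param min_replicates Replicates that must agree (default 2).
#' @param one_sided Use the lower tail only instead of the two-sided tail.
#' @return A `gene_screen_result`: list with `gene`, `status`
#'   (`"screened"` or `"unscreenable"`), `n_replicates`, `replicate_flags`
#'   (long data frame) and `hits` (per-pair data frame with `hit_level`
#'   among `"none"`, `"0.05"`, `"0.01"`).
#' @export
call_hits <- function(replicates, ref, gene = NA_character_, pairs = NULL,
                      reduction = 0.5, alphas = c(0.05, 0.01),
                      min_replicates = 2L, one_sided = FALSE) {
  stopifnot(inherits(ref, "wt_reference"))
  if (is.null(pairs)) {
    pairs <- ref$monitored
  }
  if (!length(pairs)) {
    stop("no monitored pairs; run select_async_pairs() first")
  }
  if (!length(replicates)) {
    return(structure(list(gene = gene, status = "unscreenable",
                          n_replicates = 0L, replicate_flags = NULL,
                          hits = NULL),
                     class = "gene_screen_result"))
  }
  alphas <- sort(alphas, decreasing = TRUE)
  pref <- ref$pairs[match(pairs, ref$pairs$parent), ]
  side <- if (one_sided) "lower" else "two"

  flags <- do.call(rbind, lapply(seq_along(replicates), function(r) {
    tb <- replicates[[r]]
    i <- match(pairs, tb$parent)
    ads <- tb$ads_min[i]
    cens <- is.na(i) | tb$censored[i] | is.na(ads)
    p <- rep(NA_real_, length(pairs))
    ok <- !cens
    if (any(ok)) {
      p[ok] <- mapply(function(m, s, x) tail_probability(m, s, x, side),
                      pref$mean_ads_min[ok], pref$sd_ads_min[ok], ads[ok])
    }
    reduced <- ok & !is.na(ads) & ads <= (1 - reduction) * pref$mean_ads_min &
      ads < pref$mean_ads_min
    out <- data.frame(
      replicate = r, parent = pairs, ads_min = ads, censored = cens,
      reduction_frac = 1 - ads / pref$mean_ads_min, p = p,
      stringsAsFactors = FALSE
    )
    flag_cols <- paste0("flag", sub("^0[.]", "", format(alphas)))
    for (k in seq_along(alphas)) {
      out[[flag_cols[k]]] <- reduced & !is.na(p) & p < alphas[k]
    }
    out
  }))

  flag_cols <- paste0("flag", sub("^0[.]", "", format(alphas)))
  hits <- do.call(rbind, lapply(pairs, function(q) {
    fq <- flags[flags$parent == q, ]
    counts <- vapply(flag_cols, function(cl) sum(fq[[cl]]), integer(1))
    level <- "none"
    # strictest level first (alphas are sorted decreasing, so reverse)
    for (k in rev(seq_along(alphas))) {
      if (counts[k] >= min_replicates) {
        level <- format(alphas[k])
        break
      }
    }
    row <- data.frame(parent = q, hit_level = level, stringsAsFactors = FALSE)
    for (k in seq_along(alphas)) {
      row[[paste0("n_", flag_cols[k])]] <- counts[k]
    }
    row
  }))

  structure(list(gene = gene, status = "screened",
                 n_replicates = length(replicates),
                 replicate_flags = flags, hits = hits),
            class = "gene_screen_result")
}

#' @export
print.gene_screen_result <- function(x, ...) {
  nh <- if (is.null(x$hits)) 0L else sum(x$hits$hit_level != "none")
  cat(sprintf("<gene_screen_result %s> %s, %d replicate(s), %d hit pair(s)\n",
              x$gene, x$status, x$n_replicates, nh))
  invisible(x)
}

#' Variance-buffering (capacitor) detection
#'
#' Per generation of the chosen lineage, computes deviations of each
#' embryo's cycle lengths from the wild-type per-cell mean, and applies a
#' one-sided two-sample F-test of Var(perturbed deviations) >
#' Var(wild-type deviations). The gene is flagged when the minimum
#' per-generation p falls below alpha. Signed deviations are used by
#' default; `absolute = TRUE` tests absolute deviations instead.
#'
#' @param perturbed List of [cycle_lengths()] tables (QC-passing
#'   replicates of one gene).
#' @param wildtype List of [cycle_lengths()] tables (>= 2 embryos).
#' @param lineage Sublineage name prefix (default `"AB"`).
#' @param alpha Flagging level (default 0.01).
#' @param min_side Minimum deviations per side per generation (default 3;
#'   smaller generations are skipped and recorded).
#' @param absolute Test absolute instead of signed deviations.
#' @param loo_wt Compute each wild-type embryo's deviations against the
#'   leave-one-out mean of the remaining embryos (default `TRUE`). With
#'   the plain pooled mean a wild-type embryo's own value deflates the
#'   wild-type dispersion and inflates the false-flag rate well above
#'   alpha for modest cohort sizes; leave-one-out restores the F-test's
#'   nominal level. `FALSE` uses the pooled mean on both sides.
#' @param speed_normalize Rescale each embryo's cycle lengths by its
#'   median ratio to the wild-type per-cell means before computing
#'   deviations (default `TRUE`). Embryo-to-embryo global pace variation
#'   otherwise enters the deviations as a component shared by all cells
#'   of an embryo; with few replicates that component has almost no
#'   degrees of freedom and the F-test mistakes ordinary pace spread for
#'   a dispersion phenotype.
#' @return List: `table` (generation, n per side, F, p, skipped),
#'   `flag`, `min_p`.
#' @export
buffering_test <- function(perturbed, wildtype, lineage = "AB",
                           alpha = 0.01, min_side = 3L, absolute = FALSE,
                           loo_wt = TRUE, speed_normalize = TRUE) {
  if (!length(perturbed)) {
    stop("need at least one perturbed cycle table")
  }
  if (length(wildtype) < 2L) {
    stop("need at least two wild-type embryos")
  }
  pick <- function(tb) {
    tb[!tb$censored & startsWith(tb$cell, lineage),
       c("cell", "generation", "cycle_length_min")]
  }
  wt_tabs <- lapply(wildtype, pick)
  pert_tabs <- lapply(perturbed, pick)
  if (!sum(vapply(wt_tabs, nrow, 1L)) ||
      !sum(vapply(pert_tabs, nrow, 1L))) {
    stop("no uncensored cells in lineage '", lineage, "'")
  }
  if (speed_normalize) {
    ref_mean <- tapply(
      do.call(rbind, wt_tabs)$cycle_length_min,
      do.call(rbind, wt_tabs)$cell, mean
    )
    rescale <- function(tb) {
      m <- ref_mean[tb$cell]
      r <- stats::median(tb$cycle_length_min[!is.na(m)] / m[!is.na(m)])
      if (is.finite(r) && r > 0) tb$cycle_length_min <- tb$cycle_length_min / r
      tb
    }
    wt_tabs <- lapply(wt_tabs, rescale)
    pert_tabs <- lapply(pert_tabs, rescale)
  }
  wt <- do.call(rbind, wt_tabs)
  pert <- do.call(rbind, pert_tabs)
  wt_sum <- tapply(wt$cycle_length_min, wt$cell, sum)
  wt_n <- tapply(wt$cycle_length_min, wt$cell, length)
  wt_mean <- wt_sum / wt_n
  dev_of <- function(d) {
    m <- wt_mean[d$cell]
    keep <- !is.na(m)
    data.frame(generation = d$generation[keep],
               dev = d$cycle_length_min[keep] - m[keep])
  }
  pert_dev <- dev_of(pert)
  if (loo_wt) {
    wt_dev <- do.call(rbind, lapply(wt_tabs, function(d) {
      s <- wt_sum[d$cell]
      k <- wt_n[d$cell]
      keep <- !is.na(s) & k >= 2
      m <- (s[keep] - d$cycle_length_min[keep]) / (k[keep] - 1)
      data.frame(generation = d$generation[keep],
                 dev = d$cycle_length_min[keep] - m)
    }))
  } else {
    wt_dev <- dev_of(wt)
  }
  if (absolute) {
    wt_dev$dev <- abs(wt_dev$dev)
    pert_dev$dev <- abs(pert_dev$dev)
  }
  gens <- sort(intersect(unique(wt_dev$generation),
                         unique(pert_dev$generation)))
  rows <- lapply(gens, function(g) {
    xp <- pert_dev$dev[pert_dev$generation == g]
    xw <- wt_dev$dev[wt_dev$generation == g]
    if (length(xp) < min_side || length(xw) < min_side) {
      return(data.frame(generation = g, n_perturbed = length(xp),
                        n_wildtype = length(xw), f_stat = NA_real_,
                        p = NA_real_, skipped = TRUE))
    }
    ft <- stats::var.test(xp, xw, alternative = "greater")
    data.frame(generation = g, n_perturbed = length(xp),
               n_wildtype = length(xw),
               f_stat = unname(ft$statistic), p = ft$p.value,
               skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  min_p <- suppressWarnings(min(tab$p, na.rm = TRUE))
  if (!is.finite(min_p)) min_p <- NA_real_
  list(table = tab, flag = isTRUE(min_p < alpha), min_p = min_p)
}

#' Tissue-marker expression change in a sublineage
#'
#' Ratio of the perturbed embryo's mean per-nucleus intensity over all
#' observations of cells in the sublineage to the same quantity averaged
#' over the wild-type cohort, with a qualitative call.
#'
#' @param perturbed An `embryo_recording` carrying intensities.
#' @param wildtype List of wild-type `embryo_recording`s with intensities.
#' @param root Sublineage root cell name.
#' @param loss_ratio Ratio below which expression is called `lost`
#'   (default 0.2); `reduced` below 0.67, `unchanged` up to 1.5, `gained`
#'   above.
#' @return List: `ratio`, `call`, `caveat` (`TRUE` when the sublineage is
#'   truncated in the perturbed embryo, e.g. by arrest).
#' @export
expression_change <- function(perturbed, wildtype, root, loss_ratio = 0.2) {
  sub_mean <- function(rec, required = TRUE) {
    obs <- rec$observations
    if (all(is.na(obs$intensity))) {
      stop("recording '", rec$id, "' carries no intensity values")
    }
    cells <- unique(obs$cell)
    in_sub <- cells[vapply(cells, function(nm) is_ancestor(root, nm),
                           logical(1))]
    if (!length(in_sub)) {
      if (required) {
        stop("sublineage root '", root, "' absent from '", rec$id, "'")
      }
      return(NULL)
    }
    sel <- obs$cell %in% in_sub
    list(mean = mean(obs$intensity[sel], na.rm = TRUE),
         n_cells = length(in_sub))
  }
  wt_stats <- lapply(wildtype, sub_mean)
  wt_level <- mean(vapply(wt_stats, `[[`, numeric(1), "mean"))
  wt_depth <- stats::median(vapply(wt_stats, `[[`, numeric(1), "n_cells"))
  p <- sub_mean(perturbed, required = FALSE)
  if (is.null(p)) {
    # arrest before the sublineage appears: fall back to the root's mother
    # chain is not meaningful; report total loss with a caveat
    return(list(ratio = NA_real_, call = "lost", caveat = TRUE))
  }
  ratio <- p$mean / wt_level
  call <- if (ratio < loss_ratio) "lost"
  else if (ratio < 0.67) "reduced"
  else if (ratio <= 1.5) "unchanged"
  else "gained"
  list(ratio = ratio, call = call, caveat = p$n_cells < 0.5 * wt_depth)
}
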