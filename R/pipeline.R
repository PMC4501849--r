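## Orchestration and report emission: read -> QC -> wild-type reference ->
## screen -> buffering -> spatial -> tab-delimited reports.

#' Pipeline configuration
#'
#' Bundles the screening thresholds and paths. Defaults mirror the
#' screening design: 5-min asynchrony threshold, 50 percent reduction,
#' significance at 0.05/0.01 in at least two replicates, buffering at
#' 0.01, QC at 300 cells (last frame) / 350 cells (frame 240), 1.5-min
#' frames.
#'
#' @param manifest Path to a cohort manifest (see [read_manifest()]), or
#'   `NULL` when recordings are passed in memory.
#' @param out_dir Output directory for reports.
#' @param async_threshold_min,reduction,alphas,min_replicates Screening
#'   thresholds.
#' @param buffering_alpha,buffering_lineage Buffering detector settings.
#' @param qc_cells_last,qc_cells_240,qc_frame QC rule.
#' @param frame_interval_min Minutes per frame.
#' @param annotation Optional pair-category annotation data frame.
#' @param spatial_cells Cells to score for positional deviation.
#' @param seed Master seed recorded in the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = NULL,
                            async_threshold_min = 5.0, reduction = 0.5,
                            alphas = c(0.05, 0.01), min_replicates = 2L,
                            buffering_alpha = 0.01, buffering_lineage = "AB",
                            qc_cells_last = 300L, qc_cells_240 = 350L,
                            qc_frame = 240L, frame_interval_min = 1.5,
                            annotation = NULL, spatial_cells = character(),
                            seed = 1L) {
  stopifnot(reduction > 0, reduction < 1, all(alphas > 0 & alphas < 1),
            frame_interval_min > 0)
  structure(
    list(manifest = manifest, out_dir = out_dir,
         async_threshold_min = async_threshold_min, reduction = reduction,
         alphas = alphas, min_replicates = min_replicates,
         buffering_alpha = buffering_alpha,
         buffering_lineage = buffering_lineage,
         qc_cells_last = qc_cells_last, qc_cells_240 = qc_cells_240,
         qc_frame = qc_frame, frame_interval_min = frame_interval_min,
         annotation = annotation, spatial_cells = spatial_cells,
         seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full screening pipeline
#'
#' Executes read (or takes in-memory recordings), QC, wild-type reference
#' construction, asynchronous-pair selection, per-gene hit calling,
#' buffering detection, and optional positional statistics. Deterministic
#' given inputs and seed.
#'
#' @param config A `pipeline_config`.
#' @param recordings Optional named input: a list with elements `wildtype`
#'   (list of recordings) and `perturbed` (named list of per-gene
#'   recording lists). When `NULL`, recordings are read from
#'   `config$manifest` (genes taken from `target_gene`).
#' @return A `pipeline_result` list: `reference`, `qc`, `screen`
#'   (per-gene results), `buffering`, `spatial`, `exclusions`, `config`.
#' @export
run_pipeline <- function(config, recordings = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(recordings)) {
    if (is.null(config$manifest)) {
      stop("no recordings given and no manifest configured")
    }
    man <- read_manifest(config$manifest)
    recs <- lapply(seq_len(nrow(man)), function(i) {
      read_nuclei_table(man$path[i], id = man$recording_id[i],
                        target_gene = man$target_gene[i],
                        replicate = man$replicate[i], marker = man$marker[i],
                        frame_interval_min = config$frame_interval_min)
    })
    genes <- unique(man$target_gene[man$target_gene != "wild-type"])
    recordings <- list(
      wildtype = recs[man$target_gene == "wild-type"],
      perturbed = stats::setNames(
        lapply(genes, function(g) recs[man$target_gene == g]), genes
      )
    )
  }
  wt <- recordings$wildtype
  perturbed <- recordings$perturbed

  # QC every recording; track exclusions
  qc_one <- function(rec) {
    qc_embryo(rec, config$qc_cells_last, config$qc_cells_240,
              config$qc_frame)
  }
  wt_qc <- lapply(wt, qc_one)
  wt_pass <- vapply(wt_qc, `[[`, logical(1), "pass")
  exclusions <- data.frame(id = character(), gene = character(),
                           reason = character(), stringsAsFactors = FALSE)
  add_excl <- function(ex, ids, gene, reasons) {
    rbind(ex, data.frame(id = ids, gene = gene, reason = reasons,
                         stringsAsFactors = FALSE))
  }
  if (any(!wt_pass)) {
    bad <- which(!wt_pass)
    exclusions <- add_excl(
      exclusions, vapply(wt[bad], `[[`, character(1), "id"), "wild-type",
      vapply(wt_qc[bad], function(q) paste(q$reasons, collapse = ";"),
             character(1))
    )
  }
  wt <- wt[wt_pass]

  # wild-type reference
  wt_trees <- lapply(wt, build_lineage)
  wt_cuts <- vapply(wt, cutoff_frame_350, numeric(1))
  wt_cycles <- Map(function(tr, cf) cycle_lengths(tr, cutoff_frame = cf),
                   wt_trees, wt_cuts)
  wt_pairs <- Map(function(tr, cf) pair_measures(tr, cutoff_frame = cf),
                  wt_trees, wt_cuts)
  ref <- build_pair_reference(list(pair_tables = wt_pairs,
                                   cycle_tables = wt_cycles))
  ref <- select_async_pairs(ref, config$async_threshold_min)
  if (!is.null(config$annotation)) {
    ref <- assign_pair_categories(ref, config$annotation)
  }

  # per-gene screening
  screen <- list()
  buffering <- list()
  for (gene in names(perturbed)) {
    reps <- perturbed[[gene]]
    rep_qc <- lapply(reps, qc_one)
    rep_pass <- vapply(rep_qc, `[[`, logical(1), "pass")
    if (any(!rep_pass)) {
      bad <- which(!rep_pass)
      exclusions <- add_excl(
        exclusions, vapply(reps[bad], `[[`, character(1), "id"), gene,
        vapply(rep_qc[bad], function(q) paste(q$reasons, collapse = ";"),
               character(1))
      )
    }
    reps <- reps[rep_pass]
    if (!length(reps)) {
      screen[[gene]] <- structure(
        list(gene = gene, status = "unscreenable", n_replicates = 0L,
             replicate_flags = NULL, hits = NULL),
        class = "gene_screen_result"
      )
      next
    }
    trees <- lapply(reps, build_lineage)
    cuts <- vapply(reps, cutoff_frame_350, numeric(1))
    ptabs <- Map(function(tr, cf) pair_measures(tr, cutoff_frame = cf),
                 trees, cuts)
    ctabs <- Map(function(tr, cf) cycle_lengths(tr, cutoff_frame = cf),
                 trees, cuts)
    screen[[gene]] <- call_hits(
      ptabs, ref, gene = gene, reduction = config$reduction,
      alphas = config$alphas, min_replicates = config$min_replicates
    )
    buffering[[gene]] <- buffering_test(
      ctabs, wt_cycles, lineage = config$buffering_lineage,
      alpha = config$buffering_alpha
    )
  }

  # spatial statistics for configured cells
  spatial <- NULL
  if (length(config$spatial_cells)) {
    wt_norm <- lapply(wt, function(r) normalize_axes(r)$recording)
    rows <- list()
    for (gene in names(perturbed)) {
      for (rec in perturbed[[gene]]) {
        norm <- tryCatch(normalize_axes(rec)$recording,
                         error = function(e) NULL)
        if (is.null(norm)) next
        for (cell in config$spatial_cells) {
          pd <- tryCatch(position_deviation(norm, wt_norm, cell),
                         error = function(e) NULL)
          if (is.null(pd)) next
          rows[[length(rows) + 1L]] <- data.frame(
            gene = gene, recording = rec$id, cell = cell,
            distance = pd$distance, p = pd$p, stringsAsFactors = FALSE
          )
        }
      }
    }
    spatial <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  result <- structure(
    list(reference = ref, qc = list(wildtype = wt_qc),
         screen = screen, buffering = buffering, spatial = spatial,
         exclusions = exclusions,
         cycle_tables = wt_cycles, pair_tables = wt_pairs,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    write_reports(result, config$out_dir)
  }
  result
}

#' Write tab-delimited pipeline reports
#'
#' Emits the per-cell cycle table, per-pair per-embryo ADS table, the pair
#' reference, the gene x pair hit matrix (cells empty, `0.05` or `0.01`),
#' the QC/exclusion log, the buffering table, positional deviations when
#' computed, and a plain-text run log echoing the configuration and seed.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }

  cyc <- do.call(rbind, lapply(seq_along(result$cycle_tables), function(i) {
    tb <- result$cycle_tables[[i]]
    tb$embryo <- attr(tb, "id")
    tb
  }))
  emit(cyc, "cycle_lengths.tsv")

  ads <- do.call(rbind, lapply(seq_along(result$pair_tables), function(i) {
    tb <- result$pair_tables[[i]]
    tb$embryo <- attr(tb, "id")
    tb[!tb$censored, ]
  }))
  emit(ads, "ads_by_embryo.tsv")

  emit(result$reference$pairs, "pair_reference.tsv")

  if (length(result$screen)) {
    pairs <- result$reference$monitored
    hm <- do.call(rbind, lapply(names(result$screen), function(gene) {
      sr <- result$screen[[gene]]
      row <- stats::setNames(rep("", length(pairs)), pairs)
      if (!is.null(sr$hits)) {
        lv <- sr$hits$hit_level
        lv[lv == "none"] <- ""
        row[sr$hits$parent] <- lv
      }
      cbind(data.frame(gene = gene, status = sr$status,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(row), check.names = FALSE))
    }))
    emit(hm, "hit_matrix.tsv")
  }

  if (length(result$buffering)) {
    buf <- do.call(rbind, lapply(names(result$buffering), function(gene) {
      b <- result$buffering[[gene]]
      tb <- b$table
      tb$gene <- gene
      tb$flagged <- b$flag
      tb
    }))
    emit(buf, "buffering.tsv")
  }

  emit(result$exclusions, "exclusions.tsv")
  if (!is.null(result$spatial)) {
    emit(result$spatial, "spatial_deviations.tsv")
  }

  cfg <- result$config
  log_lines <- c(
    paste0("lineatime ", as.character(utils::packageVersion("lineatime"))),
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", cfg$seed),
    "config:",
    paste0("  ", names(cfg)[!vapply(cfg, is.null, logical(1))], " = ",
           vapply(cfg[!vapply(cfg, is.null, logical(1))], function(v) {
             if (is.data.frame(v)) paste0("<", nrow(v), "-row table>")
             else paste(format(v), collapse = ",")
           }, character(1)))
  )
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  written <- c(written, log_path)
  invisible(written)
}
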