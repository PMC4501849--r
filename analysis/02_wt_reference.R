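#!/usr/bin/env Rscript
# Build the wild-type reference: per-cell cycle statistics, the
# between-embryo reproducibility matrix with complete-linkage Manhattan
# clustering, the generation-wise SD trend, and the per-pair ADS
# reference with normality flags and the >5-min monitored-pair selection.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ds <- study_dataset()
wt <- ds$wildtype

tabs <- lapply(wt, function(r) {
  tree <- build_lineage(r)
  cf <- cutoff_frame_350(r)
  list(cycles = cycle_lengths(tree, cutoff_frame = cf),
       pairs = pair_measures(tree, cutoff_frame = cf))
})
cycles <- lapply(tabs, `[[`, "cycles")
pairs <- lapply(tabs, `[[`, "pairs")

n_cells <- vapply(cycles, function(tb) sum(!tb$censored), 1L)
message(sprintf("quantified %d-%d cell cycle lengths per embryo",
                min(n_cells), max(n_cells)))

cm <- correlation_matrix(cycles)
off <- cm[upper.tri(cm)]
message(sprintf("between-embryo Pearson r: %.3f-%.3f (median %.3f)",
                min(off), max(off), median(off)))
cl <- cluster_embryos(cm)
cm_out <- data.frame(embryo = rownames(cm), round(cm, 4),
                     cluster_order = order(cl$order))
write_tsv(cm_out, "wt_correlation_matrix.tsv")

prof <- generation_sd_profile(cycles)
message("generation-wise mean SD of cycle length (min):")
message(paste(sprintf("  gen %d: %.2f (%d cells)", prof$generation,
              prof$mean_sd_min, prof$n_cells), collapse = "\n"))
write_tsv(prof, "wt_generation_sd_profile.tsv")

ref <- build_pair_reference(list(pair_tables = pairs,
                                 cycle_tables = cycles))
ref <- select_async_pairs(ref, 5.0)
ann <- attr(study_template(), "async_pairs")[, c("parent", "category")]
ref <- assign_pair_categories(ref, ann)
message(sprintf(
  "pair reference: %d pairs, %d monitored (mean ADS > 5 min), %.1f%% pass K2 normality",
  nrow(ref$pairs), length(ref$monitored),
  100 * mean(ref$pairs$normal_pass, na.rm = TRUE)))
message("monitored pairs: ", paste(sort(ref$monitored), collapse = ", "))
write_tsv(ref$pairs, "wt_pair_reference.tsv")
write_tsv(ref$cells, "wt_cell_reference.tsv")
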