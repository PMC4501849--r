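#!/usr/bin/env Rscript
# Generate the study's synthetic recordings: a 20-embryo wild-type cohort
# plus 3 replicates for each of 7 perturbation pseudo-genes, and export
# them as AceTree-style nuclei tables with a manifest (under scratch/ --
# they are bulky and fully reproducible from the seed). A compact truth
# table and per-embryo summary go to results/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ds <- study_dataset()
message(sprintf("simulated %d wild-type embryos and %d genes x %d replicates",
                length(ds$wildtype), length(ds$perturbed), REPLICATES))

dir.create(SCRATCH_DIR, showWarnings = FALSE, recursive = TRUE)
all_recs <- c(ds$wildtype, unlist(ds$perturbed, recursive = FALSE))
manifest <- data.frame(
  recording_id = vapply(all_recs, `[[`, character(1), "id"),
  path = paste0(vapply(all_recs, `[[`, character(1), "id"), ".tsv"),
  target_gene = vapply(all_recs, `[[`, character(1), "target_gene"),
  replicate = vapply(all_recs, `[[`, integer(1), "replicate"),
  marker = vapply(all_recs, `[[`, character(1), "marker")
)
for (i in seq_along(all_recs)) {
  write_nuclei_table(all_recs[[i]],
                     file.path(SCRATCH_DIR, manifest$path[i]),
                     xy_um_per_px = 1, z_um_per_plane = 1)
}
utils::write.table(manifest, file.path(SCRATCH_DIR, "manifest.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("exported ", nrow(manifest), " recordings to ", SCRATCH_DIR)

summary_tab <- data.frame(
  recording_id = manifest$recording_id,
  target_gene = manifest$target_gene,
  replicate = manifest$replicate,
  last_curated_frame = vapply(all_recs, `[[`, integer(1),
                              "last_curated_frame"),
  final_cell_count = vapply(all_recs, function(r) {
    cell_count_at(r, r$last_curated_frame)
  }, integer(1)),
  frame_350 = vapply(all_recs, cutoff_frame_350, numeric(1))
)
write_tsv(summary_tab, "recording_summary.tsv")
write_tsv(ds$truth, "perturbation_truth.tsv")

wt_350 <- summary_tab$frame_350[summary_tab$target_gene == "wild-type"]
message(sprintf(
  "wild-type embryos reach 350 cells at frame %.0f-%.0f (%.0f-%.0f min)",
  min(wt_350), max(wt_350), min(wt_350) * 1.5, max(wt_350) * 1.5))
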