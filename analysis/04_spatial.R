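#!/usr/bin/env Rscript
# Spatial statistics around the excretory-lineage precursor division
# (ABplpa): embryo axis normalization, positional deviation of the
# anterior granddaughter at its last time point against the wild-type
# centroid, and Box-Cox division-angle deviations in the three reference
# planes.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ds <- study_dataset()
FOCAL_PARENT <- "ABplpa"
FOCAL_CELL <- "ABplpapa"

wt_norm <- lapply(ds$wildtype, function(r) normalize_axes(r))
wt_recs <- lapply(wt_norm, `[[`, "recording")

# wild-type division-angle reference for the focal division
wt_angles <- t(vapply(seq_along(ds$wildtype), function(i) {
  division_angles(ds$wildtype[[i]], FOCAL_PARENT, wt_norm[[i]]$transform)
}, numeric(3)))
message(sprintf("wild-type %s division angles (deg, median): %s",
                FOCAL_PARENT,
                paste(colnames(wt_angles), round(apply(wt_angles, 2,
                                                       median), 1),
                      sep = "=", collapse = " ")))

rows <- list()
for (gene in names(ds$perturbed)) {
  for (rec in ds$perturbed[[gene]]) {
    nz <- tryCatch(normalize_axes(rec), error = function(e) NULL)
    if (is.null(nz)) next
    pd <- tryCatch(position_deviation(nz$recording, wt_recs, FOCAL_CELL),
                   error = function(e) NULL)
    ang <- tryCatch(division_angles(rec, FOCAL_PARENT, nz$transform),
                    error = function(e) NULL)
    for (plane in colnames(wt_angles)) {
      ad <- if (is.null(ang)) NULL else
        angle_deviation(wt_angles[, plane], ang[[plane]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, recording = rec$id, cell = FOCAL_CELL, plane = plane,
        position_distance = if (is.null(pd)) NA else round(pd$distance, 4),
        position_p = if (is.null(pd)) NA else signif(pd$p, 3),
        angle_deg = if (is.null(ang)) NA else round(ang[[plane]], 2),
        angle_p = if (is.null(ad)) NA else signif(ad$p, 3))
    }
  }
}
spatial <- do.call(rbind, rows)
write_tsv(spatial, "spatial_deviations.tsv")

sig <- spatial[!is.na(spatial$position_p) & spatial$position_p < 0.05, ]
message("recordings with positional deviation P < 0.05: ",
        paste(unique(sig$recording), collapse = ", "))
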