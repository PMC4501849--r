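# Shared setup for the analysis scripts: fixed study seed, the lineage
# template, and the screen dataset. Recordings are bulky, so scripts
# regenerate them deterministically from the master seed; if
# 01_simulate.R has exported them under scratch/, the manifest there is
# authoritative and identical by construction.

library(lineatime)

STUDY_SEED <- 17L
WT_N <- 20L
REPLICATES <- 3L

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch/recordings"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_template <- function() make_template(rounds = 9L, seed = 1L)

# the perturbation panel: one null pseudo-gene, two ADS collapses, a
# global slowdown, a variance capacitor, an early arrest and a marker
# knockout -- the phenotype classes the screen is built to separate
study_gene_specs <- function() {
  list(
    nullg      = perturbation(),
    adsA       = perturbation(ads_factor = c(P3 = 0.2, ABplpp = 0.2)),
    adsB       = perturbation(ads_factor = c(ABplpa = 0.3, MSaa = 0.3,
                                             Eal = 0.3)),
    slowpoke   = perturbation(slowdown = 2.0),
    capacitor  = perturbation(variance_inflation = 4),
    arrester   = perturbation(arrest_cell_count = 150),
    knockout   = perturbation(expression_knockout = c("MSaa", "ABalpa"),
                              ads_factor = c(MSaa = 0.3)),
    mispos     = perturbation(position_shift = list(cell = "ABplpa",
                                                    shift = c(0.7, 0.5, 0.3)),
                              angle_rotation = list(cell = "ABplpa",
                                                    degrees = 60,
                                                    plane = "AP-LR"))
  )
}

study_dataset <- function() {
  simulate_screen_dataset(study_template(), gene_specs = study_gene_specs(),
                          replicates = REPLICATES, seed = STUDY_SEED,
                          wt_n = WT_N)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path, "  (", nrow(df), " rows)")
}
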