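## EmbryoRecording: one embryo's curated 4D nuclei-tracking table plus
## metadata, as produced by automated lineaging pipelines (AceTree-style
## tabular output).

#' Construct an embryo recording
#'
#' @param observations Data frame with columns `cell`, `frame`, `x`, `y`,
#'   `z` and optionally `intensity`. Positions in micrometres, `frame`
#'   1-based integers.
#' @param id Recording identifier.
#' @param target_gene RNAi target gene, or `"wild-type"`.
#' @param replicate Replicate index within the gene.
#' @param marker Tissue-marker name (optional).
#' @param frame_interval_min Minutes per imaging frame (default 1.5).
#' @param last_curated_frame Last frame covered by curation; defaults to the
#'   maximum observed frame.
#' @param deaths Character vector of cells scored as dying (censored for
#'   timing).
#' @param validate Run [validate_recording()] (default `TRUE`).
#' @return An object of class `embryo_recording`.
#' @export
embryo_recording <- function(observations, id, target_gene = "wild-type",
                             replicate = 1L, marker = NA_character_,
                             frame_interval_min = 1.5,
                             last_curated_frame = NULL,
                             deaths = character(), validate = TRUE) {
  stopifnot(is.data.frame(observations))
  req <- c("cell", "frame", "x", "y", "z")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    stop("observations missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"intensity" %in% names(observations)) {
    observations$intensity <- NA_real_
  }
  observations <- observations[order(observations$cell, observations$frame),
                               c(req, "intensity")]
  observations$frame <- as.integer(observations$frame)
  rownames(observations) <- NULL
  if (is.null(last_curated_frame)) {
    last_curated_frame <- max(observations$frame)
  }
  rec <- structure(
    list(
      id = id, target_gene = target_gene, replicate = as.integer(replicate),
      marker = marker, frame_interval_min = frame_interval_min,
      last_curated_frame = as.integer(last_curated_frame),
      deaths = deaths, observations = observations
    ),
    class = "embryo_recording"
  )
  if (validate) {
    validate_recording(rec)
  }
  rec
}

#' @export
print.embryo_recording <- function(x, ...) {
  cat(sprintf(
    "<embryo_recording %s> gene=%s rep=%d  %d cells, frames 1..%d (dt=%.1f min)\n",
    x$id, x$target_gene, x$replicate,
    length(unique(x$observations$cell)), x$last_curated_frame,
    x$frame_interval_min
  ))
  invisible(x)
}

#' Validate an embryo recording
#'
#' Checks frame positivity, uniqueness of (cell, frame), per-cell frame
#' contiguity, mother/daughter frame continuity for observed mothers, and
#' that `last_curated_frame` covers every retained observation.
#'
#' @param rec An `embryo_recording`.
#' @return `rec`, invisibly; stops on violation.
#' @export
validate_recording <- function(rec) {
  obs <- rec$observations
  if (nrow(obs) == 0L) {
    stop("recording '", rec$id, "' has no observations")
  }
  if (any(obs$frame < 1L)) {
    stop("frame indices must be >= 1")
  }
  key <- paste(obs$cell, obs$frame)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (cell, frame) observations at rows: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  bad_names <- unique(obs$cell[!is_sulston_name(obs$cell)])
  if (length(bad_names)) {
    stop("invalid cell name(s): ", paste(utils::head(bad_names, 5), collapse = ", "))
  }
  first <- tapply(obs$frame, obs$cell, min)
  last <- tapply(obs$frame, obs$cell, max)
  n <- tapply(obs$frame, obs$cell, length)
  gap <- (last - first + 1L) != n
  if (any(gap)) {
    stop("non-contiguous frame range for cell(s): ",
         paste(utils::head(names(first)[gap], 5), collapse = ", "))
  }
  if (rec$last_curated_frame < max(obs$frame)) {
    stop("last_curated_frame (", rec$last_curated_frame,
         ") precedes the last observation (", max(obs$frame), ")")
  }
  # mother/daughter continuity where the mother is observed
  cells <- names(first)
  mothers <- vapply(cells, function(nm) {
    if (nm == "P0") NA_character_ else mother_of(nm)
  }, character(1))
  idx <- match(mothers, cells)
  observed <- !is.na(idx)
  if (any(observed)) {
    db <- first[cells[observed]]
    ml <- last[cells[idx[observed]]]
    bad <- db != ml + 1L
    if (any(bad)) {
      offender <- cells[observed][bad][1]
      stop("continuity error: '", offender, "' first appears at frame ",
           db[bad][1], " but its mother's last frame is ", ml[bad][1])
    }
  }
  invisible(rec)
}

#' Read a nuclei-tracking table
#'
#' Reads a delimited text table (comma or tab, header row) with columns
#' `cell`, `frame` (or `time`), `x`, `y`, `z` and optional `intensity`.
#' Positions are converted to micrometres using the supplied pixel/plane
#' scales. Rows whose cell name matches a whitelisted non-lineage pattern
#' (polar bodies, segmentation artifacts) are dropped and counted in the
#' read report attached as attribute `"read_report"`.
#'
#' @param path File path.
#' @param id Recording id; defaults to the file name without extension.
#' @param xy_um_per_px Micrometres per pixel in x and y (default 1.0).
#' @param z_um_per_plane Micrometres per imaging plane in z (default 0.71).
#' @param drop_patterns Regular expressions for non-lineage names to drop.
#' @param ... Passed to [embryo_recording()] (metadata fields).
#' @return A validated `embryo_recording`.
#' @export
read_nuclei_table <- function(path, id = NULL, xy_um_per_px = 1.0,
                              z_um_per_plane = 0.71,
                              drop_patterns = c("^Nuc", "^polar", "^p[12]$"),
                              ...) {
  if (is.null(id)) {
    id <- sub("\\.[^.]*$", "", basename(path))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if ("time" %in% names(tab) && !"frame" %in% names(tab)) {
    names(tab)[names(tab) == "time"] <- "frame"
  }
  req <- c("cell", "frame", "x", "y", "z")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  drop_re <- paste(drop_patterns, collapse = "|")
  dropped <- grepl(drop_re, tab$cell)
  report <- list(rows_read = nrow(tab), rows_dropped = sum(dropped),
                 dropped_names = unique(tab$cell[dropped]))
  tab <- tab[!dropped, , drop = FALSE]
  tab$x <- tab$x * xy_um_per_px
  tab$y <- tab$y * xy_um_per_px
  tab$z <- tab$z * z_um_per_plane
  rec <- embryo_recording(tab, id = id, ...)
  attr(rec, "read_report") <- report
  attr(rec, "scale") <- c(xy_um_per_px = xy_um_per_px,
                          z_um_per_plane = z_um_per_plane)
  rec
}

#' Write a nuclei-tracking table
#'
#' Inverse of [read_nuclei_table()]: positions are converted from
#' micrometres back to pixel/plane units and written as delimited text.
#'
#' @param rec An `embryo_recording`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @param xy_um_per_px,z_um_per_plane Scales used on read.
#' @return `path`, invisibly.
#' @export
write_nuclei_table <- function(rec, path, sep = "\t",
                               xy_um_per_px = 1.0, z_um_per_plane = 0.71) {
  obs <- rec$observations
  obs$x <- obs$x / xy_um_per_px
  obs$y <- obs$y / xy_um_per_px
  obs$z <- obs$z / z_um_per_plane
  if (all(is.na(obs$intensity))) {
    obs$intensity <- NULL
  }
  utils::write.table(obs, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Number of distinct cells present at a frame
#'
#' @param rec An `embryo_recording`.
#' @param frame Frame index, `1 <= frame <= last_curated_frame`.
#' @return Integer cell count.
#' @export
cell_count_at <- function(rec, frame) {
  if (frame < 1L || frame > rec$last_curated_frame) {
    stop("frame ", frame, " outside 1..", rec$last_curated_frame)
  }
  sum(rec$observations$frame == frame)
}

#' Developmental speed curve (cell count over time)
#'
#' @param rec An `embryo_recording`.
#' @return Data frame with columns `frame`, `count` for every observed
#'   frame; monotone non-decreasing for death-free recordings.
#' @export
speed_curve <- function(rec) {
  tab <- table(rec$observations$frame)
  data.frame(frame = as.integer(names(tab)), count = as.integer(tab))
}

#' Read a cohort manifest
#'
#' Delimited file with columns `recording_id`, `path`, `target_gene`,
#' `replicate`, `marker`. Paths are resolved relative to the manifest's
#' directory.
#'
#' @param path Manifest path.
#' @return Data frame with resolved `path` column.
#' @export
read_manifest <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  man <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("recording_id", "path", "target_gene", "replicate", "marker")
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols)) {
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}
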