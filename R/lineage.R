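## LineageTree: binary pedigree of Sulston-named cells with birth/division
## frames, reconstructed from a curated recording.

#' Build a lineage tree from a recording
#'
#' One node per distinct observed cell. Roots are the cells present at the
#' first observed frame (early names AB, P1, ABa, ABp, EMS, P2 are accepted
#' as roots even though their mothers were never imaged). A cell's division
#' is timestamped at its daughters' birth frame, which must equal the
#' mother's last observed frame + 1.
#'
#' @param rec A validated `embryo_recording`.
#' @return A `lineage_tree`: data frame (class-tagged) with one row per
#'   cell: `name`, `parent`, `daughter1`, `daughter2`, `birth_frame`,
#'   `last_frame`, `died`, `founder`, `generation`, plus attributes
#'   `frame_interval_min`, `last_curated_frame`, `roots`, `id`.
#' @export
build_lineage <- function(rec) {
  obs <- rec$observations
  first <- tapply(obs$frame, obs$cell, min)
  last <- tapply(obs$frame, obs$cell, max)
  cells <- names(first)
  parent <- vapply(cells, function(nm) {
    if (nm == "P0") NA_character_ else mother_of(nm)
  }, character(1))
  parent[!parent %in% cells] <- NA_character_

  first_frame <- min(obs$frame)
  roots <- cells[is.na(parent)]
  orphan <- roots[first[roots] > first_frame &
                    !roots %in% c("P0", "AB", "P1", "ABa", "ABp", "EMS", "P2")]
  if (length(orphan)) {
    stop("cell(s) appear mid-recording without an observed mother: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  # inconsistency: daughter present while mother still present
  has_parent <- !is.na(parent)
  if (any(has_parent)) {
    overlap <- first[cells[has_parent]] <= last[parent[has_parent]]
    if (any(overlap)) {
      bad <- cells[has_parent][overlap][1]
      stop("inconsistent tree: '", bad, "' present at frame ",
           first[[bad]], " while its mother is still present")
    }
  }

  d1 <- d2 <- rep(NA_character_, length(cells))
  kid_of <- split(cells[has_parent], parent[has_parent])
  for (p in names(kid_of)) {
    kids <- sort(kid_of[[p]])
    if (length(kids) > 2L) {
      stop("cell '", p, "' has more than two daughters")
    }
    i <- match(p, cells)
    d1[i] <- kids[1]
    if (length(kids) == 2L) d2[i] <- kids[2]
  }
  one_daughter <- !is.na(d1) & is.na(d2)
  if (any(one_daughter)) {
    stop("cell(s) with a single observed daughter: ",
         paste(utils::head(cells[one_daughter], 5), collapse = ", "))
  }

  tree <- data.frame(
    name = cells,
    parent = parent,
    daughter1 = d1,
    daughter2 = d2,
    birth_frame = as.integer(first),
    last_frame = as.integer(last),
    died = cells %in% rec$deaths,
    founder = founder_of(cells),
    generation = generation_of(cells),
    stringsAsFactors = FALSE
  )
  rownames(tree) <- NULL
  attr(tree, "frame_interval_min") <- rec$frame_interval_min
  attr(tree, "last_curated_frame") <- rec$last_curated_frame
  attr(tree, "roots") <- roots
  attr(tree, "id") <- rec$id
  class(tree) <- c("lineage_tree", "data.frame")
  tree
}

#' Export a lineage tree as a newick string
#'
#' Branch lengths are cell cycle lengths in minutes (birth to division, or
#' birth to last observed frame for undivided cells; censored branches can
#' be written as 0).
#'
#' @param tree A `lineage_tree`.
#' @param censored_as_zero Write undivided/terminal branch lengths as their
#'   observed (censored) duration if `FALSE` (default) or as 0 if `TRUE`.
#' @return A newick string (one tree if single root, else a semicolon-
#'   separated forest, one newick tree per root).
#' @export
to_newick <- function(tree, censored_as_zero = FALSE) {
  dt <- attr(tree, "frame_interval_min")
  idx <- stats::setNames(seq_len(nrow(tree)), tree$name)
  blen <- function(i) {
    divided <- !is.na(tree$daughter1[i])
    if (divided) {
      d <- idx[[tree$daughter1[i]]]
      (tree$birth_frame[d] - tree$birth_frame[i]) * dt
    } else if (censored_as_zero) {
      0
    } else {
      (tree$last_frame[i] - tree$birth_frame[i] + 1L) * dt
    }
  }
  recurse <- function(i) {
    nm <- tree$name[i]
    len <- format(blen(i), trim = TRUE)
    if (is.na(tree$daughter1[i])) {
      return(paste0(nm, ":", len))
    }
    kids <- paste(recurse(idx[[tree$daughter1[i]]]),
                  recurse(idx[[tree$daughter2[i]]]), sep = ",")
    paste0("(", kids, ")", nm, ":", len)
  }
  roots <- attr(tree, "roots")
  paste0(vapply(idx[roots], recurse, character(1)), ";", collapse = "\n")
}
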