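## Sulston nomenclature: founder relationships and generic suffix rules.

# Special mother table for the early embryo. Everything else is a founder
# stem plus a string of division-axis letters (a/p, l/r, d/v).
.SPECIAL_MOTHER <- c(
  AB = "P0", P1 = "P0",
  ABa = "AB", ABp = "AB",
  EMS = "P1", P2 = "P1",
  MS = "EMS", E = "EMS",
  C = "P2", P3 = "P2",
  D = "P3", P4 = "P3",
  Z2 = "P4", Z3 = "P4"
)

.SPECIAL_DAUGHTERS <- list(
  P0 = c("AB", "P1"), AB = c("ABa", "ABp"), P1 = c("EMS", "P2"),
  EMS = c("MS", "E"), P2 = c("C", "P3"), P3 = c("D", "P4"),
  P4 = c("Z2", "Z3")
)

.AXIS_LETTERS <- c("a", "p", "l", "r", "d", "v")

# Founders whose clones define sublineages; early cells reached before a
# founder map to the sentinel "early".
.FOUNDERS <- c("ABa", "ABp", "MS", "E", "C", "D", "P4")

# Cells whose division timings are excluded (first two rounds; imaging
# starts at the two- to four-cell stage).
.EARLY_EXCLUDED <- c("AB", "P1", "ABa", "ABp", "EMS", "P2")

#' Validate a Sulston cell name
#'
#' A name is valid if it is one of the early special names (P0--P4, AB, ABa,
#' ABp, EMS, MS, E, C, D, Z2, Z3) or a founder stem (AB, MS, E, C, D)
#' followed by division-axis letters from \{a, p, l, r, d, v\}.
#'
#' @param name Character vector of candidate names.
#' @return Logical vector.
#' @export
is_sulston_name <- function(name) {
  special <- name %in% c(names(.SPECIAL_MOTHER), "P0")
  generic <- grepl("^(AB|MS|E|C|D)[aplrdv]+$", name)
  special | generic
}

#' Mother of a cell under Sulston rules
#'
#' Early relationships follow the fixed founder table (e.g. E arises from
#' EMS; D and P4 are the two daughters of P3 and hence sisters). For all
#' other cells the mother's name is obtained by stripping the final
#' division-axis letter.
#'
#' @param name A single valid Sulston name other than P0.
#' @return The mother's name (character scalar).
#' @export
mother_of <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (identical(name, "P0")) {
    stop("P0 is the zygote and has no mother")
  }
  if (name %in% names(.SPECIAL_MOTHER)) {
    return(unname(.SPECIAL_MOTHER[[name]]))
  }
  if (!is_sulston_name(name)) {
    stop("not a valid Sulston name: '", name, "'")
  }
  last <- substr(name, nchar(name), nchar(name))
  if (!last %in% .AXIS_LETTERS) {
    stop("cannot strip division-axis letter from '", name, "'")
  }
  substr(name, 1L, nchar(name) - 1L)
}

#' Daughters of a cell under Sulston rules
#'
#' Inverse of [mother_of()]: the special table for the early embryo, and the
#' two division-axis letters appended for generic cells.
#'
#' @param name A single valid Sulston name.
#' @param axis Two-letter division axis for generic cells, one of
#'   `"ap"`, `"lr"`, `"dv"`. Default `"ap"`.
#' @return Character vector of the two daughter names.
#' @export
daughters_of <- function(name, axis = "ap") {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% names(.SPECIAL_DAUGHTERS)) {
    return(.SPECIAL_DAUGHTERS[[name]])
  }
  if (name %in% c("Z2", "Z3")) {
    stop("'", name, "' has no defined daughters (terminal germline cell)")
  }
  if (!is_sulston_name(name)) {
    stop("not a valid Sulston name: '", name, "'")
  }
  letters2 <- strsplit(axis, "")[[1]]
  if (length(letters2) != 2L || !all(letters2 %in% .AXIS_LETTERS)) {
    stop("axis must be one of 'ap', 'lr', 'dv'")
  }
  paste0(name, letters2)
}

#' Generation of a cell (divisions from the zygote)
#'
#' P0 is generation 0, AB and P1 generation 1, and so on; generic names add
#' one generation per division-axis letter beyond their special stem.
#'
#' @param name Character vector of valid names.
#' @return Integer vector of generations.
#' @export
generation_of <- function(name) {
  special_gen <- c(
    P0 = 0L, AB = 1L, P1 = 1L,
    ABa = 2L, ABp = 2L, EMS = 2L, P2 = 2L,
    MS = 3L, E = 3L, C = 3L, P3 = 3L,
    D = 4L, P4 = 4L, Z2 = 5L, Z3 = 5L
  )
  vapply(name, function(nm) {
    if (nm %in% names(special_gen)) {
      return(special_gen[[nm]])
    }
    if (!is_sulston_name(nm)) {
      stop("not a valid Sulston name: '", nm, "'")
    }
    stem <- sub("[aplrdv]+$", "", nm)
    suffix_len <- nchar(nm) - nchar(stem)
    special_gen[[stem]] + suffix_len
  }, integer(1), USE.NAMES = FALSE)
}

#' Founder sublineage of a cell
#'
#' Walks up the pedigree until one of the seven founders (ABa, ABp, MS, E,
#' C, D, P4) is reached; cells at or above the founders map to the sentinel
#' `"early"`.
#'
#' @param name Character vector of valid names.
#' @return Character vector of founder names or `"early"`.
#' @export
founder_of <- function(name) {
  vapply(name, function(nm) {
    cur <- nm
    repeat {
      if (cur %in% .FOUNDERS) {
        return(cur)
      }
      if (cur == "P0") {
        return("early")
      }
      # Z2/Z3 sit below founder P4
      cur <- mother_of(cur)
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Is `ancestor` an ancestor of (or equal to) `name`?
#'
#' @param name,ancestor Single valid Sulston names.
#' @param strict If `TRUE`, a cell is not its own ancestor.
#' @return Logical scalar.
#' @export
is_ancestor <- function(ancestor, name, strict = FALSE) {
  cur <- name
  if (!strict && identical(cur, ancestor)) {
    return(TRUE)
  }
  while (cur != "P0") {
    cur <- mother_of(cur)
    if (identical(cur, ancestor)) {
      return(TRUE)
    }
  }
  FALSE
}
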