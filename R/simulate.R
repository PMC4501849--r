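## Seeded generator of wild-type and perturbed embryo recordings with the
## statistical structure the analysis assumes: an invariant binary lineage
## with Sulston names, generation-dependent cycle-length noise, designated
## asynchronous sister pairs, 1.5-min frame quantization, 3D positions in
## a 2:1:1 ellipsoid, a marker sublineage, and perturbation phenotypes.

# run expr under a seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default designated asynchronous sister pairs
#'
#' Twelve parents whose daughters carry large mean cycle-length offsets
#' (8--40 min), spanning the founder sublineages and the three fate
#' categories; the P3 pair (D vs P4, soma vs germline) carries the largest
#' offset, as in the real embryo. All other pairs default to a 1-min
#' offset (anterior/left/dorsal daughter slightly faster).
#'
#' @return Data frame: `parent`, `offset_min`, `category`.
#' @export
default_async_pairs <- function() {
  data.frame(
    parent = c("P3", "ABplpa", "ABalpa", "ABarpa", "ABplaa", "ABprpp",
               "MSaa", "MSpa", "Eal", "Cap", "Dap", "ABplpp"),
    offset_min = c(40, 12, 10, 9, 9, 15, 8, 12, 10, 8, 8, 20),
    category = c("different-fate", "different-fate", "different-fate",
                 "blast-vs-terminal", "blast-vs-terminal", "different-fate",
                 "same-fate", "same-fate", "same-fate", "same-fate",
                 "same-fate", "same-fate"),
    stringsAsFactors = FALSE
  )
}

# founder tissue labels for fate assignment
.FOUNDER_FATE <- c(ABa = "pharynx", ABp = "neuron", MS = "pharynx",
                   E = "intestine", C = "hypodermis", D = "muscle",
                   P4 = "germline", early = "early")

# baseline mean cycle length (minutes) by generation; the widening spread
# mirrors the real embryo, where late-generation cycles stretch to an hour
.mu_gen <- function(g) {
  base <- c(15, 17, 18, 20, 24, 30, 38, 48, 60)
  ifelse(g <= 9, base[pmin(g, 9)], 60 + 10 * (g - 9))
}

#' Build an invariant lineage template
#'
#' Deterministic for fixed inputs. Contains the canonical founder skeleton
#' (P0 to AB/P1, P1 to EMS/P2, EMS to MS/E, P2 to C/P3, P3 to D/P4, P4 to
#' Z2/Z3) and expands every founder sublineage to `rounds` generations
#' with mostly anterior-posterior divisions (some l/r and d/v axes mixed
#' in). Baseline mean cycle lengths grow with generation; designated
#' asynchronous pairs carry mean offsets between their daughters, realized
#' as opposite-signed half-offsets around the pair mean.
#'
#' @param rounds Maximum generation (>= 5 so that 350 cells are
#'   reachable; default 9).
#' @param seed Seed for the deterministic axis-letter choices.
#' @param async_pairs Data frame as [default_async_pairs()].
#' @param marker_roots Sublineage roots expressing the tissue marker.
#' @param marker_level Mean marker intensity inside the sublineage.
#' @return A `lineage_template`: data frame with columns `name`, `parent`,
#'   `generation`, `founder`, `mu_base`, `mu_offset`, `axis`, `fate`,
#'   `divides`, plus attributes `async_pairs`, `marker`, `rounds`, `seed`.
#' @export
make_template <- function(rounds = 9L, seed = 1L,
                          async_pairs = default_async_pairs(),
                          marker_roots = c("ABalpa", "MSaa"),
                          marker_level = 1000) {
  if (rounds < 5L) {
    stop("rounds must be >= 5 to reach the 350-cell stage")
  }
  with_seed(seed, {
    # special skeleton with hand-set early cycle means (AB divides well
    # before P1 so the four-cell stage exists; EMS divides early)
    special <- data.frame(
      name = c("P0", "AB", "P1", "ABa", "ABp", "EMS", "P2",
               "MS", "E", "C", "P3", "D", "P4", "Z2", "Z3"),
      mu = c(NA, 15, 19, 17, 17.5, 16, 18, 18, 19, 18.5, 20, 20, 20, NA, NA),
      stringsAsFactors = FALSE
    )
    rows <- list()
    add_row <- function(name, parent, mu, axis) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = name, parent = parent, mu = mu, axis = axis,
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(nrow(special))) {
      nm <- special$name[i]
      add_row(nm, if (nm == "P0") NA_character_ else mother_of(nm),
              special$mu[i], "special")
    }
    # letters that must be produced so designated parents and marker roots
    # exist in the tree
    needed <- unique(c(async_pairs$parent, marker_roots))
    axis_of_letter <- c(a = "ap", p = "ap", l = "lr", r = "lr",
                        d = "dv", v = "dv")
    # expand generic sublineages breadth-first
    queue <- c("ABa", "ABp", "MS", "E", "C", "D")
    while (length(queue)) {
      cell <- queue[1]
      queue <- queue[-1]
      g <- generation_of(cell)
      if (g >= rounds) next
      forced <- needed[startsWith(needed, cell) & nchar(needed) > nchar(cell)]
      # names like "E" prefix-match "EMS"-free here: generic names only
      forced <- forced[is_sulston_name(forced)]
      if (length(forced)) {
        next_letter <- substr(forced[1], nchar(cell) + 1L, nchar(cell) + 1L)
        axis <- axis_of_letter[[next_letter]]
      } else {
        axis <- sample(c("ap", "lr", "dv"), 1, prob = c(0.7, 0.2, 0.1))
      }
      kids <- daughters_of(cell, axis)
      for (k in kids) {
        add_row(k, cell, .mu_gen(g + 1L), axis)
        queue <- c(queue, k)
      }
    }
    tpl <- do.call(rbind, rows)
    tpl$generation <- generation_of(tpl$name)
    tpl$founder <- founder_of(tpl$name)
    has_kids <- tpl$name %in% tpl$parent
    tpl$divides <- has_kids

    # fates: founder tissue, overridden for designated pairs below
    tpl$fate <- .FOUNDER_FATE[tpl$founder]

    # asynchrony offsets: designated pairs get +/- offset/2 around the
    # pair mean (clamped so both cycles stay positive); all other sister
    # pairs get a 1-min generic offset
    tpl$mu_base <- tpl$mu
    tpl$mu_offset <- 0
    first_letters <- c("a", "l", "d")
    generic_offset <- 1.0
    for (i in which(tpl$divides)) {
      kids <- tpl$name[!is.na(tpl$parent) & tpl$parent == tpl$name[i]]
      kids <- sort(kids)
      ki <- match(kids, tpl$name)
      spec_row <- match(tpl$name[i], async_pairs$parent)
      delta <- if (!is.na(spec_row)) async_pairs$offset_min[spec_row]
      else generic_offset
      base <- mean(tpl$mu[ki])
      fast <- max(base - delta / 2, 0.25 * base)
      slow <- fast + delta
      # first (anterior/left/dorsal, lexicographically first) daughter is
      # the fast one; for P3 the fast daughter is D (soma), slow is P4
      tpl$mu_base[ki] <- (fast + slow) / 2
      tpl$mu_offset[ki] <- c(-delta / 2, delta / 2)
      if (!is.na(spec_row)) {
        cat_lab <- async_pairs$category[spec_row]
        if (cat_lab == "different-fate") {
          alt <- setdiff(c("muscle", "neuron"), tpl$fate[ki[1]])[1]
          tpl$fate[ki[2]] <- alt
        } else if (cat_lab == "blast-vs-terminal") {
          tpl$fate[ki[1]] <- paste0(tpl$fate[ki[1]], "-terminal")
          tpl$fate[ki[2]] <- "blast"
        }
      }
    }
    missing_pairs <- setdiff(async_pairs$parent, tpl$name[tpl$divides])
    if (length(missing_pairs)) {
      stop("designated pair parent(s) not realized in template: ",
           paste(missing_pairs, collapse = ", "))
    }
    if (any(tpl$mu_base + tpl$mu_offset <= 0, na.rm = TRUE)) {
      stop("an asynchrony offset drives a mean cycle length <= 0")
    }
    tpl$mu <- NULL
    rownames(tpl) <- NULL
    attr(tpl, "async_pairs") <- async_pairs
    attr(tpl, "marker") <- list(roots = marker_roots, level = marker_level)
    attr(tpl, "rounds") <- rounds
    attr(tpl, "seed") <- seed
    class(tpl) <- c("lineage_template", "data.frame")
    tpl
  })
}

#' Cycle-length noise model
#'
#' Per-cell SD grows linearly with generation, sigma(c) = sigma0 + kappa x
#' generation(c); a shared per-embryo speed factor (SD `rho`) models
#' embryo-to-embryo global pace variation, which makes between-embryo
#' cycle-length correlation realistically high without per-cell
#' correlation.
#'
#' @param sigma0 Baseline SD in minutes (default 0.8).
#' @param kappa SD growth per generation, min/generation (default 0.25).
#' @param rho SD of the shared per-embryo speed factor (default 0.04).
#' @param speed Deterministic global speed multiplier (default 1).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma0 = 0.8, kappa = 0.25, rho = 0.04, speed = 1) {
  stopifnot(sigma0 >= 0, kappa >= 0, rho >= 0, rho < 1, speed > 0)
  structure(list(sigma0 = sigma0, kappa = kappa, rho = rho, speed = speed),
            class = "noise_model")
}

#' Perturbation phenotype specification
#'
#' Encodes the phenotype classes the screen must detect.
#'
#' @param ads_factor Named numeric, per designated pair parent: 0 collapses
#'   the pair's asynchrony, 1 leaves it untouched.
#' @param slowdown Global cycle-length multiplier (default 1).
#' @param variance_inflation Variance multiplier for the cycle-length noise
#'   (scalar, or named by founder).
#' @param arrest_frame Truncate the recording at this frame (optional).
#' @param arrest_cell_count Truncate when this cell count is reached.
#' @param position_shift List `(cell =, shift =)` with `shift` a 3-vector
#'   in normalized axis units, applied to the cell's subtree.
#' @param angle_rotation List `(cell =, degrees =, plane =)` rotating the
#'   cell's daughter separation within a reference plane.
#' @param expression_knockout Character vector of marker sublineage roots
#'   whose expression is zeroed.
#' @return A `perturbation` list.
#' @export
perturbation <- function(ads_factor = numeric(), slowdown = 1,
                         variance_inflation = 1, arrest_frame = NA,
                         arrest_cell_count = NA, position_shift = NULL,
                         angle_rotation = NULL,
                         expression_knockout = character()) {
  stopifnot(all(ads_factor >= 0), slowdown > 0, all(variance_inflation >= 0))
  structure(
    list(ads_factor = ads_factor, slowdown = slowdown,
         variance_inflation = variance_inflation,
         arrest_frame = arrest_frame, arrest_cell_count = arrest_cell_count,
         position_shift = position_shift, angle_rotation = angle_rotation,
         expression_knockout = expression_knockout),
    class = "perturbation"
  )
}

# letter -> direction in the raw embryo frame (AP ~ x, LR ~ y, DV ~ z)
.LETTER_DIR <- list(
  a = c(-1, 0, 0), p = c(1, 0, 0),
  l = c(0, -1, 0), r = c(0, 1, 0),
  d = c(0, 0, -1), v = c(0, 0, 1)
)

.SEMI_AXES <- c(26, 13, 13) # 2:1:1 ellipsoid, micrometres

#' Simulate one embryo recording
#'
#' Per-cell cycle length = slowdown x speed x shared-embryo-factor x
#' mu(c) + noise, with the noise SD from the generation-dependent model;
#' division times accumulate down the tree and are quantized to 1.5-min
#' frames (round-half-up, daughters' birth forced at least one frame
#' after the parent's). The recording is truncated at the first of: the
#' 350-cell stage plus a configurable overshoot, frame 240, or an arrest.
#' Positions are placed recursively (daughters at parent +/- half a
#' separation along the division-axis direction plus isotropic jitter,
#' kept inside a 2:1:1 ellipsoid); marker intensity is emitted inside the
#' marker sublineage.
#'
#' @param template A `lineage_template`.
#' @param noise A `noise_model`.
#' @param perturb A `perturbation`.
#' @param seed Integer seed (same seed, same recording).
#' @param id,target_gene,replicate,marker Recording metadata.
#' @param frame_interval_min Minutes per frame (default 1.5).
#' @param cell_target Cell count triggering the curation cutoff (350).
#' @param overshoot_frames Frames curated past the cell target (default 3).
#' @param max_frame Imaging duration in frames (default 240).
#' @param with_intensity Emit the intensity column (default `TRUE`).
#' @return A validated `embryo_recording`.
#' @export
simulate_embryo <- function(template, noise = noise_model(),
                            perturb = perturbation(), seed = 1L,
                            id = sprintf("sim_%06d", seed),
                            target_gene = "wild-type", replicate = 1L,
                            marker = "simulated-marker",
                            frame_interval_min = 1.5, cell_target = 350L,
                            overshoot_frames = 10L, max_frame = 240L,
                            with_intensity = TRUE) {
  tpl <- template[template$name != "P0", , drop = FALSE]
  n <- nrow(tpl)
  idx <- stats::setNames(seq_len(n), tpl$name)
  parent_i <- match(tpl$parent, tpl$name)
  dt <- frame_interval_min

  with_seed(seed, {
    speed_e <- noise$speed * (1 + stats::rnorm(1, 0, noise$rho))

    # effective mean cycle: asynchrony factor scales the pair offset
    f <- rep(1, n)
    if (length(perturb$ads_factor)) {
      hit <- tpl$parent %in% names(perturb$ads_factor)
      f[hit] <- perturb$ads_factor[tpl$parent[hit]]
    }
    mu_eff <- tpl$mu_base + tpl$mu_offset * f

    vi <- if (is.null(names(perturb$variance_inflation)))
      rep(perturb$variance_inflation, n)
    else {
      v <- rep(1, n)
      hit <- tpl$founder %in% names(perturb$variance_inflation)
      v[hit] <- perturb$variance_inflation[tpl$founder[hit]]
      v
    }
    sigma <- (noise$sigma0 + noise$kappa * tpl$generation) * sqrt(vi)
    cycle <- pmax(perturb$slowdown * speed_e * mu_eff +
                    stats::rnorm(n, 0, sigma), dt)

    # absolute birth/division times from the AB/P1 roots (time 0)
    birth <- rep(NA_real_, n)
    birth[idx[c("AB", "P1")]] <- 0
    for (g in sort(unique(tpl$generation))) {
      sel <- which(tpl$generation == g & is.na(birth))
      if (length(sel)) {
        birth[sel] <- birth[parent_i[sel]] + cycle[parent_i[sel]]
      }
    }

    # quantize to frames (round half up); daughters' birth is forced at
    # least one frame after the parent's so every cell is observed
    q <- function(t) as.integer(floor(t / dt + 0.5)) + 1L
    birth_frame <- rep(NA_integer_, n)
    div_frame <- rep(NA_integer_, n)
    birth_frame[idx[c("AB", "P1")]] <- 1L
    for (g in sort(unique(tpl$generation))) {
      par_g <- which(tpl$generation == g & tpl$divides)
      if (!length(par_g)) next
      div_frame[par_g] <- pmax(q(birth[par_g] + cycle[par_g]),
                               birth_frame[par_g] + 1L)
      kid_rows <- which(parent_i %in% par_g)
      birth_frame[kid_rows] <- div_frame[parent_i[kid_rows]]
    }

    # cell counts over frames (divisions proceed regardless of curation)
    ends <- ifelse(tpl$divides, div_frame - 1L, max_frame)
    delta <- integer(max_frame + 1L)
    bs <- pmin(birth_frame, max_frame + 1L)
    es <- pmin(ends + 1L, max_frame + 1L)
    for (i in seq_len(n)) {
      if (bs[i] <= max_frame) {
        delta[bs[i]] <- delta[bs[i]] + 1L
        delta[es[i]] <- delta[es[i]] - 1L
      }
    }
    count <- cumsum(delta)[seq_len(max_frame)]

    cutoff <- max_frame
    hit350 <- which(count >= cell_target)
    if (length(hit350)) {
      cutoff <- min(cutoff, min(hit350) + overshoot_frames)
    }
    if (!is.na(perturb$arrest_cell_count)) {
      hit_a <- which(count >= perturb$arrest_cell_count)
      if (length(hit_a)) cutoff <- min(cutoff, min(hit_a))
    }
    if (!is.na(perturb$arrest_frame)) {
      cutoff <- min(cutoff, perturb$arrest_frame)
    }
    four_cell_start <- birth_frame[idx[["EMS"]]]
    if (cutoff <= four_cell_start) {
      stop("arrest before the four-cell stage: recording would not ",
           "contain the reference frame")
    }

    # positions: static per cell, recursive placement
    pos <- matrix(NA_real_, n, 3)
    early_pos <- list(
      AB = c(-9, 0, 0), P1 = c(9, 0, 0),
      ABa = c(-14, -2, 1), ABp = c(-5, 6, 0),
      EMS = c(5, -6, 0), P2 = c(14, 2, -1)
    )
    dir_of <- function(nm) {
      if (nm %in% c("MS", "C", "D", "Z2")) return(.LETTER_DIR$a)
      if (nm %in% c("E", "P3", "P4", "Z3")) return(.LETTER_DIR$p)
      .LETTER_DIR[[substr(nm, nchar(nm), nchar(nm))]]
    }
    for (g in sort(unique(tpl$generation))) {
      sel <- which(tpl$generation == g)
      for (i in sel) {
        nm <- tpl$name[i]
        if (nm %in% names(early_pos)) {
          pos[i, ] <- early_pos[[nm]] + stats::rnorm(3, 0, 0.4)
        } else {
          r <- 26 * 0.72^g
          p <- pos[parent_i[i], ] + dir_of(nm) * r / 2 +
            stats::rnorm(3, 0, 0.12 * r)
          s <- sqrt(sum((p / .SEMI_AXES)^2))
          if (s > 0.97) p <- p * 0.97 / s
          pos[i, ] <- p
        }
      }
    }

    # post hoc: subtree position shift
    subtree_rows <- function(root) {
      keep <- rep(FALSE, n)
      keep[idx[[root]]] <- TRUE
      for (g in sort(unique(tpl$generation))) {
        sel <- which(tpl$generation == g & !is.na(parent_i))
        keep[sel] <- keep[sel] | keep[parent_i[sel]]
      }
      which(keep)
    }
    if (!is.null(perturb$position_shift)) {
      ps <- perturb$position_shift
      if (ps$cell %in% tpl$name) {
        rows <- subtree_rows(ps$cell)
        pos[rows, ] <- sweep(pos[rows, , drop = FALSE], 2,
                             -ps$shift * .SEMI_AXES)
      }
    }
    if (!is.null(perturb$angle_rotation)) {
      ar <- perturb$angle_rotation
      if (ar$cell %in% tpl$name && tpl$divides[idx[[ar$cell]]]) {
        kid_rows <- which(parent_i == idx[[ar$cell]])
        mid <- colMeans(pos[kid_rows, , drop = FALSE])
        axis_i <- switch(ar$plane, "AP-LR" = 3L, "AP-DV" = 2L,
                         "LR-DV" = 1L, 3L)
        th <- ar$degrees * pi / 180
        rot2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
        plane_dims <- setdiff(1:3, axis_i)
        for (k in kid_rows) {
          off_old <- pos[k, ] - mid
          off_new <- off_old
          off_new[plane_dims] <- as.numeric(rot2 %*% off_old[plane_dims])
          move <- off_new - off_old
          rows <- subtree_rows(tpl$name[k])
          pos[rows, ] <- sweep(pos[rows, , drop = FALSE], 2, -move)
        }
      }
    }

    # observations
    last_obs <- pmin(ifelse(tpl$divides & div_frame <= cutoff,
                            div_frame - 1L, cutoff), cutoff)
    keep <- birth_frame <= cutoff
    counts <- last_obs[keep] - birth_frame[keep] + 1L
    cell_col <- rep(tpl$name[keep], counts)
    frame_col <- unlist(lapply(which(keep), function(i) {
      seq.int(birth_frame[i], last_obs[i])
    }), use.names = FALSE)
    row_i <- rep(which(keep), counts)
    obs <- data.frame(
      cell = cell_col, frame = frame_col,
      x = pos[row_i, 1], y = pos[row_i, 2], z = pos[row_i, 3],
      stringsAsFactors = FALSE
    )

    mk <- attr(template, "marker")
    if (with_intensity && !is.null(mk)) {
      roots <- setdiff(mk$roots, perturb$expression_knockout)
      in_marker <- rep(FALSE, n)
      for (rt in intersect(roots, tpl$name)) {
        in_marker[subtree_rows(rt)] <- TRUE
      }
      m_obs <- in_marker[row_i]
      inten <- abs(stats::rnorm(nrow(obs), 30, 10))
      inten[m_obs] <- mk$level * pmax(0, 1 + stats::rnorm(sum(m_obs), 0, 0.05))
      obs$intensity <- inten
    }

    embryo_recording(obs, id = id, target_gene = target_gene,
                     replicate = replicate, marker = marker,
                     frame_interval_min = dt, last_curated_frame = cutoff)
  })
}

#' Simulate a cohort of independent embryos
#'
#' @param template,noise As in [simulate_embryo()].
#' @param n Number of embryos (>= 1).
#' @param seed Master seed; per-embryo seeds are drawn from it.
#' @param target_gene,perturb Shared metadata / perturbation.
#' @param id_prefix Prefix for recording ids.
#' @param ... Passed to [simulate_embryo()].
#' @return List of recordings with a `manifest` attribute (data frame).
#' @export
simulate_cohort <- function(template, noise = noise_model(), n = 20L,
                            seed = 1L, target_gene = "wild-type",
                            perturb = perturbation(), id_prefix = "wt",
                            ...) {
  if (n < 1L) stop("n must be >= 1")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  recs <- lapply(seq_len(n), function(i) {
    simulate_embryo(template, noise, perturb, seed = seeds[i],
                    id = sprintf("%s_%03d", id_prefix, i),
                    target_gene = target_gene, replicate = i, ...)
  })
  attr(recs, "manifest") <- data.frame(
    recording_id = vapply(recs, `[[`, character(1), "id"),
    target_gene = target_gene,
    replicate = seq_len(n),
    seed = seeds,
    stringsAsFactors = FALSE
  )
  recs
}

#' Simulate a full screen dataset with ground truth
#'
#' A wild-type cohort plus, for each pseudo-gene, `replicates` perturbed
#' embryos drawn under that gene's perturbation, with a machine-readable
#' truth table.
#'
#' @param template,noise As in [simulate_embryo()].
#' @param gene_specs Named list of `perturbation` objects (empty
#'   perturbations are null genes).
#' @param replicates Replicates per gene (default 3).
#' @param seed Master seed.
#' @param wt_n Wild-type cohort size (default 20).
#' @param ... Passed to [simulate_embryo()].
#' @return List: `wildtype` (cohort), `perturbed` (named list of recording
#'   lists), `truth` (data frame: gene, perturbed pairs, factors).
#' @export
simulate_screen_dataset <- function(template, noise = noise_model(),
                                    gene_specs, replicates = 3L, seed = 1L,
                                    wt_n = 20L, ...) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      1L + length(gene_specs)))
  wt <- simulate_cohort(template, noise, n = wt_n, seed = seeds[1], ...)
  perturbed <- lapply(seq_along(gene_specs), function(k) {
    gene <- names(gene_specs)[k]
    simulate_cohort(template, noise, n = replicates, seed = seeds[1L + k],
                    target_gene = gene, perturb = gene_specs[[k]],
                    id_prefix = gene, ...)
  })
  names(perturbed) <- names(gene_specs)
  truth <- do.call(rbind, lapply(names(gene_specs), function(gene) {
    sp <- gene_specs[[gene]]
    data.frame(
      gene = gene,
      ads_pairs = paste(names(sp$ads_factor), collapse = ","),
      ads_factors = paste(sp$ads_factor, collapse = ","),
      slowdown = sp$slowdown,
      variance_inflation = paste(sp$variance_inflation, collapse = ","),
      arrest_frame = sp$arrest_frame,
      expression_knockout = paste(sp$expression_knockout, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  list(wildtype = wt, perturbed = perturbed, truth = truth)
}
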