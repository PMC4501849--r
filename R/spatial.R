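## Embryo coordinate normalization, trajectories, migration-deviation
## statistics and Box-Cox division-angle statistics.

#' Last frame of the four-cell stage
#'
#' The greatest frame at which exactly \{ABa, ABp, EMS, P2\} are present.
#'
#' @param rec An `embryo_recording`.
#' @return Integer frame.
#' @export
last_four_cell_frame <- function(rec) {
  obs <- rec$observations
  four <- c("ABa", "ABp", "EMS", "P2")
  counts <- table(obs$frame)
  cand <- as.integer(names(counts)[counts == 4L])
  for (f in rev(cand)) {
    if (setequal(obs$cell[obs$frame == f], four)) {
      return(f)
    }
  }
  stop("recording '", rec$id, "' has no four-cell stage frame ",
       "(started later or mis-curated)")
}

#' Normalize embryo axes and scale to the unit cube
#'
#' At the last four-cell frame, the A-P direction is the ABa-to-P2 line
#' (anterior negative) and the second axis is the ABp-to-EMS line
#' orthogonalized against A-P (labelled L-R, following the field's
#' four-cell convention for these statistics); D-V completes a
#' right-handed frame. All positions are translated to the four-cell
#' centroid, rotated, and each axis affinely mapped so the global min/max
#' over all frames and cells lands on [-1, 1]. A `time_min` column is
#' added with the reference frame at time 0.
#'
#' @param rec An `embryo_recording`.
#' @return List: `recording` (normalized copy) and `transform` (class
#'   `embryo_frame_transform`: `reference_frame`, `origin`, `rotation`
#'   with rows A-P, L-R, D-V, `scale` with per-axis `lo`/`hi`).
#' @export
normalize_axes <- function(rec) {
  f4 <- last_four_cell_frame(rec)
  obs <- rec$observations
  at4 <- obs[obs$frame == f4, ]
  pos <- function(nm) as.numeric(at4[at4$cell == nm, c("x", "y", "z")])
  p_aba <- pos("ABa"); p_abp <- pos("ABp")
  p_ems <- pos("EMS"); p_p2 <- pos("P2")

  ap <- p_p2 - p_aba
  nap <- sqrt(sum(ap^2))
  if (nap < 1e-12) stop("degenerate four-cell geometry (ABa == P2)")
  ap <- ap / nap
  lr <- p_ems - p_abp
  lr <- lr - sum(lr * ap) * ap
  nlr <- sqrt(sum(lr^2))
  if (nlr < 1e-9) stop("degenerate four-cell geometry (cells collinear)")
  lr <- lr / nlr
  dv <- c(ap[2] * lr[3] - ap[3] * lr[2],
          ap[3] * lr[1] - ap[1] * lr[3],
          ap[1] * lr[2] - ap[2] * lr[1])
  rot <- rbind(AP = ap, LR = lr, DV = dv)
  origin <- (p_aba + p_abp + p_ems + p_p2) / 4

  xyz <- as.matrix(obs[, c("x", "y", "z")])
  rotated <- sweep(xyz, 2, origin) %*% t(rot)
  lo <- apply(rotated, 2, min)
  hi <- apply(rotated, 2, max)
  if (any(hi - lo < 1e-12)) stop("degenerate extent along an embryo axis")
  scaled <- sweep(sweep(rotated, 2, (lo + hi) / 2), 2, (hi - lo) / 2, "/")

  out <- rec
  out$observations$x <- scaled[, 1]
  out$observations$y <- scaled[, 2]
  out$observations$z <- scaled[, 3]
  out$observations$time_min <-
    (out$observations$frame - f4) * rec$frame_interval_min

  transform <- structure(
    list(reference_frame = f4, origin = origin, rotation = rot,
         scale = list(lo = lo, hi = hi)),
    class = "embryo_frame_transform"
  )
  list(recording = out, transform = transform)
}

#' Apply an embryo frame transform to raw positions
#'
#' @param xyz n x 3 matrix of raw micrometre positions.
#' @param transform An `embryo_frame_transform`.
#' @param scale Also apply the per-axis [-1, 1] mapping (default `TRUE`);
#'   `FALSE` gives rotated-but-unscaled coordinates (used for angles).
#' @return n x 3 matrix in (AP, LR, DV) coordinates.
#' @export
apply_frame_transform <- function(xyz, transform, scale = TRUE) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  rotated <- sweep(xyz, 2, transform$origin) %*% t(transform$rotation)
  if (!scale) {
    return(rotated)
  }
  lo <- transform$scale$lo
  hi <- transform$scale$hi
  sweep(sweep(rotated, 2, (lo + hi) / 2), 2, (hi - lo) / 2, "/")
}

#' Migration trajectory of a cell through its ancestors
#'
#' Concatenated per-frame positions of the ancestor chain from `start`
#' down to the target's last observed frame; consecutive points define the
#' migration arrows.
#'
#' @param rec An `embryo_recording` (raw or normalized).
#' @param target Cell whose history is traced.
#' @param start Ancestor at which the trace begins (default the target's
#'   founder-side root present in the recording).
#' @return Data frame: `cell`, `frame`, `time_min` (if present), `x`,
#'   `y`, `z`, ordered by frame.
#' @export
trajectory <- function(rec, target, start = NULL) {
  obs <- rec$observations
  present <- unique(obs$cell)
  if (!target %in% present) {
    stop("target cell '", target, "' not observed")
  }
  chain <- target
  cur <- target
  while (cur != "P0") {
    if (!is.null(start) && cur == start) break
    mom <- if (cur == "P0") NA_character_ else tryCatch(
      mother_of(cur), error = function(e) NA_character_
    )
    if (is.na(mom) || !mom %in% present) break
    chain <- c(mom, chain)
    cur <- mom
  }
  if (!is.null(start)) {
    if (!start %in% chain) {
      stop("'", start, "' is not an observed ancestor of '", target, "'")
    }
    chain <- chain[which(chain == start):length(chain)]
  }
  path <- obs[obs$cell %in% chain, , drop = FALSE]
  path <- path[order(path$frame), , drop = FALSE]
  keep <- intersect(c("cell", "frame", "time_min", "x", "y", "z"),
                    names(path))
  rownames(path) <- NULL
  path[, keep]
}

#' Positional deviation of a cell from the wild-type centroid
#'
#' In normalized coordinates, the wild-type centroid of the cell's
#' position at its last observed frame is computed across the cohort; the
#' perturbed embryo's distance to that centroid is referred to a normal
#' fitted to the wild-type distances (upper tail). Per-coordinate
#' K-squared normality of the wild-type spatial distribution is reported
#' when the cohort is large enough.
#'
#' @param perturbed A normalized `embryo_recording`.
#' @param wildtype List of normalized wild-type `embryo_recording`s.
#' @param cell Cell name.
#' @param min_n Minimum wild-type embryos carrying the cell (default 8).
#' @return List: `distance`, `p`, `centroid`, `wt_distances`,
#'   `coord_k2_p` (3-vector or NULL).
#' @export
position_deviation <- function(perturbed, wildtype, cell, min_n = 8L) {
  last_pos <- function(rec) {
    obs <- rec$observations[rec$observations$cell == cell, , drop = FALSE]
    if (!nrow(obs)) {
      return(NULL)
    }
    as.numeric(obs[which.max(obs$frame), c("x", "y", "z")])
  }
  wt_pos <- Filter(Negate(is.null), lapply(wildtype, last_pos))
  if (length(wt_pos) < min_n) {
    stop("cell '", cell, "' present in only ", length(wt_pos),
         " wild-type embryos (need ", min_n, ")")
  }
  wt_mat <- do.call(rbind, wt_pos)
  centroid <- colMeans(wt_mat)
  wt_d <- sqrt(rowSums(sweep(wt_mat, 2, centroid)^2))
  pp <- last_pos(perturbed)
  if (is.null(pp)) {
    stop("cell '", cell, "' absent from perturbed recording")
  }
  d <- sqrt(sum((pp - centroid)^2))
  m <- mean(wt_d)
  s <- stats::sd(wt_d)
  if (s == 0) {
    warning("degenerate wild-type distance distribution (sd = 0)")
    p <- if (d <= m) 1 else 0
  } else {
    p <- tail_probability(m, s, d, side = "upper")
  }
  coord_k2 <- if (nrow(wt_mat) >= 8L) {
    vapply(1:3, function(k) {
      tryCatch(dagostino_k2(wt_mat[, k])$p_value,
               error = function(e) NA_real_)
    }, numeric(1))
  } else NULL
  list(distance = d, p = p, centroid = centroid, wt_distances = wt_d,
       coord_k2_p = coord_k2)
}

#' Division angles against the three embryo reference planes
#'
#' The angle between the line joining the two daughters immediately after
#' division and each reference plane (AP-LR, AP-DV, LR-DV), computed in
#' rotated-but-unscaled coordinates (anisotropic scaling would distort
#' angles). For a plane with unit normal n, the angle is
#' asin(|v . n| / |v|), reported in [0, 90] degrees.
#'
#' @param rec A raw `embryo_recording`.
#' @param cell A divided cell (both daughters observed).
#' @param transform The embryo's `embryo_frame_transform`.
#' @return Named numeric: `AP-LR`, `AP-DV`, `LR-DV` (degrees).
#' @export
division_angles <- function(rec, cell, transform) {
  obs <- rec$observations
  d <- sort(intersect(
    if (cell %in% names(.SPECIAL_DAUGHTERS)) .SPECIAL_DAUGHTERS[[cell]]
    else paste0(cell, .AXIS_LETTERS),
    unique(obs$cell)
  ))
  if (length(d) != 2L) {
    stop("cell '", cell, "' does not have two observed daughters")
  }
  birth <- min(obs$frame[obs$cell == d[1]])
  p1 <- as.numeric(obs[obs$cell == d[1] & obs$frame == birth,
                       c("x", "y", "z")])
  p2 <- as.numeric(obs[obs$cell == d[2] & obs$frame == birth,
                       c("x", "y", "z")])
  v <- apply_frame_transform(rbind(p2), transform, scale = FALSE) -
    apply_frame_transform(rbind(p1), transform, scale = FALSE)
  v <- as.numeric(v)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    stop("zero-length daughter separation for '", cell, "'")
  }
  # components are (AP, LR, DV); plane normals: AP-LR -> DV, AP-DV -> LR,
  # LR-DV -> AP
  ang <- asin(pmin(1, abs(v[c(3, 2, 1)]) / nv)) * 180 / pi
  stats::setNames(ang, c("AP-LR", "AP-DV", "LR-DV"))
}

#' Box-Cox power parameter by profile maximum likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood
#' (lambda - 1) * sum(log x) - n/2 * log(sigma-hat^2(y_lambda)) over
#' lambda in [-5, 5] with a bracketing optimizer (tolerance 1e-6).
#'
#' @param x Positive sample, n >= 10.
#' @return The MLE lambda.
#' @export
boxcox_lambda_mle <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 10L) {
    stop("need n >= 10 for Box-Cox lambda estimation")
  }
  if (any(x <= 0)) {
    stop("Box-Cox requires strictly positive values")
  }
  slog <- sum(log(x))
  n <- length(x)
  llf <- function(lambda) {
    y <- boxcox_transform(x, lambda)
    v <- mean((y - mean(y))^2)
    (lambda - 1) * slog - n / 2 * log(v)
  }
  stats::optimize(llf, interval = c(-5, 5), maximum = TRUE,
                  tol = 1e-6)$maximum
}

#' Box-Cox transform
#'
#' @param x Positive values.
#' @param lambda Power parameter; `(x^lambda - 1)/lambda`, or `log(x)` at
#'   lambda = 0.
#' @return Transformed values.
#' @export
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Division-angle deviation of a perturbed embryo
#'
#' Fits Box-Cox lambda on the wild-type angle sample (angles clamped to
#' >= `floor_deg` since the transform needs positives), transforms,
#' removes outliers beyond 3 SD in a single pass, recomputes mean/SD and
#' K-squared normality, then transforms the perturbed angle with the same
#' lambda and reports its two-sided normal tail probability.
#'
#' @param wt_angles Wild-type angle sample in degrees (n >= 10).
#' @param perturbed_angle Perturbed embryo's angle (degrees).
#' @param floor_deg Positivity clamp (default 0.1 degrees).
#' @return List: `z`, `p`, `reference` (lambda, mean, sd, n_outliers,
#'   k2_p).
#' @export
angle_deviation <- function(wt_angles, perturbed_angle, floor_deg = 0.1) {
  wt <- pmax(as.numeric(wt_angles), floor_deg)
  lambda <- boxcox_lambda_mle(wt)
  y <- boxcox_transform(wt, lambda)
  m0 <- mean(y); s0 <- stats::sd(y)
  keep <- abs(y - m0) < 3 * s0
  y <- y[keep]
  if (length(y) < 8L) {
    stop("fewer than 8 wild-type angles remain after outlier removal")
  }
  m <- mean(y); s <- stats::sd(y)
  k2p <- tryCatch(dagostino_k2(y)$p_value, error = function(e) NA_real_)
  yp <- boxcox_transform(max(perturbed_angle, floor_deg), lambda)
  z <- (yp - m) / s
  p <- tail_probability(m, s, yp, side = "two")
  list(z = z, p = p,
       reference = list(lambda = lambda, mean = m, sd = s,
                        n_outliers = sum(!keep), k2_p = k2p))
}
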