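# Water-water hydrogen bonds by donor-acceptor (O-O) distance cutoff.
# The classic cutoffs are 2.8 A (strong), 3.0 A (medium), 3.3 A (weak).
# No angular term: fixtures and coarse water models carry oxygens only; an
# optional donor-H..acceptor angle filter is available when hydrogens exist.

#' Find water-water hydrogen-bond pairs in one frame
#'
#' Returns every unordered oxygen pair whose minimum-image distance is at
#' most `cutoff`. Uses a cell-list neighbour search (linear in N for dense
#' systems); results are identical to the all-pairs scan. When the box
#' accommodates fewer than 3 cells per edge the all-pairs scan is used
#' directly.
#'
#' @param frame `N x 3` coordinate matrix (Angstrom) of water oxygens, or a
#'   one-frame selection thereof.
#' @param cutoff donor-acceptor distance cutoff, Angstrom; must be
#'   `<= L/2` for the minimum-image convention to be valid.
#' @param L cubic box edge, Angstrom.
#' @param hydrogens optional list per oxygen of `K x 3` hydrogen coordinate
#'   matrices; when supplied together with `angle_min`, pairs are kept only
#'   if some donor-H..acceptor angle is at least `angle_min` degrees.
#' @param angle_min optional angle filter in degrees (default NULL = off).
#' @return two-column integer matrix of pair indices (i < j) with an
#'   attached `"dist"` attribute of pair distances.
#' @export
find_hbonds <- function(frame, cutoff, L, hydrogens = NULL,
                        angle_min = NULL) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L, cutoff > 0, L > 0)
  if (cutoff > L / 2)
    stop("cutoff (", cutoff, " A) exceeds L/2 (", L / 2,
         " A); minimum-image pair search is invalid")
  n <- nrow(frame)
  pos <- wrap_box(frame, L)
  ncell <- floor(L / cutoff)
  pairs <- if (n < 2L) {
    matrix(integer(0), ncol = 2)
  } else if (ncell < 3L) {
    all_pairs_within(pos, cutoff, L)
  } else {
    cell_list_pairs(pos, cutoff, L, ncell)
  }
  if (!is.null(angle_min) && !is.null(hydrogens) && nrow(pairs) > 0) {
    keep <- vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      ok <- function(d, h) {  # donor d with hydrogens h, acceptor the other
        if (is.null(h) || nrow(h) == 0) return(FALSE)
        any(apply(h, 1L, function(hp) {
          v1 <- min_image(rbind(hp - pos[d, ]), L)[1, ]
          v2 <- min_image(rbind(pos[setdiff(c(i, j), d), ] - pos[d, ]), L)[1, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
          (180 - ang * 180 / pi) >= angle_min
        }))
      }
      ok(i, hydrogens[[i]]) || ok(j, hydrogens[[j]])
    }, logical(1))
    d <- attr(pairs, "dist")[keep]
    pairs <- pairs[keep, , drop = FALSE]
    attr(pairs, "dist") <- d
  }
  pairs
}

# All-pairs minimum-image search; reference implementation and fallback.
all_pairs_within <- function(pos, cutoff, L) {
  n <- nrow(pos)
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  d <- min_image(pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE], L)
  dist <- sqrt(rowSums(d * d))
  keep <- dist <= cutoff
  out <- cbind(i = ii[keep], j = jj[keep])
  attr(out, "dist") <- dist[keep]
  out
}

# Cell-list search: bin atoms into ncell^3 cells of edge >= cutoff, then
# scan each cell against itself and its 13 forward periodic neighbours.
cell_list_pairs <- function(pos, cutoff, L, ncell) {
  cl <- L / ncell
  ci <- pmin(floor(pos / cl), ncell - 1L)  # 0-based cell coords
  id <- ci[, 1] + ncell * (ci[, 2] + ncell * ci[, 3])
  members <- split(seq_len(nrow(pos)), id)
  occ_ids <- as.integer(names(members))
  # 13 lexicographically-forward offsets: each unordered cell pair once
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
             (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  pair_block <- function(ia, ib) {
    d <- min_image(pos[rep(ib, each = length(ia)), , drop = FALSE] -
                   pos[rep(ia, times = length(ib)), , drop = FALSE], L)
    dist <- sqrt(rowSums(d * d))
    keep <- dist <= cutoff
    list(i = rep(ia, times = length(ib))[keep],
         j = rep(ib, each = length(ia))[keep], d = dist[keep])
  }
  for (k in seq_along(members)) {
    ia <- members[[k]]
    if (length(ia) > 1L) {  # within-cell pairs
      p <- all_pairs_within(pos[ia, , drop = FALSE], cutoff, L)
      res_i <- c(res_i, ia[p[, 1]]); res_j <- c(res_j, ia[p[, 2]])
      res_d <- c(res_d, attr(p, "dist"))
    }
    cid <- occ_ids[k]
    cx <- cid %% ncell; cy <- (cid %/% ncell) %% ncell; cz <- cid %/% ncell^2
    for (o in seq_len(nrow(off))) {
      nx <- (cx + off[o, 1]) %% ncell
      ny <- (cy + off[o, 2]) %% ncell
      nz <- (cz + off[o, 3]) %% ncell
      nb <- members[[as.character(nx + ncell * (ny + ncell * nz))]]
      if (is.null(nb)) next
      p <- pair_block(ia, nb)
      res_i <- c(res_i, p$i); res_j <- c(res_j, p$j); res_d <- c(res_d, p$d)
    }
  }
  swap <- res_i > res_j
  tmp <- res_i[swap]; res_i[swap] <- res_j[swap]; res_j[swap] <- tmp
  ord <- order(res_i, res_j)
  out <- cbind(i = res_i[ord], j = res_j[ord])
  attr(out, "dist") <- res_d[ord]
  out
}

#' Per-frame average number of hydrogen bonds per water molecule
#'
#' For each analysed frame, the per-molecule average is
#' `2 * pairs / N_water` (each bond credited to both partners; the
#' "pairs" convention, `pairs / N_water`, is selectable — it halves the
#' absolute level but leaves drops and fluctuation trends untouched).
#'
#' @param traj an [trajectory()] whose water oxygens to analyse.
#' @param cutoff donor-acceptor cutoff, Angstrom (2.8 / 3.0 / 3.3 are the
#'   conventional strong/medium/weak choices).
#' @param stride analyse every `stride`-th frame.
#' @param selection integer indices of water oxygens; by default atoms whose
#'   residue name is one of `water_resnames` (all atoms if no metadata).
#' @param convention `"both"` (default, `2*pairs/N`) or `"pairs"`
#'   (`pairs/N`).
#' @param water_resnames residue names treated as water.
#' @return object of class `sbx_hbond_stats`: an [timeseries()]-like list
#'   with `times` (ns), `values` (bonds/molecule), plus `cutoff`,
#'   `convention`, `n_water`.
#' @export
hbond_timeseries <- function(traj, cutoff, stride = 1L, selection = NULL,
                             convention = c("both", "pairs"),
                             water_resnames = c("HOH", "TIP3", "SOL", "WAT")) {
  stopifnot(inherits(traj, "sbx_trajectory"))
  convention <- match.arg(convention)
  if (is.null(selection)) {
    selection <- if (is.null(traj$atoms)) seq_len(n_atoms(traj)) else
      select_atoms(traj, resname = water_resnames)
  }
  if (!length(selection)) stop("water selection is empty")
  frames <- seq(1L, n_frames(traj), by = stride)
  nw <- length(selection)
  fac <- if (convention == "both") 2 else 1
  vals <- vapply(frames, function(f) {
    p <- find_hbonds(frame_mat(traj$coords, selection, f), cutoff, traj$box)
    fac * nrow(p) / nw
  }, numeric(1))
  obj <- list(times = (frames - 1L) * traj$dt / 1000,  # ps -> ns
              values = vals, label = "<N_H-bonds>/molecule", unit = "count",
              cutoff = cutoff, convention = convention, n_water = nw,
              metadata = list())
  class(obj) <- c("sbx_hbond_stats", "sbx_timeseries")
  obj
}

#' Interval means, fluctuations, and per-transition drops of a series
#'
#' Running averages over the time intervals between structural transitions:
#' per interval the mean, standard deviation and sample count, plus the
#' successive-interval mean differences (the drop per transition).
#'
#' @param x an `sbx_timeseries` (e.g. from [hbond_timeseries()]).
#' @param boundaries_ns sorted interior interval boundaries, ns, inside the
#'   series span.
#' @return data.frame with `start`, `end`, `mean`, `sd`, `n`, plus
#'   attribute `"drops"` = `diff(mean)`.
#' @export
interval_statistics <- function(x, boundaries_ns) {
  stopifnot(inherits(x, "sbx_timeseries"))
  if (length(boundaries_ns) && is.unsorted(boundaries_ns))
    stop("interval boundaries must be sorted")
  span <- range(x$times)
  if (length(boundaries_ns) &&
      (any(boundaries_ns <= span[1]) || any(boundaries_ns >= span[2])))
    stop("interval boundaries must lie strictly inside the series span")
  edges <- c(span[1], boundaries_ns, span[2])
  out <- data.frame(start = edges[-length(edges)], end = edges[-1],
                    mean = NA_real_, sd = NA_real_, n = NA_integer_)
  for (k in seq_len(nrow(out))) {
    inside <- x$times >= out$start[k] &
      (if (k == nrow(out)) x$times <= out$end[k] else x$times < out$end[k])
    if (!any(inside))
      stop("interval [", out$start[k], ", ", out$end[k], ") holds no samples")
    v <- x$values[inside]
    out$mean[k] <- mean(v)
    out$sd[k] <- if (length(v) > 1L) stats::sd(v) else 0
    out$n[k] <- length(v)
  }
  attr(out, "drops") <- diff(out$mean)
  out
}
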