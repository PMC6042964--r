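# Hydration structure: radial distribution functions, Chandler-style
# solvent density profiles around a solute, and water counts in geometric
# regions (all minimum-image aware).

#' Radial distribution function g(r)
#'
#' Histogram of minimum-image reference-target distances, normalized per
#' frame by the ideal-gas shell expectation `4 pi r^2 dr * rho`, with
#' `rho = n_target / L^3` the target bulk number density. For a uniform
#' target g(r) tends to 1.
#'
#' @param traj an [trajectory()].
#' @param ref_selection integer indices of reference atoms (non-empty).
#' @param target_selection integer indices of target atoms (non-empty;
#'   atoms in both selections are never paired with themselves).
#' @param r_max histogram range, Angstrom; must be `<= L/2`.
#' @param dr bin width, Angstrom (default 0.1, the usual choice for
#'   residue-water g(r); use ~0.5 for protein-scale profiles).
#' @param frames frame indices to average over (default all).
#' @return object of class `sbx_rdf`: `r` (bin centers), `g`, `dr`,
#'   `counts` (raw pair counts per bin), `n_frames`, `rho`.
#' @export
radial_distribution <- function(traj, ref_selection, target_selection,
                                r_max, dr = 0.1, frames = NULL) {
  stopifnot(inherits(traj, "sbx_trajectory"), dr > 0, r_max > 0)
  L <- traj$box
  if (r_max > L / 2)
    stop("r_max (", r_max, " A) exceeds L/2 (", L / 2,
         " A): minimum-image distances are ambiguous beyond L/2")
  if (!length(ref_selection)) stop("reference selection is empty")
  if (!length(target_selection)) stop("target selection is empty")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  for (f in frames) {
    fr <- traj$coords[, , f, drop = TRUE]
    for (i in ref_selection) {
      tg <- setdiff(target_selection, i)
      d <- min_image(fr[tg, , drop = FALSE] -
                     matrix(fr[i, ], length(tg), 3, byrow = TRUE), L)
      dist <- sqrt(rowSums(d * d))
      dist <- dist[dist < r_max]
      if (length(dist))
        counts <- counts + tabulate(findInterval(dist, breaks,
                                                 left.open = TRUE), nb)
    }
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  widths <- diff(breaks)
  rho <- length(target_selection) / L^3
  shell <- 4 * pi * centers^2 * widths
  norm <- length(frames) * length(ref_selection) * shell * rho
  obj <- list(r = centers, g = counts / norm, dr = dr, counts = counts,
              n_frames = length(frames), rho = rho)
  class(obj) <- "sbx_rdf"
  obj
}

#' @export
print.sbx_rdf <- function(x, ...) {
  cat("<sbx_rdf> ", length(x$r), " bins, dr = ", x$dr, " A, ",
      x$n_frames, " frame(s)\n", sep = "")
  invisible(x)
}

#' First local maxima of a g(r) (or density) profile
#'
#' A bin is a local maximum when its value exceeds both neighbours and a
#' noise floor. Used to read off hydration-shell radii.
#'
#' @param profile an `sbx_rdf` or `sbx_density_profile`.
#' @param n_peaks how many leading maxima to return.
#' @param min_height ignore maxima below this value (default 1: above the
#'   bulk level).
#' @return numeric vector of bin-center positions (Angstrom).
#' @export
profile_peaks <- function(profile, n_peaks = 2L, min_height = 1) {
  y <- if (!is.null(profile$g)) profile$g else profile$ratio
  r <- profile$r
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > min_height
  r[which(is_max)][seq_len(min(n_peaks, sum(is_max)))]
}

# Effective solute radius: radius of the sphere about the centre of
# geometry containing `coverage` of the solute atoms.
effective_radius <- function(coords, coverage = 0.99) {
  center <- colMeans(coords)
  d <- sqrt(rowSums(sweep(coords, 2, center)^2))
  unname(stats::quantile(d, coverage, names = FALSE))
}

#' Solvent density profile around a solute
#'
#' For each water, the distance to the solute centre of geometry minus the
#' effective solute radius R; densities are binned in shells of width `dr`
#' at radius `R + r` and normalized by the bulk density measured in the
#' outermost 10% of valid distances (valid means `R + r <= L/2`). If no
#' bulk region exists the profile is returned unnormalized with a warning.
#'
#' @param traj an [trajectory()].
#' @param solute_selection indices of solute atoms (non-empty).
#' @param water_selection indices of water oxygens.
#' @param dr bin width, Angstrom (default 0.5 for protein-scale profiles).
#' @param R effective solute radius override, Angstrom; default the
#'   99%-coverage radius of the solute selection.
#' @param frames frame indices to average (default all).
#' @return object of class `sbx_density_profile`: `r` (distance from the
#'   solute surface, bin centers), `ratio` (rho(r)/rho_bulk), `R`,
#'   `rho_bulk`, `normalized`.
#' @export
density_profile <- function(traj, solute_selection, water_selection,
                            dr = 0.5, R = NULL, frames = NULL) {
  stopifnot(inherits(traj, "sbx_trajectory"), dr > 0)
  if (!length(solute_selection)) stop("solute selection is empty")
  if (!length(water_selection)) stop("water selection is empty")
  L <- traj$box
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  fr1 <- traj$coords[, , frames[1], drop = TRUE]
  sol <- fr1[solute_selection, , drop = FALSE]
  if (is.null(R)) R <- if (nrow(sol) > 1L) effective_radius(sol) else 0
  r_valid <- L / 2 - R
  if (r_valid <= dr)
    stop("box too small: no room for shells outside the solute radius")
  breaks <- seq(0, r_valid, by = dr)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  for (f in frames) {
    fr <- traj$coords[, , f, drop = TRUE]
    center <- colMeans(fr[solute_selection, , drop = FALSE])
    d <- min_image(fr[water_selection, , drop = FALSE] -
                   matrix(center, length(water_selection), 3, byrow = TRUE),
                   L)
    rr <- sqrt(rowSums(d * d)) - R
    rr <- rr[rr >= 0 & rr < breaks[nb + 1L]]
    if (length(rr))
      counts <- counts + tabulate(findInterval(rr, breaks,
                                               left.open = TRUE), nb)
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell <- 4 * pi * (R + centers)^2 * dr
  dens <- counts / (length(frames) * shell)
  bulk_bins <- which(centers >= 0.9 * r_valid)
  normalized <- length(bulk_bins) >= 1L && any(dens[bulk_bins] > 0)
  if (normalized) {
    rho_bulk <- mean(dens[bulk_bins])
    ratio <- dens / rho_bulk
  } else {
    warning("no bulk region available; returning unnormalized density")
    rho_bulk <- NA_real_
    ratio <- dens
  }
  obj <- list(r = centers, ratio = ratio, R = R, rho_bulk = rho_bulk,
              normalized = normalized, dr = dr)
  class(obj) <- "sbx_density_profile"
  obj
}

#' Count water oxygens inside a geometric region
#'
#' Regions are spheres (`center`, `radius`) or cylinders (`center`, unit
#' `axis`, `radius`, `half_height`); membership uses minimum-image
#' displacements from the region centre, so the count is invariant under
#' rigid translation of the whole frame.
#'
#' @param frame `N x 3` coordinate matrix (Angstrom).
#' @param region list: `list(type="sphere", center=, radius=)` or
#'   `list(type="cylinder", center=, axis=, radius=, half_height=)`.
#' @param L cubic box edge, Angstrom.
#' @param water_selection row indices to consider (default all rows).
#' @return integer count.
#' @export
count_waters_in_region <- function(frame, region, L,
                                   water_selection = NULL) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L, L > 0)
  if (is.null(water_selection)) water_selection <- seq_len(nrow(frame))
  if (is.null(region$type) || !region$type %in% c("sphere", "cylinder"))
    stop("region$type must be 'sphere' or 'cylinder'")
  if (!is.finite(region$radius) || region$radius <= 0)
    stop("region radius must be positive (zero-volume region)")
  d <- min_image(frame[water_selection, , drop = FALSE] -
                 matrix(region$center, length(water_selection), 3,
                        byrow = TRUE), L)
  if (region$type == "sphere") {
    sum(rowSums(d * d) <= region$radius^2)
  } else {
    if (!is.finite(region$half_height) || region$half_height <= 0)
      stop("cylinder half_height must be positive (zero-volume region)")
    a <- region$axis / sqrt(sum(region$axis^2))
    z <- as.numeric(d %*% a)
    rad2 <- rowSums(d * d) - z^2
    sum(abs(z) <= region$half_height & rad2 <= region$radius^2)
  }
}

#' Distribution of per-frame water counts in a region
#'
#' @param traj an [trajectory()] (>= 2 frames).
#' @param region as in [count_waters_in_region()].
#' @param water_selection row indices to consider (default all).
#' @return list: `counts` (per frame), `values`/`prob` (normalized
#'   histogram, sums to 1), `mean`, `sd`.
#' @export
water_count_distribution <- function(traj, region, water_selection = NULL) {
  stopifnot(inherits(traj, "sbx_trajectory"))
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  counts <- vapply(seq_len(n_frames(traj)), function(f)
    count_waters_in_region(traj$coords[, , f, drop = TRUE], region,
                           traj$box, water_selection), integer(1))
  tab <- table(counts)
  list(counts = counts,
       values = as.integer(names(tab)),
       prob = as.numeric(tab) / length(counts),
       mean = mean(counts), sd = stats::sd(counts))
}
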