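# Seeded synthetic-trajectory generators. Each generator records its ground
# truth (true D, planted counts, change points, shell radii, seed) in the
# returned object's metadata so downstream tests never re-derive it from the
# fixture itself. Generators are statistical stand-ins, not water models:
# there are no intermolecular forces, no hydrogens, no thermostat.

#' Generate Brownian "water": independent Gaussian random walks in a box
#'
#' Each of the N particles performs an independent, isotropic Gaussian
#' random walk with per-step, per-dimension displacement variance
#' `2 * D * dt` (D converted from cm^2/s to A^2/ps), the discrete-time
#' process whose mean-squared displacement is exactly `6 D t`. Positions are
#' stored unwrapped (continuous), as required by MSD estimation; analyses
#' that need in-box positions wrap on the fly.
#'
#' @param N number of particles.
#' @param L cubic box edge, Angstrom.
#' @param D self-diffusion coefficient, cm^2/s (>= 0). `D = 0` gives a
#'   static trajectory.
#' @param dt frame spacing, ps.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed (always explicit).
#' @return an [trajectory()] with `metadata$D_true`, `$seed`.
#' @examples
#' tr <- gen_brownian_water(N = 50, L = 30, D = 5.95e-5, dt = 1,
#'                          n_frames = 100, seed = 1)
#' @export
gen_brownian_water <- function(N, L, D, dt, n_frames, seed) {
  stopifnot(N >= 1, L > 0, dt > 0, n_frames >= 1)
  if (!is.finite(D) || D < 0) stop("D must be a finite non-negative cm^2/s value")
  var_step <- 2 * cm2s_to_A2ps(D) * dt  # A^2 per step per dimension
  if (!is.finite(var_step)) stop("per-step variance overflow: check D and dt")
  set.seed(seed)
  x0 <- matrix(stats::runif(N * 3, 0, L), ncol = 3)
  coords <- array(0, dim = c(N, 3L, n_frames))
  coords[, , 1] <- x0
  if (n_frames > 1L) {
    sd_step <- sqrt(var_step)
    for (t in 2:n_frames)
      coords[, , t] <- coords[, , t - 1] +
        matrix(stats::rnorm(N * 3, sd = sd_step), ncol = 3)
  }
  atoms <- data.frame(name = "OW", element = "O", resname = "HOH",
                      resno = seq_len(N), chain = "W",
                      stringsAsFactors = FALSE)
  trajectory(coords, box = L, dt = dt, atoms = atoms, unwrapped = TRUE,
             metadata = list(kind = "brownian_water", D_true = D,
                             seed = seed, step_var = var_step))
}

#' Generate a single uniform (ideal-gas) configuration
#'
#' N points uniform in the cubic box; the g(r) of this configuration is flat
#' (== 1) up to sampling noise, which makes it the normalization oracle for
#' radial distribution functions.
#'
#' @inheritParams gen_brownian_water
#' @return a one-frame [trajectory()].
#' @export
gen_ideal_gas <- function(N, L, seed) {
  stopifnot(N >= 2, L > 0)
  set.seed(seed)
  coords <- array(stats::runif(N * 3, 0, L), dim = c(N, 3L, 1L))
  atoms <- data.frame(name = "OW", element = "O", resname = "HOH",
                      resno = seq_len(N), chain = "W",
                      stringsAsFactors = FALSE)
  trajectory(coords, box = L, dt = 1, atoms = atoms, unwrapped = FALSE,
             metadata = list(kind = "ideal_gas", seed = seed))
}

#' Generate a periodic simple-cubic lattice of oxygen sites
#'
#' `n_side^3` sites with box edge `n_side * spacing`, so under periodicity
#' every site has exactly 6 nearest neighbours at distance `spacing` (and
#' the next shell at `spacing * sqrt(2)`). This gives hydrogen-bond counting
#' an exactly known answer: with a cutoff at or above the spacing, 6 bonds
#' per molecule when both partners are credited, 3 pairs per molecule when
#' pairs are counted once.
#'
#' @param n_side sites per edge (>= 2).
#' @param spacing lattice constant, Angstrom.
#' @return a one-frame [trajectory()] with
#'   `metadata$neighbours_per_site = 6`.
#' @export
gen_hbond_lattice <- function(n_side, spacing) {
  stopifnot(n_side >= 2, spacing > 0)
  g <- (seq_len(n_side) - 1L) * spacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  coords <- array(pts, dim = c(nrow(pts), 3L, 1L))
  atoms <- data.frame(name = "OW", element = "O", resname = "HOH",
                      resno = seq_len(nrow(pts)), chain = "W",
                      stringsAsFactors = FALSE)
  trajectory(coords, box = n_side * spacing, dt = 1, atoms = atoms,
             unwrapped = FALSE,
             metadata = list(kind = "hbond_lattice", spacing = spacing,
                             neighbours_per_site = 6L))
}

#' Generate layered hydration shells around a spherical solute
#'
#' Particle 1 is the solute reference site at the box center; exactly
#' `shell_counts[i]` waters are placed uniformly on the sphere of radius
#' `shell_radii[i]`, plus `bulk_N` waters uniform in the box but excluded
#' from a sphere of radius `max(shell_radii) + 1` Angstrom. The known shell
#' radii are the g(r) peak-position ground truth.
#'
#' @param R solute radius, Angstrom (shells must lie outside it).
#' @param shell_radii increasing radii of the hydration shells, Angstrom.
#' @param shell_counts waters per shell (same length).
#' @param bulk_N uniform background waters.
#' @param L cubic box edge, Angstrom.
#' @param seed RNG seed.
#' @return a one-frame [trajectory()]; `metadata$solute_index = 1`,
#'   `$shell_radii`, `$shell_counts`, `$center`.
#' @export
gen_layered_solute <- function(R, shell_radii, shell_counts, bulk_N, L, seed) {
  stopifnot(L > 0, R >= 0, length(shell_radii) == length(shell_counts))
  if (length(shell_radii)) {
    if (is.unsorted(shell_radii, strictly = TRUE))
      stop("shell_radii must be strictly increasing")
    if (any(shell_radii <= R))
      stop("hydration shell at r <= solute radius R overlaps the solute")
  }
  set.seed(seed)
  center <- rep(L / 2, 3)
  pts <- list(matrix(center, nrow = 1))
  for (i in seq_along(shell_radii)) {
    v <- matrix(stats::rnorm(shell_counts[i] * 3), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts[[length(pts) + 1L]] <-
      sweep(v * shell_radii[i], 2, center, `+`)
  }
  if (bulk_N > 0) {
    excl <- if (length(shell_radii)) max(shell_radii) + 1 else R
    got <- matrix(numeric(0), ncol = 3)
    while (nrow(got) < bulk_N) {
      cand <- matrix(stats::runif(2 * bulk_N * 3, 0, L), ncol = 3)
      d <- sqrt(rowSums(min_image(sweep(cand, 2, center), L)^2))
      got <- rbind(got, cand[d > excl, , drop = FALSE])
    }
    pts[[length(pts) + 1L]] <- got[seq_len(bulk_N), , drop = FALSE]
  }
  m <- do.call(rbind, pts)
  n <- nrow(m)
  atoms <- data.frame(
    name = c("SOL", rep("OW", n - 1L)),
    element = c("C", rep("O", n - 1L)),
    resname = c("SLT", rep("HOH", n - 1L)),
    resno = seq_len(n), chain = c("S", rep("W", n - 1L)),
    stringsAsFactors = FALSE)
  trajectory(array(m, dim = c(n, 3L, 1L)), box = L, dt = 1, atoms = atoms,
             unwrapped = FALSE,
             metadata = list(kind = "layered_solute", solute_index = 1L,
                             center = center, R = R,
                             shell_radii = shell_radii,
                             shell_counts = shell_counts,
                             bulk_N = bulk_N, seed = seed))
}

#' Generate a piecewise-constant trace with planted transitions
#'
#' Emulates a structural distance time series that jumps between plateaus at
#' known change points, with i.i.d. Gaussian noise. (Real traces are
#' autocorrelated; i.i.d. noise is the minimal testable choice.)
#'
#' @param change_points_ns strictly increasing change-point times, inside
#'   `(0, T_ns)`.
#' @param levels plateau means, length `length(change_points_ns) + 1`.
#' @param sigma noise standard deviation (same unit as `levels`).
#' @param dt_ns sampling interval, ns.
#' @param T_ns total duration, ns.
#' @param seed RNG seed.
#' @return an [timeseries()] (times in ns) with the planted truth in
#'   `metadata$change_points_ns`, `$levels`, `$sigma`.
#' @export
gen_transition_trace <- function(change_points_ns, levels, sigma, dt_ns,
                                 T_ns, seed) {
  stopifnot(dt_ns > 0, T_ns > 0, sigma >= 0)
  if (length(levels) != length(change_points_ns) + 1L)
    stop("need length(levels) == length(change_points_ns) + 1")
  if (length(change_points_ns)) {
    if (is.unsorted(change_points_ns, strictly = TRUE))
      stop("change points must be strictly increasing")
    if (any(change_points_ns <= 0 | change_points_ns >= T_ns))
      stop("change points must lie strictly inside (0, T)")
  }
  set.seed(seed)
  times <- seq(dt_ns, T_ns, by = dt_ns)
  seg <- findInterval(times, change_points_ns) + 1L
  vals <- levels[seg] + stats::rnorm(length(times), sd = sigma)
  timeseries(times, vals, label = "planted transition trace", unit = "A",
             metadata = list(kind = "transition_trace",
                             change_points_ns = change_points_ns,
                             levels = levels, sigma = sigma, seed = seed))
}
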