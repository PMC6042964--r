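# Self-diffusion from the mean-squared displacement, Einstein relation
# D = lim slope(MSD)/6, plus the Yeh-Hummer hydrodynamic finite-size
# correction for periodic cubic boxes.

#' Mean-squared displacement of selected particles
#'
#' `MSD(tau)` is averaged over all selected particles and over all time
#' origins `t0` (thinned by `origin_stride`):
#' `MSD(tau) = < |r(t0 + tau) - r(t0)|^2 >`. Requires unwrapped
#' (continuous) coordinates; wrapped trajectories are refused because box
#' jumps corrupt displacements.
#'
#' @param traj an unwrapped [trajectory()].
#' @param selection integer atom indices (default: all atoms).
#' @param max_lag largest lag, in ps (< trajectory length); default half
#'   the trajectory.
#' @param origin_stride use every `origin_stride`-th frame as a time origin
#'   (1 = all origins).
#' @return object of class `sbx_msd`: `lag` (ps, starting at 0),
#'   `msd` (A^2, `msd[1] == 0`), `n_samples` (particle x origin samples per
#'   lag, non-increasing).
#' @export
compute_msd <- function(traj, selection = NULL, max_lag = NULL,
                        origin_stride = 1L) {
  stopifnot(inherits(traj, "sbx_trajectory"))
  if (!traj$unwrapped)
    stop("trajectory coordinates are wrapped; MSD needs continuous ",
         "(unwrapped) coordinates - regenerate or unwrap first")
  nf <- n_frames(traj)
  dt <- traj$dt
  if (is.null(max_lag)) max_lag <- floor(nf / 2) * dt
  max_lag_frames <- floor(max_lag / dt)
  if (max_lag_frames < 1L || max_lag_frames >= nf)
    stop("max_lag must be at least one frame and below the trajectory length")
  co <- if (is.null(selection)) traj$coords else
    traj$coords[selection, , , drop = FALSE]
  n_sel <- dim(co)[1]
  msd <- numeric(max_lag_frames + 1L)
  nsamp <- integer(max_lag_frames + 1L)
  nsamp[1] <- n_sel * length(seq(1L, nf, by = origin_stride))
  for (lag in seq_len(max_lag_frames)) {
    orig <- seq(1L, nf - lag, by = origin_stride)
    d <- co[, , orig + lag, drop = FALSE] - co[, , orig, drop = FALSE]
    msd[lag + 1L] <- sum(d * d) / (n_sel * length(orig))
    nsamp[lag + 1L] <- n_sel * length(orig)
  }
  obj <- list(lag = (0:max_lag_frames) * dt, msd = msd, n_samples = nsamp,
              dt = dt, L = traj$box)
  class(obj) <- "sbx_msd"
  obj
}

#' @export
print.sbx_msd <- function(x, ...) {
  cat("<sbx_msd> ", length(x$lag), " lags, 0 .. ",
      x$lag[length(x$lag)], " ps\n", sep = "")
  invisible(x)
}

#' Fit the diffusion coefficient from an MSD curve
#'
#' Least-squares slope of MSD vs lag over `[t_min, t_max]`, divided by 6 and
#' converted to cm^2/s. The error bar is the absolute difference between the
#' diffusion coefficients fitted separately on the two halves of the fit
#' interval. The default window is the central 10-50% of the available
#' lags, away from the short-lag and poorly-sampled long-lag ends.
#'
#' @param msd an `sbx_msd` from [compute_msd()].
#' @param t_min,t_max fit window in ps; defaults 10% and 50% of the largest
#'   lag. Each half of the window must contain at least 4 points.
#' @param L box edge (A) recorded in the estimate, for later finite-size
#'   correction; defaults to the MSD's own.
#' @return object of class `sbx_diffusion`: `D_pbc` and `error` (cm^2/s),
#'   `fit_interval` (ps), `L` (A), `D0` (NA until corrected),
#'   `xi` (correction constant, NA until corrected).
#' @export
fit_diffusion <- function(msd, t_min = NULL, t_max = NULL, L = msd$L) {
  stopifnot(inherits(msd, "sbx_msd"))
  tmaxlag <- msd$lag[length(msd$lag)]
  if (is.null(t_min)) t_min <- 0.1 * tmaxlag
  if (is.null(t_max)) t_max <- 0.5 * tmaxlag
  if (!(t_min < t_max && t_max <= tmaxlag))
    stop("fit window must satisfy t_min < t_max <= max lag")
  in_win <- which(msd$lag >= t_min & msd$lag <= t_max)
  if (length(in_win) < 8L)
    stop("fit window holds ", length(in_win),
         " points; need at least 4 per half")
  slope_of <- function(idx) {
    x <- msd$lag[idx]; y <- msd$msd[idx]
    stats::cov(x, y) / stats::var(x)
  }
  D <- A2ps_to_cm2s(slope_of(in_win) / 6)
  half <- length(in_win) %/% 2L
  D1 <- A2ps_to_cm2s(slope_of(in_win[seq_len(half)]) / 6)
  D2 <- A2ps_to_cm2s(slope_of(in_win[(half + 1L):length(in_win)]) / 6)
  obj <- list(D_pbc = D, error = abs(D1 - D2),
              fit_interval = c(t_min, t_max), L = L,
              D0 = NA_real_, xi = NA_real_)
  class(obj) <- "sbx_diffusion"
  obj
}

#' @export
print.sbx_diffusion <- function(x, ...) {
  cat(sprintf("<sbx_diffusion> D_pbc = %.4g +- %.2g cm^2/s (fit %g-%g ps, L = %g A)\n",
              x$D_pbc, x$error, x$fit_interval[1], x$fit_interval[2], x$L))
  if (!is.na(x$D0)) cat(sprintf("  D0 (corrected) = %.4g cm^2/s\n", x$D0))
  invisible(x)
}

#' Yeh-Hummer finite-size correction for periodic cubic boxes
#'
#' Under periodic boundary conditions the measured self-diffusion
#' coefficient is depressed by hydrodynamic self-interaction with the
#' periodic images; the infinite-system value is
#' `D0 = D_pbc + kB*T*xi / (6*pi*eta*L)` with `xi = 2.837297` (the cubic
#' lattice Ewald constant). The term is proportional to `1/L`, equivalently
#' `N^(-1/3)` at fixed density.
#'
#' @param D_pbc measured coefficient, cm^2/s (an `sbx_diffusion` is also
#'   accepted).
#' @param L box edge, Angstrom.
#' @param temperature K (default 298).
#' @param viscosity shear viscosity, Pa s; default 3.21e-4 (TIP3P water at
#'   298 K).
#' @return the corrected `D0` in cm^2/s; if `D_pbc` was an `sbx_diffusion`,
#'   the estimate with `D0` and `xi` filled in.
#' @export
finite_size_correct <- function(D_pbc, L, temperature = 298,
                                viscosity = 3.21e-4) {
  est <- NULL
  if (inherits(D_pbc, "sbx_diffusion")) {
    est <- D_pbc
    if (missing(L)) L <- est$L
    D_pbc <- est$D_pbc
  }
  stopifnot(L > 0, temperature > 0)
  if (!is.finite(viscosity) || viscosity <= 0)
    stop("viscosity must be positive (Pa s)")
  xi <- 2.837297
  corr_m2s <- .kB * temperature * xi / (6 * pi * viscosity * (L * 1e-10))
  D0 <- D_pbc + corr_m2s * 1e4  # m^2/s -> cm^2/s
  if (is.null(est)) return(D0)
  est$D0 <- D0
  est$xi <- xi
  est
}

#' Fit the box-size scaling of the diffusion coefficient
#'
#' Least-squares line of `D_pbc` versus `1/L`; the intercept is the
#' infinite-box extrapolation, the (negative) slope measures the
#' finite-size depression.
#'
#' @param L box edges, Angstrom (>= 2 distinct values).
#' @param D_pbc matching measured coefficients, cm^2/s.
#' @return list with `intercept` (D at 1/L = 0, cm^2/s), `slope`
#'   (cm^2/s * A), `fitted` values.
#' @export
scaling_fit <- function(L, D_pbc) {
  stopifnot(length(L) == length(D_pbc))
  if (length(unique(L)) < 2L)
    stop("need at least two distinct box sizes")
  invL <- 1 / L
  fit <- stats::lm(D_pbc ~ invL)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       fitted = unname(stats::fitted(fit)))
}

#' Extrapolate the first-transition time from its linear dependence on D
#'
#' The lifetime of the starting quaternary state grows linearly with the
#' water diffusion coefficient across box sizes; fitting `t_first ~ D` and
#' evaluating at a query D predicts when the first transition would occur.
#'
#' @param D measured water diffusion coefficients, cm^2/s (>= 2 distinct).
#' @param t_first matching first-transition times, ns.
#' @param D_query coefficient(s) at which to predict.
#' @return list with `t_predicted` (ns), `slope`, `intercept`, `residuals`.
#' @export
extrapolate_transition_time <- function(D, t_first, D_query) {
  stopifnot(length(D) == length(t_first), length(D) >= 2L)
  if (length(unique(D)) < 2L)
    stop("all D values are equal; the line is undetermined")
  fit <- stats::lm(t_first ~ D)
  list(t_predicted = unname(stats::predict(fit,
                                           newdata = data.frame(D = D_query))),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = unname(stats::residuals(fit)))
}
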