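test_that("ideal-gas g(r) is flat at 1 within sampling noise", {
  L <- 24
  g <- gen_ideal_gas(600, L, seed = 19)
  rdf <- radial_distribution(g, ref_selection = 1:600,
                             target_selection = 1:600,
                             r_max = L / 2, dr = 0.25)
  keep <- rdf$r >= 2 & rdf$r <= L / 4
  # per-bin tolerance 3/sqrt(samples in bin)
  tol <- 3 / sqrt(pmax(rdf$counts[keep], 1))
  expect_true(all(abs(rdf$g[keep] - 1) <= tol + 0.02))
  # integral of g rho 4 pi r^2 dr over (0, L/2] ~ expected neighbour count
  shell <- 4 * pi * rdf$r^2 * rdf$dr
  n_expected_tot <- sum(rdf$g * rdf$rho * shell)
  n_ideal <- 4 / 3 * pi * (L / 2)^3 * (600 - 1) / L^3
  expect_lt(abs(n_expected_tot / n_ideal - 1), 0.05)
})

test_that("planted hydration shells are recovered as the first two g(r) maxima", {
  fx <- gen_layered_solute(R = 1, shell_radii = c(2.7, 4.1),
                           shell_counts = c(200, 200), bulk_N = 500,
                           L = 50, seed = 3)
  rdf <- radial_distribution(fx, ref_selection = 1L,
                             target_selection = 2:n_atoms(fx),
                             r_max = 12, dr = 0.1)
  pk <- profile_peaks(rdf, n_peaks = 2)
  expect_equal(length(pk), 2L)
  expect_lt(abs(pk[1] - 2.7), 0.1 + 1e-9)  # within one bin
  expect_lt(abs(pk[2] - 4.1), 0.1 + 1e-9)
})

test_that("empty selections and invalid ranges are errors, not silent zeros", {
  g <- gen_ideal_gas(50, 20, seed = 1)
  expect_error(radial_distribution(g, integer(0), 1:50, r_max = 5), "empty")
  expect_error(radial_distribution(g, 1L, integer(0), r_max = 5), "empty")
  expect_error(radial_distribution(g, 1L, 1:50, r_max = 11), "L/2")
})

test_that("density profile: flat for a pointlike solute in ideal gas, depleted first shell detected", {
  # average several independent uniform frames to tame shell-count noise
  frames <- lapply(1:10, function(s)
    frame_coords(gen_ideal_gas(2000, 30, seed = 230 + s)))
  g <- trajectory(frames, box = 30, dt = 1)
  prof <- density_profile(g, solute_selection = 1L,
                          water_selection = 2:2000, dr = 1)
  keep <- prof$r >= 2
  expect_true(all(abs(prof$ratio[keep] - 1) < 0.35))
  expect_true(prof$normalized)

  # layered fixture with an empty region just outside the solute
  # (shell at 6.3 A sits mid-bin, away from any bin boundary)
  fx <- gen_layered_solute(R = 2, shell_radii = 6.3, shell_counts = 150,
                           bulk_N = 1200, L = 40, seed = 29)
  prof <- density_profile(fx, solute_selection = 1L,
                          water_selection = 2:n_atoms(fx), dr = 1, R = 2)
  expect_lt(prof$ratio[1], 0.5)          # depleted near the solute
  far <- prof$r > 0.8 * max(prof$r)
  expect_lt(abs(mean(prof$ratio[far]) - 1), 0.35)
  # the shell spike integrates back to the planted count exactly
  # (ratio * rho_bulk * shell volume undoes the normalization)
  shell_bin <- which.max(prof$ratio)
  vol <- 4 * pi * (2 + prof$r[shell_bin])^2 * 1
  expect_equal(prof$ratio[shell_bin] * prof$rho_bulk * vol, 150,
               tolerance = 1e-9)
})

test_that("region water counts are exact, conserved over a partition, and translation invariant", {
  fx <- gen_layered_solute(R = 1, shell_radii = c(3, 5),
                           shell_counts = c(40, 60), bulk_N = 200, L = 30,
                           seed = 31)
  fr <- frame_coords(fx)
  waters <- 2:n_atoms(fx)
  center <- fx$metadata$center
  # exact planted counts in nested spheres
  expect_equal(count_waters_in_region(fr, list(type = "sphere",
               center = center, radius = 4), fx$box, waters), 40L)
  expect_equal(count_waters_in_region(fr, list(type = "sphere",
               center = center, radius = 5.5), fx$box, waters), 100L)
  # a partition of the box conserves the total: sphere + complement
  r_in <- 7
  n_in <- count_waters_in_region(fr, list(type = "sphere", center = center,
                                          radius = r_in), fx$box, waters)
  d <- sqrt(rowSums(solvbox:::min_image(
    sweep(fr[waters, ], 2, center), fx$box)^2))
  expect_equal(n_in + sum(d > r_in), length(waters))
  # rigid translation (with wrap) leaves counts unchanged
  shift <- c(11.3, -4.2, 7.9)
  fr2 <- solvbox:::wrap_box(sweep(fr, 2, shift, `+`), fx$box)
  expect_equal(count_waters_in_region(fr2, list(type = "sphere",
               center = center + shift, radius = r_in), fx$box, waters),
               n_in)
})

test_that("planted cylinder occupancy of ~150 waters is counted exactly", {
  # 150 waters inside a cylinder of radius 8.5, none near the boundary
  set.seed(37)
  L <- 60
  axis <- c(0, 0, 1)
  center <- rep(L / 2, 3)
  n_in <- 150; n_out <- 100
  rad_in <- sqrt(runif(n_in)) * 7.0   # strictly inside radius 8.5
  th <- runif(n_in, 0, 2 * pi)
  z_in <- runif(n_in, -9, 9)
  inside <- cbind(center[1] + rad_in * cos(th),
                  center[2] + rad_in * sin(th), center[3] + z_in)
  rad_out <- 10 + runif(n_out) * 5    # strictly outside
  th2 <- runif(n_out, 0, 2 * pi)
  outside <- cbind(center[1] + rad_out * cos(th2),
                   center[2] + rad_out * sin(th2),
                   center[3] + runif(n_out, -9, 9))
  fr <- rbind(inside, outside)
  region <- list(type = "cylinder", center = center, axis = axis,
                 radius = 8.5, half_height = 10)
  expect_equal(count_waters_in_region(fr, region, L), 150L)
  empty <- list(type = "sphere", center = c(5, 5, 5), radius = 1)
  expect_equal(count_waters_in_region(fr, empty, L), 0L)
  expect_error(count_waters_in_region(fr, list(type = "sphere",
               center = center, radius = 0), L), "zero-volume")
})

test_that("per-frame count distributions normalize and show Poisson statistics", {
  # constant count: point mass
  lat <- gen_hbond_lattice(3, 3)
  co <- array(lat$coords[, , c(1, 1, 1, 1)], dim = c(27, 3, 4))
  tr4 <- trajectory(co, box = lat$box, dt = 1)
  region <- list(type = "sphere", center = rep(lat$box / 2, 3), radius = 4)
  dist <- water_count_distribution(tr4, region)
  expect_equal(sum(dist$prob), 1)
  expect_length(dist$values, 1L)
  expect_equal(dist$sd, 0)

  # Poisson-planted occupancy: mean ~ variance
  set.seed(41)
  L <- 30; nf <- 300; lambda <- 12
  region <- list(type = "sphere", center = rep(L / 2, 3), radius = 6)
  frames <- lapply(seq_len(nf), function(f) {
    k <- rpois(1, lambda)
    v <- matrix(rnorm(3 * max(k, 1)), ncol = 3)
    v <- v / sqrt(rowSums(v^2)) * (runif(max(k, 1))^(1/3) * 5.9)
    pts <- sweep(v[seq_len(max(k, 1)), , drop = FALSE], 2, rep(L / 2, 3), `+`)
    if (k == 0) pts <- matrix(c(1, 1, 1), 1, 3)  # keep frame non-empty
    rbind(pts, matrix(runif(60, 20, 29), 20, 3))  # padding far away
  })
  nmax <- max(vapply(frames, nrow, integer(1)))
  co <- array(0, dim = c(nmax, 3, nf))
  for (f in seq_len(nf)) {
    m <- frames[[f]]
    co[, , f] <- rbind(m, matrix(28, nmax - nrow(m), 3))
  }
  tr <- trajectory(co, box = L, dt = 1)
  dist <- water_count_distribution(tr, region)
  expect_equal(sum(dist$prob), 1)
  expect_lt(abs(dist$mean - lambda), 3 * sqrt(lambda / nf) + 0.5)
  expect_lt(abs(dist$sd^2 / dist$mean - 1), 0.35)
})
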