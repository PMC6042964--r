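test_that("Kabsch superposition: identity, transform round-trip, symmetry", {
  set.seed(1)
  A <- matrix(rnorm(24, sd = 5), 8, 3)
  s <- kabsch_rmsd(A, A)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)

  # B = rigid transform of A: RMSD 0 and the recovered transform inverts it
  R <- random_rotation(seed = 2)
  tvec <- c(4, -2, 7)
  B <- A %*% t(R) + matrix(tvec, 8, 3, byrow = TRUE)
  s <- kabsch_rmsd(A, B)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_equal(s$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(s$B_aligned, A, tolerance = 1e-8)

  # symmetry: rmsd(A, B) == rmsd(B, A) for non-superposable sets
  set.seed(3)
  B2 <- A + matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_rmsd(A, B2)$rmsd, kabsch_rmsd(B2, A)$rmsd,
               tolerance = 1e-10)
  # rigid transforms of either input leave the RMSD unchanged
  expect_equal(kabsch_rmsd(A %*% t(R), B2)$rmsd, kabsch_rmsd(A, B2)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_rmsd(A[1:2, ], B2[1:2, ]), "3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_rmsd(line, line + 1), "degenerate")
})

test_that("Kabsch equals the quaternion-eigenvector oracle on small sets", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- A %*% t(random_rotation(seed + 100)) +
      matrix(rnorm(3 * n, sd = 0.5), n, 3)
    expect_equal(kabsch_rmsd(A, B)$rmsd, oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-8, info = paste("seed", seed))
  }
})

test_that("Kabsch agrees with bio3d's superposition on a random pair", {
  set.seed(9)
  A <- matrix(rnorm(60, sd = 8), 20, 3)
  B <- A %*% t(random_rotation(10)) + matrix(rnorm(60, sd = 1), 20, 3)
  ours <- kabsch_rmsd(A, B)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("structure pairing uses the (chain, resno) intersection of CA atoms", {
  set.seed(12)
  xyz <- matrix(rnorm(30, sd = 6), 10, 3)
  sA <- toy_structure(xyz)
  R <- random_rotation(13)
  sB <- toy_structure(rbind(xyz[2:10, ] %*% t(R) + 3,
                            matrix(c(99, 99, 99), 1, 3)))
  # sB's residues 1..9 pair with sA's 2..10 is NOT the intersection rule:
  # pairing is by residue number, so only common resno pair up
  s <- kabsch_rmsd(sA, sB)
  expect_equal(s$n_atoms, 10L)  # resno 1..10 on both
  # with a true common subset the mismatched residue is dropped
  sB2 <- structure_model(within(sB$atoms, resno <- c(2:10, 42)), "shift")
  s2 <- kabsch_rmsd(sA, sB2)
  expect_equal(s2$n_atoms, 9L)
  expect_equal(s2$rmsd, 0, tolerance = 1e-8)
})

test_that("residue-pair distances resolve by (chain, resno, atom) and report offenders", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  s <- structure_model(data.frame(
    name = "CA", element = "C", resname = "HIS", resno = c(146, 146),
    chain = c("B", "D"), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    "two his")
  d <- residue_pair_distance(s,
                             list(chain = "B", resno = 146, atom = "CA"),
                             list(chain = "D", resno = 146, atom = "CA"))
  expect_equal(d, 5)
  same <- residue_pair_distance(s,
                                list(chain = "B", resno = 146, atom = "CA"),
                                list(chain = "B", resno = 146, atom = "CA"))
  expect_equal(same, 0)
  expect_error(
    residue_pair_distance(s, list(chain = "X", resno = 1, atom = "CA"),
                          list(chain = "B", resno = 146, atom = "CA")),
    "chain=X")
})

test_that("per-frame distances are Euclidean without minimum-image wrapping", {
  co <- array(0, dim = c(2, 3, 3))
  co[2, 1, ] <- c(3, 12, 30)  # drifts beyond L/2: must NOT wrap
  atoms <- data.frame(name = "CA", element = "C", resname = "HIS",
                      resno = 146, chain = c("B", "D"))
  tr <- trajectory(co, box = 20, dt = 1000, atoms = atoms)
  ts <- residue_pair_distance(tr,
                              list(chain = "B", resno = 146, atom = "CA"),
                              list(chain = "D", resno = 146, atom = "CA"))
  expect_equal(ts$values, c(3, 12, 30))
  expect_equal(ts$times, c(0, 1, 2))  # ps -> ns at the boundary
})

test_that("contact time series report planted bound fractions", {
  nf <- 10
  co <- array(0, dim = c(2, 3, nf))
  co[2, 1, ] <- c(rep(3, 4), rep(8, 6))  # bound 4/10 frames at cutoff 4
  atoms <- data.frame(name = c("NZ", "OXT"), element = c("N", "O"),
                      resname = c("LYS", "HIS"), resno = c(40, 146),
                      chain = c("C", "B"))
  tr <- trajectory(co, box = 50, dt = 1, atoms = atoms)
  pr <- list(list(a = list(chain = "C", resno = 40, atom = "NZ"),
                  b = list(chain = "B", resno = 146, atom = "OXT")))
  res <- contact_timeseries(tr, pr, cutoff = 4)
  expect_equal(res[[1]]$bound_fraction, 0.4)
  expect_equal(contact_timeseries(tr, pr, cutoff = 0)[[1]]$bound_fraction, 0)
  expect_equal(contact_timeseries(tr, pr, cutoff = 10)[[1]]$bound_fraction, 1)
})

test_that("change-point detection: constant series, exact noiseless step, planted noisy steps", {
  flat <- timeseries(1:100, rep(5, 100))
  expect_length(detect_transitions(flat)$indices, 0L)

  step <- gen_transition_trace(10, c(0, 1), sigma = 0, dt_ns = 0.5,
                               T_ns = 20, seed = 1)
  tr <- detect_transitions(step, penalty = 0.5, min_segment = 5L)
  expect_equal(tr$indices, 19L)  # last sample of the first plateau
  expect_equal(tr$segment_means, c(0, 1))

  # planted 140/530 ns transitions, 10-sigma separation: +-5 ns over 20 seeds
  for (s in 1:20) {
    trace <- gen_transition_trace(c(140, 530), c(30.9, 25.9, 20.9),
                                  sigma = 0.5, dt_ns = 0.5, T_ns = 1000,
                                  seed = 2000 + s)
    det <- detect_transitions(trace)
    expect_equal(length(det$indices), 2L, info = paste("seed", s))
    expect_lt(abs(det$times[1] - 140), 5)
    expect_lt(abs(det$times[2] - 530), 5)
    expect_true(all(diff(det$times) > 0))
  }
})

test_that("a transition spread over a ~10 ns ramp is localized within the ramp", {
  set.seed(77)
  dt <- 0.5
  times <- seq(dt, 1000, by = dt)
  ramp_lo <- 495; ramp_hi <- 505
  mu <- ifelse(times < ramp_lo, 30.9,
               ifelse(times > ramp_hi, 20.9,
                      30.9 - (times - ramp_lo)))
  trace <- timeseries(times, mu + rnorm(length(times), sd = 0.5))
  det <- detect_transitions(trace)
  expect_gte(length(det$indices), 1L)
  expect_true(any(det$times >= ramp_lo - 2 & det$times <= ramp_hi + 2))
})
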