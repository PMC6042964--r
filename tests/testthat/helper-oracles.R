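# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package
# internals they verify.

# Minimum-image distance by explicit minimum over all 27 image translations
# (inputs first reduced into the primary box, where +-1 images suffice).
oracle_min_image_27 <- function(p, q, L) {
  p <- p - L * floor(p / L)
  q <- q - L * floor(q / L)
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p - (q + L * c(ix, iy, iz))
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# MSD by a double loop over origins and particles.
oracle_msd_double_loop <- function(coords, max_lag_frames, dt) {
  nf <- dim(coords)[3]
  n <- dim(coords)[1]
  msd <- numeric(max_lag_frames + 1L)
  for (lag in seq_len(max_lag_frames)) {
    acc <- 0; cnt <- 0L
    for (t0 in seq_len(nf - lag)) {
      for (i in seq_len(n)) {
        d <- coords[i, , t0 + lag] - coords[i, , t0]
        acc <- acc + sum(d * d)
        cnt <- cnt + 1L
      }
    }
    msd[lag + 1L] <- acc / cnt
  }
  list(lag = (0:max_lag_frames) * dt, msd = msd)
}

# Least-squares slope straight from the normal equations.
oracle_ls_slope <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) / (sum(x^2) - n * mean(x)^2)
}

# All-pairs neighbour search under the minimum-image convention, via the
# 27-image oracle distance (quadratic, tiny fixtures only).
oracle_all_pairs <- function(pos, cutoff, L) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (oracle_min_image_27(pos[i, ], pos[j, ], L) <= cutoff)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Horn's quaternion method for the optimal RMSD superposition: the largest
# eigenvalue of the 4x4 key matrix gives the residual directly.
oracle_quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- crossprod(B0, A0)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(e2, 0))
}

# A tiny hand-built structure: n atoms on one chain, coordinates supplied.
toy_structure <- function(xyz, chain = "A", atom = "CA") {
  n <- nrow(xyz)
  structure_model(data.frame(
    name = atom, element = "C", resname = "ALA", resno = seq_len(n),
    chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), title = "toy")
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
           2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}
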