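# Structural observables that track the quaternary state: Kabsch
# superposition / RMSD against reference X-ray structures, residue-pair
# distance and salt-bridge contact time series, and change-point detection
# of the transitions those series exhibit.

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Least-squares proper rotation + translation of `coords_B` onto
#' `coords_A` via the SVD of the covariance matrix; reflections are
#' rejected by flipping the sign of the smallest singular direction.
#' When the inputs are `sbx_structure`s, atoms are paired as the
#' intersection of their (chain, residue number) keys restricted to
#' `pairing_atom` (default "CA"); mismatched residues are dropped and the
#' retained count reported.
#'
#' @param coords_A,coords_B `n x 3` matrices with paired rows (n >= 3,
#'   non-collinear), or two `sbx_structure`s.
#' @param pairing_atom atom name used to pair structures (default "CA").
#' @return object of class `sbx_superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3, applied after rotation), `rmsd` (A),
#'   `n_atoms` used, and `B_aligned` (B mapped onto A's frame).
#' @export
kabsch_rmsd <- function(coords_A, coords_B, pairing_atom = "CA") {
  if (inherits(coords_A, "sbx_structure")) {
    stopifnot(inherits(coords_B, "sbx_structure"))
    a <- coords_A$atoms[coords_A$atoms$name == pairing_atom, ]
    b <- coords_B$atoms[coords_B$atoms$name == pairing_atom, ]
    ka <- paste(a$chain, a$resno); kb <- paste(b$chain, b$resno)
    common <- intersect(ka, kb)
    coords_A <- as.matrix(a[match(common, ka), c("x", "y", "z")])
    coords_B <- as.matrix(b[match(common, kb), c("x", "y", "z")])
  }
  stopifnot(is.matrix(coords_A), is.matrix(coords_B),
            ncol(coords_A) == 3L, ncol(coords_B) == 3L,
            nrow(coords_A) == nrow(coords_B))
  n <- nrow(coords_A)
  if (n < 3L) stop("need at least 3 paired atoms")
  ca <- colMeans(coords_A); cb <- colMeans(coords_B)
  A0 <- sweep(coords_A, 2, ca); B0 <- sweep(coords_B, 2, cb)
  H <- crossprod(B0, A0)              # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear or coincident) geometry: rank < 2")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # maps centred B -> centred A
  Bal <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bal)^2)))
  obj <- list(rotation = R, translation = ca - as.numeric(R %*% cb),
              rmsd = rmsd, n_atoms = n,
              B_aligned = sweep(Bal, 2, ca, `+`))
  class(obj) <- "sbx_superposition"
  obj
}

#' @export
print.sbx_superposition <- function(x, ...) {
  cat(sprintf("<sbx_superposition> RMSD = %.3f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

# Resolve one (chain, resno, atom-name) key to a single atom index.
resolve_atom <- function(atoms, key) {
  idx <- which(atoms$chain == key$chain & atoms$resno == key$resno &
               atoms$name == key$atom)
  if (length(idx) != 1L)
    stop("selection (chain=", key$chain, ", resno=", key$resno,
         ", atom=", key$atom, ") resolves to ", length(idx),
         " atoms; need exactly 1")
  idx
}

#' Distance between two named atoms, per frame or in a structure
#'
#' Plain Euclidean distance, deliberately without minimum-image wrapping:
#' intra-protein pairs stay together when the protein's centre of mass is
#' kept in the box, and wrapping would fold genuine large-amplitude motion.
#'
#' @param x an `sbx_structure` (returns a scalar) or `sbx_trajectory` with
#'   atom metadata (returns an [timeseries()] in ns).
#' @param key_a,key_b lists `list(chain=, resno=, atom=)` identifying the
#'   two atoms, e.g. `list(chain="B", resno=146, atom="CA")`.
#' @return distance in Angstrom: scalar or `sbx_timeseries`.
#' @export
residue_pair_distance <- function(x, key_a, key_b) {
  atoms <- x$atoms
  if (is.null(atoms)) stop("object carries no atom metadata")
  ia <- resolve_atom(atoms, key_a); ib <- resolve_atom(atoms, key_b)
  if (inherits(x, "sbx_structure")) {
    pa <- as.numeric(atoms[ia, c("x", "y", "z")])
    pb <- as.numeric(atoms[ib, c("x", "y", "z")])
    return(sqrt(sum((pa - pb)^2)))
  }
  d <- x$coords[ia, , , drop = TRUE] - x$coords[ib, , , drop = TRUE]
  vals <- sqrt(colSums(d^2))
  timeseries((seq_len(n_frames(x)) - 1L) * x$dt / 1000, vals,
             label = sprintf("%s%s:%s - %s%s:%s", key_a$chain, key_a$resno,
                             key_a$atom, key_b$chain, key_b$resno,
                             key_b$atom),
             unit = "A")
}

#' Contact (salt-bridge) time series and bound fractions
#'
#' @param traj `sbx_trajectory` with atom metadata.
#' @param pairs list of `list(a = key, b = key)` atom-key pairs (keys as in
#'   [residue_pair_distance()]).
#' @param cutoff contact distance, Angstrom (> 0).
#' @return list per pair: `series` (`sbx_timeseries`, A) and
#'   `bound_fraction` (share of frames with distance <= cutoff).
#' @export
contact_timeseries <- function(traj, pairs, cutoff) {
  stopifnot(inherits(traj, "sbx_trajectory"), cutoff >= 0)
  lapply(pairs, function(p) {
    ts <- residue_pair_distance(traj, p$a, p$b)
    list(series = ts, bound_fraction = mean(ts$values <= cutoff))
  })
}

# Within-segment sum of squared deviations via prefix sums.
# s1/s2 are c(0, cumsum(x)) and c(0, cumsum(x^2)); segment is (a, b] 0-based.
seg_sse <- function(s1, s2, a, b) {
  n <- b - a
  (s2[b + 1L] - s2[a + 1L]) - (s1[b + 1L] - s1[a + 1L])^2 / n
}

#' Detect change points in a structural time series
#'
#' Penalized binary segmentation on the squared-error cost: the series is
#' recursively split at the point that maximally reduces the total
#' within-segment sum of squares, accepting a split only when the reduction
#' exceeds the penalty. The default penalty is `3 * sigma^2 * log(n)`
#' (BIC-like), with `sigma` estimated robustly from the median absolute
#' successive difference (`mad(diff(x)) / sqrt(2)`), so plateau shifts do
#' not inflate the noise estimate.
#'
#' @param series an `sbx_timeseries` (times in ns).
#' @param penalty cost-reduction threshold per accepted change; default
#'   `3 * sigma_hat^2 * log(n)`.
#' @param min_segment minimum segment length in samples (default 10).
#' @return object of class `sbx_transitions`: `times` (ns, strictly
#'   increasing, possibly empty), `indices`, `segment_means`, `penalty`,
#'   `min_segment`.
#' @export
detect_transitions <- function(series, penalty = NULL, min_segment = 10L) {
  stopifnot(inherits(series, "sbx_timeseries"), min_segment >= 1L)
  x <- series$values
  n <- length(x)
  if (n < 2L * min_segment)
    stop("series length ", n, " is below 2 * min_segment")
  if (is.null(penalty)) {
    sig <- stats::mad(diff(x)) / sqrt(2)
    penalty <- 3 * sig^2 * log(n)
  }
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  cps <- integer(0)
  # stack of (a, b] segments, 0-based bounds
  stack <- list(c(0L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    if (b - a < 2L * min_segment) next
    ks <- (a + min_segment):(b - min_segment)  # split after index k
    gain <- seg_sse(s1, s2, a, b) -
      (seg_sse(s1, s2, a, ks) + seg_sse(s1, s2, ks, b))
    best <- which.max(gain)
    if (gain[best] > penalty) {
      k <- ks[best]
      cps <- c(cps, k)
      stack <- c(stack, list(c(a, k), c(k, b)))
    }
  }
  cps <- sort(cps)
  edges <- c(0L, cps, n)
  means <- vapply(seq_len(length(edges) - 1L), function(i)
    mean(x[(edges[i] + 1L):edges[i + 1L]]), numeric(1))
  obj <- list(times = series$times[cps], indices = cps,
              segment_means = means, penalty = penalty,
              min_segment = min_segment)
  class(obj) <- "sbx_transitions"
  obj
}

#' @export
print.sbx_transitions <- function(x, ...) {
  cat("<sbx_transitions> ", length(x$indices), " change point(s)",
      if (length(x$indices))
        paste0(" at ", paste(signif(x$times, 4), collapse = ", "), " ns"),
      "\n", sep = "")
  invisible(x)
}
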