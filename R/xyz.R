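# Multi-frame XYZ is the package's canonical plain-text trajectory fixture
# format. Each frame is:
#   <N>
#   box=<L> dt=<dt> [unwrapped=<0|1>]
#   <name> <x> <y> <z>      (N lines)
# The comment line carries the cubic box edge (A) and frame spacing (ps) so
# fixtures are self-describing and need no binary-format dependency.

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj an [trajectory()] object.
#' @param path output path.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6L) {
  stopifnot(inherits(traj, "sbx_trajectory"))
  n <- n_atoms(traj)
  names <- if (!is.null(traj$atoms)) traj$atoms$name else rep("O", n)
  con <- file(path, open = "wt")
  on.exit(close(con))
  comment <- sprintf("box=%.6g dt=%.6g unwrapped=%d",
                     traj$box, traj$dt, as.integer(traj$unwrapped))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (i in seq_len(n_frames(traj))) {
    fr <- traj$coords[, , i, drop = FALSE]
    writeLines(c(as.character(n), comment,
                 sprintf(fmt, names, fr[, 1, 1], fr[, 2, 1], fr[, 3, 1])),
               con)
  }
  invisible(path)
}

#' Read a trajectory from file
#'
#' Multi-frame XYZ (the canonical fixture format) is always supported; the
#' box edge and time step are taken from the `box=L dt=dt` comment line when
#' present, else from the `box` / `dt` arguments.
#'
#' @param path input path.
#' @param format only "xyz" is supported.
#' @param box,dt fallbacks (A, ps) when the file carries no box/dt comment.
#' @return an [trajectory()] object.
#' @export
read_trajectory <- function(path, format = "xyz", box = NULL, dt = NULL) {
  format <- match.arg(format, "xyz")
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("empty trajectory file: ", path)
  frames <- list(); names1 <- NULL; i <- 1L
  file_box <- NULL; file_dt <- NULL; file_unwrapped <- FALSE
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L)
      stop("malformed XYZ atom-count line ", i, " in ", path)
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i, " in ", path)
    comment <- lines[i + 1L]
    kv <- regmatches(comment, gregexpr("[A-Za-z_]+=[-0-9.eE+]+", comment))[[1]]
    if (length(kv)) {
      kvs <- strsplit(kv, "=", fixed = TRUE)
      for (p in kvs) {
        if (p[1] == "box") file_box <- as.numeric(p[2])
        if (p[1] == "dt") file_dt <- as.numeric(p[2])
        if (p[1] == "unwrapped") file_unwrapped <- as.numeric(p[2]) != 0
      }
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) < 4L))
      stop("malformed XYZ coordinate line ",
           i + 1L + which(lengths(parts) < 4L)[1L], " in ", path)
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3L, byrow = TRUE)
    if (!all(is.finite(m)))
      stop("non-numeric coordinate in XYZ frame starting at line ", i,
           " in ", path)
    if (is.null(names1)) names1 <- vapply(parts, `[`, "", 1L)
    if (length(frames) && nrow(m) != nrow(frames[[1]]))
      stop("inconsistent atom count in XYZ frame starting at line ", i)
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  box <- if (!is.null(file_box)) file_box else box
  dt <- if (!is.null(file_dt)) file_dt else dt
  if (is.null(box)) stop("no box edge in file and none supplied")
  if (is.null(dt)) dt <- 1
  atoms <- data.frame(name = names1, element = names1,
                      resname = "HOH", resno = seq_along(names1),
                      chain = "W", stringsAsFactors = FALSE)
  trajectory(frames, box = box, dt = dt, atoms = atoms,
             unwrapped = file_unwrapped)
}

#' Minimum-image distance in a cubic periodic box
#'
#' Euclidean distance between two points using the nearest periodic image of
#' each coordinate difference; the result never exceeds L*sqrt(3)/2.
#'
#' @param p,q numeric length-3 coordinates (Angstrom).
#' @param L cubic box edge (Angstrom, > 0).
#' @return distance in Angstrom.
#' @export
minimum_image_distance <- function(p, q, L) {
  stopifnot(L > 0)
  d <- p - q
  d <- d - L * round(d / L)
  sqrt(sum(d * d))
}

# Vectorized minimum-image displacement for an n x 3 matrix of differences.
min_image <- function(d, L) d - L * round(d / L)

# Wrap coordinates into [0, L)
wrap_box <- function(m, L) m - L * floor(m / L)

#' Resolve an atom selection to indices
#'
#' Selections are predicates over atom metadata; they resolve to a stable,
#' ordered index vector against a structure's or trajectory's atom table.
#'
#' @param x an `sbx_structure` or `sbx_trajectory` with atom metadata.
#' @param chain,resno,resname,name,element optional filters; each may be a
#'   vector of admissible values, NULL means "any".
#' @return integer vector of atom indices (file order).
#' @export
select_atoms <- function(x, chain = NULL, resno = NULL, resname = NULL,
                         name = NULL, element = NULL) {
  atoms <- if (inherits(x, "sbx_structure")) x$atoms else x$atoms
  if (is.null(atoms)) stop("object carries no atom metadata to select on")
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  if (!is.null(resname)) keep <- keep & atoms$resname %in% resname
  if (!is.null(name)) keep <- keep & atoms$name %in% name
  if (!is.null(element)) keep <- keep & atoms$element %in% element
  which(keep)
}
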