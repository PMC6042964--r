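#' Construct a static atomic structure
#'
#' A `sbx_structure` is an ordered atom table (name, element, residue name,
#' residue number, chain id, x/y/z in Angstrom) plus a title. The
#' (chain, resno, atom name) triple must be unique so selections resolve
#' unambiguously.
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resno`, `chain`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param title character scalar identifier.
#' @return an object of class `sbx_structure`.
#' @export
structure_model <- function(atoms, title = "") {
  req <- c("name", "element", "resname", "resno", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, atom name) triple: ",
         key[duplicated(key)][1L])
  obj <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
              title = as.character(title))
  class(obj) <- "sbx_structure"
  obj
}

#' @export
print.sbx_structure <- function(x, ...) {
  cat("<sbx_structure> ", x$title, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms),
      "  chains: ", paste(unique(x$atoms$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records (via bio3d) into an ordered atom table.
#' Records the parser does not model (headers, anisotropic factors, ...) are
#' ignored. Author chain ids and residue numbering are kept verbatim.
#'
#' @param path path to a PDB file.
#' @return an [structure_model()] object, title taken from the file name.
#' @seealso [write_pdb()]
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("no ATOM/HETATM records in ", path)
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad))
    stop("malformed coordinate field in '", path, "' at atom record ", bad[1L])
  elt <- a$elesy
  if (is.null(elt) || all(is.na(elt)))
    elt <- toupper(substr(trimws(a$elety), 1L, 1L))
  structure_model(
    data.frame(name = trimws(a$elety), element = trimws(elt),
               resname = trimws(a$resid), resno = a$resno,
               chain = ifelse(is.na(a$chain), "", a$chain),
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE),
    title = sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
}

#' Write a structure to a PDB file (ATOM/TER subset)
#'
#' @param structure an `sbx_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "sbx_structure"))
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$name, elesy = a$element)
  invisible(path)
}

#' Construct a trajectory
#'
#' A `sbx_trajectory` holds ordered frames of coordinates in a cubic
#' periodic box. Frames are stored as an `N x 3 x n_frames` array in
#' Angstrom. Non-cubic boxes are rejected.
#'
#' @param coords `N x 3 x n_frames` array, or a list of `N x 3` matrices
#'   with identical atom counts.
#' @param box cubic box edge L in Angstrom (single positive number).
#' @param dt time between frames in ps.
#' @param atoms optional atom metadata data.frame (as in
#'   [structure_model()], coordinates ignored) or NULL for anonymous atoms.
#' @param unwrapped logical: TRUE if coordinates are continuous (not wrapped
#'   back into the box), as required for mean-squared displacements.
#' @param metadata optional list of generator ground truth (seed, true D,
#'   planted counts, ...).
#' @return an object of class `sbx_trajectory`.
#' @export
trajectory <- function(coords, box, dt, atoms = NULL, unwrapped = FALSE,
                       metadata = list()) {
  if (is.list(coords) && !is.array(coords)) {
    n <- unique(vapply(coords, nrow, integer(1)))
    if (length(n) != 1L)
      stop("all frames must have the same atom count")
    coords <- array(unlist(coords), dim = c(n, 3L, length(coords)))
  }
  if (!(is.array(coords) && length(dim(coords)) == 3L && dim(coords)[2] == 3L))
    stop("coords must be an N x 3 x n_frames array")
  if (length(box) != 1L || !is.finite(box) || box <= 0)
    stop("box must be a single positive cubic edge length in Angstrom; ",
         "non-cubic boxes are not supported")
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive time step in ps")
  if (!is.null(atoms) && nrow(atoms) != dim(coords)[1])
    stop("atom metadata rows (", nrow(atoms),
         ") do not match coordinate rows (", dim(coords)[1], ")")
  obj <- list(coords = coords, box = box, dt = dt, atoms = atoms,
              unwrapped = isTRUE(unwrapped), metadata = metadata)
  class(obj) <- "sbx_trajectory"
  obj
}

#' @export
print.sbx_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<sbx_trajectory> ", d[1], " atoms x ", d[3], " frames",
      "  L = ", x$box, " A  dt = ", x$dt, " ps",
      if (x$unwrapped) "  (unwrapped)" else "  (wrapped)", "\n", sep = "")
  invisible(x)
}

#' @rdname trajectory
#' @param traj an `sbx_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as an N x 3 matrix
#' @param traj an `sbx_trajectory`.
#' @param i frame index (1-based).
#' @return `N x 3` coordinate matrix in Angstrom.
#' @export
frame_coords <- function(traj, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

# Frame extraction that survives N = 1 (plain [..] would drop to a vector).
frame_mat <- function(coords, sel, f) {
  m <- coords[sel, , f, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Construct a labelled time series
#'
#' Times are in ns (the reporting unit for trajectory-scale observables);
#' values carry a unit annotation (e.g. "A" for distances, "count" for
#' hydrogen bonds).
#'
#' @param times numeric vector, ns, strictly increasing.
#' @param values numeric vector, same length.
#' @param label character label.
#' @param unit character unit annotation for `values`.
#' @param metadata optional list of generator ground truth.
#' @return an object of class `sbx_timeseries`.
#' @export
timeseries <- function(times, values, label = "", unit = "",
                       metadata = list()) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  obj <- list(times = as.numeric(times), values = as.numeric(values),
              label = label, unit = unit, metadata = metadata)
  class(obj) <- "sbx_timeseries"
  obj
}

#' @export
print.sbx_timeseries <- function(x, ...) {
  cat("<sbx_timeseries> ", x$label, " [", x$unit, "]  n = ",
      length(x$times), "  t = ", x$times[1], " .. ",
      x$times[length(x$times)], " ns\n", sep = "")
  invisible(x)
}

#' Read / write a time series as a two-column CSV (time_ns, value)
#' @param path CSV path.
#' @param label,unit annotations for the returned series (read).
#' @return [timeseries()] object (read); `path` invisibly (write).
#' @export
read_timeseries_csv <- function(path, label = basename(path), unit = "") {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("time-series CSV needs two columns: ", path)
  timeseries(d[[1]], d[[2]], label = label, unit = unit)
}

#' @rdname read_timeseries_csv
#' @param ts an `sbx_timeseries`.
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "sbx_timeseries"))
  utils::write.csv(data.frame(time_ns = ts$times, value = ts$values),
                   path, row.names = FALSE)
  invisible(path)
}
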