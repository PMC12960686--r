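# Trajectory container and plain-text I/O (multi-model PDB, per-frame XYZ).

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)
# Bondi van der Waals radii (A)
.element_vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

element_mass <- function(element) {
  m <- unname(.element_mass[element])
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(element[is.na(m)]), collapse = ", "),
            "; assigning mass 12.0")
    m[is.na(m)] <- 12.0
  }
  m
}

element_vdw <- function(element) {
  r <- unname(.element_vdw[element])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ", "),
            "; assigning vdW radius 1.7 A")
    r[is.na(r)] <- 1.7
  }
  r
}

#' Construct a trajectory object
#'
#' The container consumed by all MD analytics: an F x N x 3 coordinate array
#' in Angstrom plus per-atom metadata. Atom ordering must be identical across
#' frames.
#'
#' @param coords F x N x 3 numeric array (Angstrom).
#' @param atoms Data frame with one row per atom: `name`, `element`,
#'   `resid`, `resname`, `chain`; `mass` (amu) and `radius` (vdW, Angstrom)
#'   are filled from a bundled element table when absent.
#' @param times Frame times in ps (default 10 ps spacing, the save interval
#'   of the emulated production runs).
#' @param box Optional orthorhombic box lengths (length-3, Angstrom).
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, atoms, times = NULL, box = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort_confunnel("`coords` must be an F x N x 3 array", "invalid_config")
  }
  n_atoms <- dim(coords)[2]
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) != n_atoms) {
    abort_confunnel("atom metadata rows must match coordinate atom count",
                    "invalid_config")
  }
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  if (!"radius" %in% names(atoms)) atoms$radius <- element_vdw(atoms$element)
  if (any(atoms$mass <= 0) || any(atoms$radius <= 0)) {
    abort_confunnel("masses and vdW radii must be positive", "invalid_config")
  }
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * 10
  structure(list(coords = coords, atoms = atoms,
                 times = as.numeric(times), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %.0f ps span\n",
              n_frames(x), n_atoms(x), diff(range(x$times))))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

# One frame as an N x 3 matrix.
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

check_selection <- function(selection, n) {
  if (length(selection) == 0) {
    abort_confunnel("empty atom selection", "empty_selection")
  }
  selection <- as.integer(selection)
  if (anyDuplicated(selection) || any(selection < 1) || any(selection > n)) {
    abort_confunnel("selection indices must be unique and within 1..N_atoms",
                    "invalid_config")
  }
  selection
}

#' Write / read a trajectory as multi-model PDB
#'
#' Frames are written as MODEL/ENDMDL blocks with 1-based atom serials,
#' coordinates in Angstrom. The reader accepts any multi-model PDB whose
#' models share the same atom ordering.
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @return `path` invisibly (writer); a `trajectory` (reader).
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    lines <- sprintf("ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     seq_len(nrow(a)),
                     substr(a$name, 1, 4), substr(a$resname, 1, 4),
                     substr(a$chain, 1, 1), a$resid,
                     xyz[, 1], xyz[, 2], xyz[, 3], a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_trajectory_pdb
#' @export
read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) model_starts <- 1L
  frame_id <- findInterval(which(is_atom), model_starts)
  atom_lines <- lines[is_atom]
  nf <- max(frame_id)
  npf <- sum(frame_id == 1)
  if (any(tabulate(frame_id, nf) != npf)) {
    abort_confunnel("models differ in atom count", "invalid_config")
  }
  x <- as.numeric(substr(atom_lines, 31, 38))
  y <- as.numeric(substr(atom_lines, 39, 46))
  z <- as.numeric(substr(atom_lines, 47, 54))
  coords <- array(NA_real_, c(nf, npf, 3))
  for (f in seq_len(nf)) {
    idx <- which(frame_id == f)
    coords[f, , ] <- cbind(x[idx], y[idx], z[idx])
  }
  first <- atom_lines[frame_id == 1]
  element <- trimws(substr(first, 77, 78))
  element[element == ""] <- toupper(substr(trimws(substr(first, 13, 16)), 1, 1))
  atoms <- tibble::tibble(
    name = trimws(substr(first, 13, 16)),
    resname = trimws(substr(first, 18, 21)),
    chain = substr(first, 22, 22),
    resid = as.integer(substr(first, 23, 26)),
    element = element)
  trajectory(coords, atoms)
}

#' Write / read a trajectory in a plain-text per-frame XYZ format
#'
#' Header line `frames <F> atoms <N>`, then for each frame a `frame <i> time
#' <t_ps>` line followed by one `element name resid x y z` line per atom.
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("frames %d atoms %d", n_frames(traj), n_atoms(traj)), con)
  a <- traj$atoms
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("frame %d time %.4f", f, traj$times[f]), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("%s %s %d %.6f %.6f %.6f", a$element, a$name, a$resid,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  nf <- as.integer(hdr[2]); na <- as.integer(hdr[4])
  coords <- array(NA_real_, c(nf, na, 3))
  times <- numeric(nf)
  pos <- 2L
  atoms <- NULL
  for (f in seq_len(nf)) {
    fh <- strsplit(lines[pos], " ")[[1]]
    times[f] <- as.numeric(fh[4])
    block <- lines[(pos + 1L):(pos + na)]
    parts <- do.call(rbind, strsplit(block, " "))
    coords[f, , ] <- cbind(as.numeric(parts[, 4]), as.numeric(parts[, 5]),
                           as.numeric(parts[, 6]))
    if (f == 1) {
      atoms <- tibble::tibble(element = parts[, 1], name = parts[, 2],
                              resid = as.integer(parts[, 3]),
                              resname = "UNK", chain = "A")
    }
    pos <- pos + na + 1L
  }
  trajectory(coords, atoms, times = times)
}
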