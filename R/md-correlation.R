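# Collective-motion analytics: DCCM and PCA free-energy landscape.

#' Dynamic cross-correlation matrix
#'
#' After optional superposition onto the mean structure, the displacement of
#' atom i at frame t is dr_i(t) = r_i(t) - mean(r_i). The matrix entry is
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>): +1 for fully
#' correlated, -1 for anti-correlated motion. Atoms with zero fluctuation
#' get NA rows/columns with a warning; the diagonal is 1 for all moving
#' atoms and |C_ij| <= 1 throughout.
#'
#' @param traj A [trajectory()] with >= 3 frames.
#' @param selection Atom indices (default all).
#' @param fit Superpose frames first (default TRUE).
#' @return N_sel x N_sel symmetric matrix.
#' @export
dccm <- function(traj, selection = seq_len(n_atoms(traj)), fit = TRUE) {
  if (n_frames(traj) < 3) {
    abort_confunnel("DCCM needs at least 3 frames", "insufficient_frames")
  }
  selection <- check_selection(selection, n_atoms(traj))
  nf <- n_frames(traj); ns <- length(selection)
  coords <- lapply(seq_len(nf), function(f)
    frame_coords(traj, f)[selection, , drop = FALSE])
  if (fit) {
    coords <- lapply(coords, function(x) kabsch_superpose(x, coords[[1]])$fitted)
    mean_str <- Reduce(`+`, coords) / nf
    coords <- lapply(coords, function(x) kabsch_superpose(x, mean_str)$fitted)
  }
  mean_str <- Reduce(`+`, coords) / nf
  # frame-major displacement blocks: dx, dy, dz each nf x ns
  dx <- t(vapply(coords, function(x) x[, 1] - mean_str[, 1], numeric(ns)))
  dy <- t(vapply(coords, function(x) x[, 2] - mean_str[, 2], numeric(ns)))
  dz <- t(vapply(coords, function(x) x[, 3] - mean_str[, 3], numeric(ns)))
  if (ns == 1) { dx <- t(dx); dy <- t(dy); dz <- t(dz) }
  cross <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / nf
  msf <- diag(cross)
  still <- msf <= 0
  if (any(still)) {
    warning(sprintf("%d atom(s) with zero fluctuation; rows set to NA",
                    sum(still)))
  }
  norm <- sqrt(msf); norm[still] <- NA_real_
  cij <- cross / outer(norm, norm)
  dg <- diag(cij); dg[!still] <- 1
  diag(cij) <- dg
  cij
}

#' Free-energy landscape over the first two principal components
#'
#' Superposed selected coordinates are projected onto their first two
#' principal components; a 2D occupancy histogram over the projections is
#' converted to free energies F_bin = -kB T ln(P_bin / P_max) in kJ/mol
#' (kB T = R T / 1000, i.e. 2.577 kJ/mol at 310 K). The most populated bin
#' has exactly F = 0; unoccupied bins are NA (masked), never 0.
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices (default all).
#' @param temperature Kelvin (default 310, physiological).
#' @param bins Bins per collective variable (default 32).
#' @param cv Optional F x 2 matrix of precomputed collective variables
#'   (e.g. RMSD and Rg series), bypassing the PCA.
#' @return List of class `fel_grid`: `free_energy` (bins x bins, kJ/mol,
#'   NA = unvisited), `counts`, `cv1_breaks`, `cv2_breaks`, `cv`
#'   (the projections), `temperature`, `kT`.
#' @export
free_energy_landscape <- function(traj, selection = seq_len(n_atoms(traj)),
                                  temperature = 310, bins = 32L, cv = NULL) {
  if (is.null(cv)) {
    if (n_frames(traj) < bins) {
      abort_confunnel("need at least `bins` frames to populate the landscape",
                      "invalid_config")
    }
    selection <- check_selection(selection, n_atoms(traj))
    nf <- n_frames(traj)
    coords <- lapply(seq_len(nf), function(f)
      frame_coords(traj, f)[selection, , drop = FALSE])
    coords <- lapply(coords, function(x) kabsch_superpose(x, coords[[1]])$fitted)
    mean_str <- Reduce(`+`, coords) / nf
    coords <- lapply(coords, function(x) kabsch_superpose(x, mean_str)$fitted)
    flat <- t(vapply(coords, as.numeric, numeric(3 * length(selection))))
    pc <- prcomp(flat, center = TRUE, scale. = FALSE)
    if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-10) {
      abort_confunnel("covariance has fewer than 2 nontrivial principal components",
                      "degenerate_pca")
    }
    cv <- pc$x[, 1:2, drop = FALSE]
  } else {
    cv <- as.matrix(cv)
    if (ncol(cv) != 2) abort_confunnel("`cv` must have 2 columns", "invalid_config")
  }
  pad <- function(r) { if (diff(r) == 0) r + c(-0.5, 0.5) else r + diff(r) * c(-1e-9, 1e-9) }
  b1 <- seq(pad(range(cv[, 1]))[1], pad(range(cv[, 1]))[2], length.out = bins + 1)
  b2 <- seq(pad(range(cv[, 2]))[1], pad(range(cv[, 2]))[2], length.out = bins + 1)
  i1 <- findInterval(cv[, 1], b1, rightmost.closed = TRUE)
  i2 <- findInterval(cv[, 2], b2, rightmost.closed = TRUE)
  counts <- matrix(0L, bins, bins)
  for (f in seq_len(nrow(cv))) counts[i1[f], i2[f]] <- counts[i1[f], i2[f]] + 1L
  kt <- 8.314462618e-3 * temperature  # kJ/mol
  fe <- matrix(NA_real_, bins, bins)
  occ <- counts > 0
  fe[occ] <- -kt * log(counts[occ] / max(counts))
  structure(list(free_energy = fe, counts = counts,
                 cv1_breaks = b1, cv2_breaks = b2, cv = cv,
                 temperature = temperature, kT = kt),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat(sprintf("<fel_grid> %dx%d bins, %d occupied, max barrier %.3f kJ/mol (T = %g K)\n",
              nrow(x$counts), ncol(x$counts), occ,
              max(x$free_energy, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' Write a free-energy landscape as long-format CSV
#'
#' Columns `cv1_bin`, `cv2_bin` (bin centers), `count`, `F_kJmol` (NA for
#' unvisited bins).
#'
#' @param fel A `fel_grid`.
#' @param path Output path.
#' @export
write_fel_csv <- function(fel, path) {
  centers1 <- (head(fel$cv1_breaks, -1) + fel$cv1_breaks[-1]) / 2
  centers2 <- (head(fel$cv2_breaks, -1) + fel$cv2_breaks[-1]) / 2
  grid <- expand.grid(i = seq_along(centers1), j = seq_along(centers2))
  out <- tibble::tibble(cv1_bin = centers1[grid$i], cv2_bin = centers2[grid$j],
                        count = fel$counts[cbind(grid$i, grid$j)],
                        F_kJmol = fel$free_energy[cbind(grid$i, grid$j)])
  readr::write_csv(out, path)
  invisible(path)
}
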