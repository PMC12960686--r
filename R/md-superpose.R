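# Superposition-based trajectory metrics: Kabsch fit, RMSD, RMSF.

#' Optimal weighted superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1; reflections excluded) and
#' translation minimizing the weighted RMSD between `mobile` and
#' `reference`.
#'
#' @param mobile,reference N x 3 coordinate matrices (Angstrom).
#' @param weights Non-negative per-atom weights, not all zero (default
#'   uniform).
#' @return List: `rotation` (3 x 3), `translation` (length 3), `fitted`
#'   (mobile after the transform), `rmsd` (weighted, post-fit). The
#'   transform maps mobile as `fitted = (mobile - mobile_center) R^T +
#'   reference_center`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n) {
    abort_confunnel("need >= 3 paired atoms for a unique rotation",
                    "degenerate_fit")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    abort_confunnel("weights must be >= 0 and not all zero", "degenerate_fit")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  # geometry must span a plane for the rotation to be unique
  if (svd(b * sqrt(w))$d[2] < 1e-8 || svd(a * sqrt(w))$d[2] < 1e-8) {
    abort_confunnel("degenerate (collinear) geometry", "degenerate_fit")
  }
  h <- t(a * w) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(a %*% t(rot), 2, cr, "+")
  dev2 <- rowSums((fitted - reference)^2)
  list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
       fitted = fitted, rmsd = sqrt(sum(w * dev2)))
}

plain_rmsd <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

#' Per-frame RMSD against a reference frame
#'
#' RMSD = sqrt(mean over selected atoms of squared displacement), after
#' optimal superposition onto the reference when `fit = TRUE`.
#'
#' @param traj A [trajectory()].
#' @param reference Reference frame index (default 1) or an N_sel x 3
#'   coordinate matrix.
#' @param selection Atom indices (1-based; default all atoms).
#' @param fit Superpose each frame before measuring (default TRUE).
#' @return Tibble: `time_ps`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = seq_len(n_atoms(traj)),
                        fit = TRUE) {
  selection <- check_selection(selection, n_atoms(traj))
  ref <- if (is.matrix(reference)) reference
         else frame_coords(traj, reference)[selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)[selection, , drop = FALSE]
    if (fit) kabsch_superpose(x, ref)$rmsd else plain_rmsd(x, ref)
  }, numeric(1))
  tibble::tibble(time_ps = traj$times, rmsd = vals)
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean over frames of |r_i - mean(r_i)|^2). With
#' `fit = TRUE`, frames are first superposed onto frame 1, the mean
#' structure computed, and frames refit onto that mean (one iteration) so
#' fluctuations are measured in a common internal frame.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param selection Atom indices (default all).
#' @param fit Remove rigid-body motion first (default TRUE).
#' @return Tibble: `atom` (selection index), `resid`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = seq_len(n_atoms(traj)), fit = TRUE) {
  if (n_frames(traj) < 2) {
    abort_confunnel("RMSF needs at least 2 frames", "insufficient_frames")
  }
  selection <- check_selection(selection, n_atoms(traj))
  nf <- n_frames(traj)
  coords <- lapply(seq_len(nf), function(f)
    frame_coords(traj, f)[selection, , drop = FALSE])
  if (fit) {
    coords <- lapply(coords, function(x) kabsch_superpose(x, coords[[1]])$fitted)
    mean_str <- Reduce(`+`, coords) / nf
    coords <- lapply(coords, function(x) kabsch_superpose(x, mean_str)$fitted)
  }
  mean_str <- Reduce(`+`, coords) / nf
  ssq <- Reduce(`+`, lapply(coords, function(x) rowSums((x - mean_str)^2)))
  tibble::tibble(atom = selection,
                 resid = traj$atoms$resid[selection],
                 rmsf = sqrt(ssq / nf))
}
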