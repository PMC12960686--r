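#' Configuration for synthetic test trajectories
#'
#' Three motion modes with known ground truth:
#' * `rigid` — every frame is a proper rotation + translation of frame 1
#'   (no internal motion; RMSD after superposition must vanish).
#' * `harmonic` — template + per-atom isotropic Gaussian displacements with
#'   configurable amplitudes (RMSF has the closed form a * sqrt(3)).
#' * `drift` — template scaled outward by (1 + drift_rate * (frame - 1))
#'   about the centroid, so the radius of gyration grows monotonically.
#'
#' @param n_frames Number of frames (>= 2).
#' @param n_atoms Number of atoms (>= 1).
#' @param mode One of "rigid", "harmonic", "drift".
#' @param amplitudes Per-atom Gaussian displacement SD in Angstrom
#'   (harmonic mode; recycled to `n_atoms`).
#' @param drift_rate Fractional expansion per frame (drift mode).
#' @param seed Integer seed.
#' @param dt_ps Time between saved frames, ps (default 10).
#' @return A `trajectory_config` list.
#' @export
trajectory_config <- function(n_frames, n_atoms,
                              mode = c("rigid", "harmonic", "drift"),
                              amplitudes = 0.5, drift_rate = 0.01,
                              seed = 1L, dt_ps = 10) {
  mode <- match.arg(mode)
  if (!is_count(n_frames) || n_frames < 2) {
    abort_confunnel("`n_frames` must be an integer >= 2", "invalid_config")
  }
  if (!is_count(n_atoms) || n_atoms < 1) {
    abort_confunnel("`n_atoms` must be a positive integer", "invalid_config")
  }
  amplitudes <- rep_len(as.numeric(amplitudes), n_atoms)
  if (any(amplitudes < 0)) {
    abort_confunnel("`amplitudes` must be >= 0", "invalid_config")
  }
  structure(list(n_frames = as.integer(n_frames), n_atoms = as.integer(n_atoms),
                 mode = mode, amplitudes = amplitudes,
                 drift_rate = drift_rate, seed = as.integer(seed),
                 dt_ps = dt_ps),
            class = "trajectory_config")
}

# Uniform random proper rotation (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic trajectory with known motion
#'
#' @param config A [trajectory_config()].
#' @return A [trajectory()] with pseudo C-alpha atoms (one residue per atom).
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  nf <- config$n_frames; na_ <- config$n_atoms
  coords <- array(NA_real_, c(nf, na_, 3))
  with_seed(config$seed, {
    template <- matrix(rnorm(na_ * 3, sd = 4), na_, 3)
    if (config$mode == "rigid") {
      coords[1, , ] <- template
      for (f in 2:nf) {
        rot <- random_rotation()
        shift <- rnorm(3, sd = 3)
        coords[f, , ] <- sweep(template %*% t(rot), 2, shift, "+")
      }
    } else if (config$mode == "harmonic") {
      for (f in seq_len(nf)) {
        disp <- matrix(rnorm(na_ * 3), na_, 3) * config$amplitudes
        coords[f, , ] <- template + disp
      }
    } else { # drift
      center <- colMeans(template)
      centered <- sweep(template, 2, center)
      for (f in seq_len(nf)) {
        scale <- 1 + config$drift_rate * (f - 1)
        coords[f, , ] <- sweep(centered * scale, 2, center, "+")
      }
    }
  })
  atoms <- tibble::tibble(
    name = "CA", element = "C", resid = seq_len(na_), resname = "GLY",
    chain = "A")
  trajectory(coords, atoms, times = (seq_len(nf) - 1) * config$dt_ps)
}
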