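# Geometric trajectory metrics: radius of gyration, SASA, hydrogen bonds.

#' Mass-weighted radius of gyration with axis components
#'
#' About the mass-weighted centroid: Rg^2 = sum(m |r|^2) / sum(m). Axis
#' components default to the about-axis convention
#' RgX^2 = sum(m (y^2 + z^2)) / sum(m) (likewise Y, Z), which satisfies the
#' identity 2 Rg^2 = RgX^2 + RgY^2 + RgZ^2. `convention = "along"` switches
#' to the along-axis form Rg_x^2 = sum(m x^2)/sum(m) with identity
#' Rg^2 = sum of components squared.
#'
#' @param frame N x 3 coordinate matrix or a [trajectory()] (then `which`
#'   selects the frame).
#' @param selection Atom indices (default all).
#' @param masses Per-atom masses; taken from trajectory metadata when
#'   available, else unit.
#' @param convention "about" (default) or "along".
#' @param which Frame index when `frame` is a trajectory (default 1).
#' @return Named numeric: `Rg`, `RgX`, `RgY`, `RgZ` (Angstrom).
#' @export
radius_of_gyration <- function(frame, selection = NULL, masses = NULL,
                               convention = c("about", "along"), which = 1L) {
  convention <- match.arg(convention)
  if (inherits(frame, "trajectory")) {
    traj <- frame
    if (is.null(selection)) selection <- seq_len(n_atoms(traj))
    selection <- check_selection(selection, n_atoms(traj))
    if (is.null(masses)) masses <- traj$atoms$mass[selection]
    frame <- frame_coords(traj, which)[selection, , drop = FALSE]
  } else {
    frame <- as.matrix(frame)
    if (!is.null(selection)) frame <- frame[selection, , drop = FALSE]
  }
  if (nrow(frame) == 0) abort_confunnel("empty atom selection", "empty_selection")
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  if (sum(masses) <= 0) abort_confunnel("total selected mass must be > 0",
                                        "empty_selection")
  w <- masses / sum(masses)
  ctr <- colSums(frame * w)
  d <- sweep(frame, 2, ctr)
  m2 <- colSums(d^2 * w)  # weighted second moments per axis
  rg <- sqrt(sum(m2))
  comps <- if (convention == "about") {
    sqrt(c(m2[2] + m2[3], m2[1] + m2[3], m2[1] + m2[2]))
  } else {
    sqrt(m2)
  }
  c(Rg = rg, RgX = unname(comps[1]), RgY = unname(comps[2]),
    RgZ = unname(comps[3]))
}

#' Per-frame radius-of-gyration series
#'
#' @inheritParams radius_of_gyration
#' @param traj A [trajectory()].
#' @return Tibble: `time_ps`, `Rg`, `RgX`, `RgY`, `RgZ`.
#' @export
rg_series <- function(traj, selection = seq_len(n_atoms(traj)),
                      convention = "about") {
  selection <- check_selection(selection, n_atoms(traj))
  vals <- t(vapply(seq_len(n_frames(traj)), function(f)
    radius_of_gyration(traj, selection, convention = convention, which = f),
    numeric(4)))
  tibble::tibble(time_ps = traj$times, Rg = vals[, 1], RgX = vals[, 2],
                 RgY = vals[, 3], RgZ = vals[, 4])
}

# Quasi-uniform points on the unit sphere (golden-spiral construction).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each selected atom, test points are placed quasi-uniformly on a
#' sphere of radius r_vdW + probe; the accessible fraction is the share of
#' points not inside any neighbour's expanded sphere, and the atom's SASA is
#' that fraction times 4 pi (r_vdW + probe)^2. Occluders include all atoms
#' of the frame (selected or not).
#'
#' @param frame N x 3 coordinates or a [trajectory()] (with `which`).
#' @param selection Atoms to report SASA for (default all).
#' @param radii Per-atom vdW radii (Angstrom); from trajectory metadata or
#'   required explicitly for bare matrices.
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points Quadrature points per atom (default 960).
#' @param which Frame index for trajectory input.
#' @return List: `per_atom` (tibble `atom`, `sasa`), `total` (Angstrom^2).
#' @export
sasa <- function(frame, selection = NULL, radii = NULL, probe_radius = 1.4,
                 n_sphere_points = 960L, which = 1L) {
  if (inherits(frame, "trajectory")) {
    traj <- frame
    if (is.null(radii)) radii <- traj$atoms$radius
    frame <- frame_coords(traj, which)
  } else {
    frame <- as.matrix(frame)
  }
  n <- nrow(frame)
  if (is.null(selection)) selection <- seq_len(n)
  selection <- check_selection(selection, n)
  if (is.null(radii) || length(radii) != n || anyNA(radii)) {
    abort_confunnel("vdW radii required for every atom", "missing_radius")
  }
  pts <- sphere_points(n_sphere_points)
  expanded <- radii + probe_radius
  per_atom <- vapply(selection, function(i) {
    ri <- expanded[i]
    # neighbours whose expanded sphere can reach atom i's surface
    d2 <- rowSums(sweep(frame, 2, frame[i, ])^2)
    nbr <- which(d2 < (ri + expanded)^2 & seq_len(n) != i)
    surf <- sweep(pts * ri, 2, frame[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nbr) {
      dj2 <- rowSums(sweep(surf, 2, frame[j, ])^2)
      acc <- acc & dj2 > expanded[j]^2
      if (!any(acc)) break
    }
    mean(acc) * 4 * pi * ri^2
  }, numeric(1))
  list(per_atom = tibble::tibble(atom = selection, sasa = per_atom),
       total = sum(per_atom))
}

#' Per-frame total SASA series
#'
#' @inheritParams sasa
#' @param traj A [trajectory()].
#' @return Tibble: `time_ps`, `sasa` (Angstrom^2).
#' @export
sasa_series <- function(traj, selection = seq_len(n_atoms(traj)),
                        probe_radius = 1.4, n_sphere_points = 960L) {
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    sasa(traj, selection, probe_radius = probe_radius,
         n_sphere_points = n_sphere_points, which = f)$total, numeric(1))
  tibble::tibble(time_ps = traj$times, sasa = vals)
}

vec_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Geometric hydrogen-bond detection
#'
#' A bond is recorded between donor heavy atom D (with its bonded hydrogen
#' H) and acceptor A iff distance(D, A) <= `d_max` and the H-D-A angle (at
#' D, between the D->H and D->A directions) <= `angle_max`. For
#' trajectories, per-frame counts and per-pair persistence (fraction of
#' frames bonded) are reported.
#'
#' @param frame N x 3 coordinates or a [trajectory()].
#' @param donors 2-column matrix / data frame of (D, H) atom index pairs.
#' @param acceptors Acceptor atom indices.
#' @param d_max Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_max H-D-A angle cutoff, degrees (default 30).
#' @return For a single frame: list `bonds` (tibble `donor`, `hydrogen`,
#'   `acceptor`, `distance`, `angle`), `count`. For a trajectory: list
#'   `counts` (tibble `time_ps`, `n_bonds`), `persistence` (tibble `donor`,
#'   `acceptor`, `fraction`).
#' @export
hydrogen_bonds <- function(frame, donors, acceptors, d_max = 3.5,
                           angle_max = 30) {
  donors <- as.matrix(donors)
  if (ncol(donors) != 2) {
    abort_confunnel("`donors` must be (D, H) index pairs", "pairing_error")
  }
  if (inherits(frame, "trajectory")) {
    traj <- frame
    per_frame <- lapply(seq_len(n_frames(traj)), function(f)
      hydrogen_bonds(frame_coords(traj, f), donors, acceptors, d_max, angle_max))
    counts <- tibble::tibble(time_ps = traj$times,
                             n_bonds = vapply(per_frame, `[[`, integer(1), "count"))
    all_pairs <- dplyr::bind_rows(lapply(seq_along(per_frame), function(f) {
      b <- per_frame[[f]]$bonds
      if (nrow(b)) dplyr::mutate(b[, c("donor", "acceptor")], frame = f) else NULL
    }))
    persistence <- if (nrow(all_pairs)) {
      dplyr::summarise(dplyr::group_by(all_pairs, .data$donor, .data$acceptor),
                       fraction = dplyr::n() / n_frames(traj), .groups = "drop")
    } else {
      tibble::tibble(donor = integer(0), acceptor = integer(0),
                     fraction = numeric(0))
    }
    return(list(counts = counts, persistence = persistence))
  }
  frame <- as.matrix(frame)
  res <- list()
  for (k in seq_len(nrow(donors))) {
    d_i <- donors[k, 1]; h_i <- donors[k, 2]
    dpos <- frame[d_i, ]; hpos <- frame[h_i, ]
    for (a_i in acceptors) {
      if (a_i == d_i || a_i == h_i) next
      apos <- frame[a_i, ]
      dist <- sqrt(sum((apos - dpos)^2))
      if (dist > d_max) next
      ang <- vec_angle_deg(hpos - dpos, apos - dpos)
      if (ang > angle_max) next
      res[[length(res) + 1]] <- tibble::tibble(
        donor = d_i, hydrogen = h_i, acceptor = a_i,
        distance = dist, angle = ang)
    }
  }
  bonds <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(donor = integer(0), hydrogen = integer(0),
                   acceptor = integer(0), distance = numeric(0),
                   angle = numeric(0))
  list(bonds = bonds, count = nrow(bonds))
}
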