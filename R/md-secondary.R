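# Simplified secondary-structure assignment (Kabsch-Sander H-bond energy,
# helix/strand/coil states) and an ideal-backbone builder for fixtures.

# Place atom D given A, B, C with bond |C-D|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg); natural-extension reference frame construction.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  theta <- angle_deg * pi / 180
  chi <- -dihedral_deg * pi / 180  # sign fixed to the standard convention
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide backbone from backbone dihedrals
#'
#' Generates N, CA, C, O coordinates for `n_res` residues at the given phi /
#' psi dihedrals with standard bond lengths and angles (omega fixed at 180,
#' trans). Useful as a geometric fixture: phi = -57, psi = -47 gives an
#' alpha-helix; phi = -139, psi = 135 an extended beta strand.
#'
#' @param n_res Number of residues (>= 2).
#' @param phi,psi Backbone dihedrals in degrees (recycled).
#' @return List: `coords` (4 * n_res x 3 matrix), `atoms` (tibble `name`,
#'   `element`, `resid`, `resname`, `chain`).
#' @export
build_peptide_backbone <- function(n_res, phi = -57, psi = -47) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7; a_caco <- 120.8
  n_pos <- ca_pos <- c_pos <- o_pos <- matrix(NA_real_, n_res, 3)
  n_pos[1, ] <- c(0, 0, 0)
  ca_pos[1, ] <- c(b_nca, 0, 0)
  th <- a_ncac * pi / 180
  c_pos[1, ] <- ca_pos[1, ] + b_cac * c(-cos(th), sin(th), 0)
  for (i in 2:n_res) {
    n_pos[i, ] <- place_atom(n_pos[i - 1, ], ca_pos[i - 1, ], c_pos[i - 1, ],
                             b_cn, a_cacn, psi[i - 1])
    ca_pos[i, ] <- place_atom(ca_pos[i - 1, ], c_pos[i - 1, ], n_pos[i, ],
                              b_nca, a_cnca, 180)
    c_pos[i, ] <- place_atom(c_pos[i - 1, ], n_pos[i, ], ca_pos[i, ],
                             b_cac, a_ncac, phi[i])
  }
  for (i in seq_len(n_res)) {
    # carbonyl O anti to the next amide N: dihedral N-CA-C-O = psi + 180
    o_pos[i, ] <- place_atom(n_pos[i, ], ca_pos[i, ], c_pos[i, ],
                             b_co, a_caco, psi[i] + 180)
  }
  coords <- matrix(NA_real_, 4 * n_res, 3)
  for (i in seq_len(n_res)) {
    coords[4 * i - 3, ] <- n_pos[i, ]
    coords[4 * i - 2, ] <- ca_pos[i, ]
    coords[4 * i - 1, ] <- c_pos[i, ]
    coords[4 * i, ] <- o_pos[i, ]
  }
  atoms <- tibble::tibble(
    name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    resid = rep(seq_len(n_res), each = 4),
    resname = "ALA", chain = "A")
  list(coords = coords, atoms = atoms)
}

# Amide H reconstructed on N(i) from C(i-1), N(i), CA(i): along the
# bisector pointing away from both bonded neighbours, N-H = 1.01 A.
reconstruct_amide_h <- function(n_xyz, ca_xyz, c_prev_xyz) {
  u1 <- n_xyz - c_prev_xyz; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- n_xyz - ca_xyz; u2 <- u2 / sqrt(sum(u2^2))
  h_dir <- u1 + u2; h_dir <- h_dir / sqrt(sum(h_dir^2))
  n_xyz + 1.01 * h_dir
}

#' Simplified secondary-structure assignment (H / E / C)
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
#' model E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol
#' between the N-H of a donor residue and the C=O of an acceptor residue;
#' a bond exists iff E < -0.5 kcal/mol. Amide H positions are reconstructed
#' from N, CA and the previous C when not provided. A residue is labeled:
#' * `H` when inside an i -> i+4 bonded run of length >= 2 (two consecutive
#'   helical turns),
#' * `E` when it forms a bridge (antiparallel or parallel ladder pattern)
#'   with a residue at sequence separation >= 3,
#' * `C` otherwise. H takes precedence over E.
#'
#' This is a deliberately simplified three-state variant of full 8-state
#' DSSP.
#'
#' @param coords M x 3 coordinate matrix covering the backbone atoms.
#' @param atoms Atom metadata tibble (`name`, `resid`) aligned with
#'   `coords`; names N, CA, C, O are used, H when present.
#' @param strict Fatal error on residues with missing backbone atoms
#'   (default FALSE: labeled C with a warning).
#' @return Character vector of per-residue labels, named by residue id.
#' @export
secondary_structure_simple <- function(coords, atoms, strict = FALSE) {
  coords <- as.matrix(coords)
  resids <- sort(unique(atoms$resid))
  nr <- length(resids)
  get_atom <- function(res, nm) {
    i <- which(atoms$resid == res & atoms$name == nm)
    if (length(i) == 0) NULL else coords[i[1], ]
  }
  bb <- lapply(resids, function(r)
    list(N = get_atom(r, "N"), CA = get_atom(r, "CA"),
         C = get_atom(r, "C"), O = get_atom(r, "O"), H = get_atom(r, "H")))
  complete <- vapply(bb, function(x)
    !is.null(x$N) && !is.null(x$CA) && !is.null(x$C) && !is.null(x$O),
    logical(1))
  if (any(!complete)) {
    msg <- paste("incomplete backbone for residue(s):",
                 paste(resids[!complete], collapse = ", "))
    if (strict) abort_confunnel(msg, "incomplete_residue")
    warning(paste(msg, "- labeled C"))
  }
  # reconstruct amide H where absent (never for the N-terminal residue)
  for (i in seq_len(nr)) {
    if (i > 1 && complete[i] && complete[i - 1] && is.null(bb[[i]]$H)) {
      bb[[i]]$H <- reconstruct_amide_h(bb[[i]]$N, bb[[i]]$CA, bb[[i - 1]]$C)
    }
  }
  ks_energy <- function(don, acc) {
    # donor N-H vs acceptor C=O
    r <- function(p, q) sqrt(sum((p - q)^2))
    0.084 * 332 * (1 / r(acc$O, don$N) + 1 / r(acc$C, don$H) -
                   1 / r(acc$O, don$H) - 1 / r(acc$C, don$N))
  }
  hb <- matrix(FALSE, nr, nr)  # hb[i, j]: N-H of residue i donates to C=O of j
  for (i in seq_len(nr)) {
    if (!complete[i] || is.null(bb[[i]]$H)) next
    for (j in seq_len(nr)) {
      if (abs(i - j) < 2 || !complete[j]) next
      if (ks_energy(bb[[i]], bb[[j]]) < -0.5) hb[i, j] <- TRUE
    }
  }
  labels <- rep("C", nr)
  # helix: two consecutive i -> i+4 turns cover residues i+1 .. i+4
  turn <- rep(FALSE, nr)
  for (i in seq_len(max(0, nr - 4))) turn[i] <- hb[i + 4, i]
  for (i in seq_len(max(0, nr - 5))) {
    if (turn[i] && turn[i + 1]) labels[(i + 1):(i + 4)] <- "H"
  }
  # strand bridges (DSSP ladder patterns), sequence separation >= 3
  at <- function(m, i, j) i >= 1 && j >= 1 && i <= nr && j <= nr && m[i, j]
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      if (abs(i - j) < 3) next
      anti <- (at(hb, i, j) && at(hb, j, i)) ||
        (at(hb, i - 1, j + 1) && at(hb, j - 1, i + 1))
      para <- (at(hb, j, i - 1) && at(hb, i + 1, j)) ||
        (at(hb, i, j - 1) && at(hb, j + 1, i))
      if ((anti || para) && labels[i] != "H") labels[i] <- "E"
    }
  }
  labels[!complete] <- "C"
  stats::setNames(labels, resids)
}
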