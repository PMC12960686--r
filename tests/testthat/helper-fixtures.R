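# Shared fixtures, built in code.

# A hand-built single-member conformal ensemble with a stub classifier whose
# predicted P(active) is a fixed function of the first feature value; used
# to exercise the p-value machinery independently of any real learner.
stub_ensemble <- function(calib_alpha1, calib_alpha0, prob_fun) {
  classifier <- list(
    fit = function(x, y) NULL,
    predict_prob = function(model, x) prob_fun(x))
  structure(list(
    members = list(list(model = NULL, seed = 1L,
                        calib_alpha0 = sort(calib_alpha0),
                        calib_alpha1 = sort(calib_alpha1))),
    classifier = classifier, calib_fraction = 0.2, base_seed = 1L,
    epsilon = NA_real_), class = "conformal_ensemble")
}

# Fast base classifier for pipeline-level tests.
fast_gbt <- function() classifier_gbt(nrounds = 25L, max_depth = 3L)

# Small trajectory around a fixed template cloud.
toy_trajectory <- function(coords_list, element = "C") {
  nf <- length(coords_list)
  na_ <- nrow(coords_list[[1]])
  arr <- array(NA_real_, c(nf, na_, 3))
  for (f in seq_len(nf)) arr[f, , ] <- coords_list[[f]]
  trajectory(arr, tibble::tibble(name = "CA", element = element,
                                 resid = seq_len(na_), resname = "GLY",
                                 chain = "A"))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Dihedral angle (degrees) of four points, standard sign convention.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Antiparallel two-strand backbone fixture (extended strands, second strand
# rotated 180 degrees about z and offset so inter-strand H-bonds form).
antiparallel_sheet <- function() {
  s <- build_peptide_backbone(5, phi = -139, psi = 135)
  rot <- diag(c(-1, -1, 1))
  b <- sweep(s$coords %*% rot, 2, c(9.25, 5.2, 0), "+")
  atoms_b <- s$atoms
  atoms_b$resid <- atoms_b$resid + 5L
  list(coords = rbind(s$coords, b), atoms = rbind(s$atoms, atoms_b))
}
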