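# DCCM and free-energy landscape.

test_that("DCCM recovers constructed correlation and anti-correlation", {
  # two atoms translated identically each frame: perfectly correlated
  base <- rbind(c(0, 0, 0), c(10, 0, 0))
  frames <- lapply(c(-1, 0.5, 2, -0.7), function(d) base + d)
  c_same <- dccm(toy_trajectory(frames), fit = FALSE)
  expect_equal(c_same[1, 2], 1, tolerance = 1e-12)
  # exact anti-phase motion along x
  anti <- lapply(c(-1, 0.5, 2, -0.7), function(d)
    rbind(c(d, 0, 0), c(10 - d, 0, 0)))
  c_anti <- dccm(toy_trajectory(anti), fit = FALSE)
  expect_equal(c_anti[1, 2], -1, tolerance = 1e-12)
})

test_that("DCCM is symmetric, unit-diagonal and bounded", {
  traj <- generate_trajectory(trajectory_config(40, 8, "harmonic",
                                                amplitudes = 0.6, seed = 10))
  cij <- dccm(traj)
  expect_equal(cij, t(cij), tolerance = 1e-12)
  expect_equal(unname(diag(cij)), rep(1, 8))
  expect_true(all(abs(cij) <= 1 + 1e-12))
  expect_error(dccm(toy_trajectory(list(diag(3), diag(3)))),
               class = "insufficient_frames")
})

test_that("DCCM agrees with bio3d on a fitted trajectory", {
  traj <- generate_trajectory(trajectory_config(60, 6, "harmonic",
                                                amplitudes = 0.5, seed = 11))
  ours <- dccm(traj, fit = TRUE)
  xyz <- t(vapply(seq_len(60), function(f)
    as.numeric(t(matrix(traj$coords[f, , ], ncol = 3))), numeric(18)))
  fitted <- suppressWarnings(bio3d::fit.xyz(xyz[1, ], xyz))
  theirs <- suppressWarnings(unclass(bio3d::dccm(fitted)))
  expect_equal(unclass(ours), theirs, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("DCCM with fitting is invariant to a global rotation of the copy", {
  traj <- generate_trajectory(trajectory_config(30, 7, "harmonic",
                                                amplitudes = 0.4, seed = 12))
  rot <- rotation_z(63)
  rotated <- traj
  for (f in seq_len(30)) {
    rotated$coords[f, , ] <- matrix(traj$coords[f, , ], ncol = 3) %*% t(rot)
  }
  expect_equal(dccm(traj, fit = TRUE), dccm(rotated, fit = TRUE),
               tolerance = 1e-6)
})

test_that("a motionless atom yields an NA row with a warning", {
  frames <- lapply(c(0, 1, 2, 3), function(d)
    rbind(c(d, 0, 0), c(5, 5, 5), c(0, d, 0)))
  expect_warning(cij <- dccm(toy_trajectory(frames), fit = FALSE),
                 "zero fluctuation")
  expect_true(all(is.na(cij[2, c(1, 3)])))
  expect_equal(cij[1, 1], 1)
})

test_that("free-energy landscape normalizes to its occupied minimum", {
  # all frames in one bin
  traj <- generate_trajectory(trajectory_config(40, 6, "harmonic",
                                                amplitudes = 0.3, seed = 13))
  one_bin <- free_energy_landscape(traj, cv = matrix(0.5, 40, 2), bins = 4)
  fe <- one_bin$free_energy
  expect_equal(sum(!is.na(fe)), 1)
  expect_equal(fe[!is.na(fe)], 0)
  # PCA route: occupied minimum exactly 0
  fel <- free_energy_landscape(traj, bins = 6)
  expect_equal(min(fel$free_energy, na.rm = TRUE), 0)
  expect_true(all(fel$free_energy >= 0, na.rm = TRUE))
})

test_that("a 75/25 two-state occupancy gives a kT ln 3 barrier", {
  cv <- rbind(matrix(0, 75, 2), matrix(10, 25, 2))
  traj <- generate_trajectory(trajectory_config(100, 5, "harmonic", seed = 14))
  fel <- free_energy_landscape(traj, cv = cv, bins = 4, temperature = 310)
  vals <- sort(unique(fel$free_energy[!is.na(fel$free_energy)]))
  kt <- 8.314462618e-3 * 310
  expect_equal(vals, c(0, kt * log(3)), tolerance = 1e-9)
  expect_equal(kt * log(3), 2.832, tolerance = 1e-3)
  # invariant to frame order
  perm <- withr::with_seed(15, sample(100))
  fel2 <- free_energy_landscape(traj, cv = cv[perm, ], bins = 4,
                                temperature = 310)
  expect_equal(fel$free_energy, fel2$free_energy)
})

test_that("degenerate covariance is rejected for the PCA projection", {
  static <- toy_trajectory(rep(list(matrix(rnorm(18), 6, 3)), 12))
  expect_error(free_energy_landscape(static, bins = 4),
               class = "degenerate_pca")
})

test_that("FEL CSV export is long-format with masked unvisited bins", {
  cv <- rbind(matrix(0, 30, 2), matrix(10, 10, 2))
  traj <- generate_trajectory(trajectory_config(40, 5, "harmonic", seed = 16))
  fel <- free_energy_landscape(traj, cv = cv, bins = 4)
  path <- tempfile(fileext = ".csv")
  write_fel_csv(fel, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$count), 40)
  expect_true(all(is.na(tab$F_kJmol[tab$count == 0])))
  unlink(path)
})
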