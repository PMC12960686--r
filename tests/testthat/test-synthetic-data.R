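# Generators: determinism, planted-signal statistics, oracle formula,
# trajectory motion modes.

test_that("library generation rejects invalid configurations", {
  expect_error(library_config(0), class = "invalid_config")
  expect_error(library_config(10, planted_bits = c(1, 1)), class = "invalid_config")
  expect_error(library_config(10, planted_bits = 1024), class = "invalid_config")
  expect_error(library_config(10, bit_density = 0), class = "invalid_config")
})

test_that("library generation is deterministic and internally consistent", {
  cfg <- library_config(100, seed = 7)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1$compounds, lib2$compounds)
  expect_identical(as.matrix(lib1$fingerprints), as.matrix(lib2$fingerprints))
  fp <- as.matrix(lib1$fingerprints)
  expect_true(all(fp %in% c(0, 1)))
  expect_equal(dim(fp), c(100, 1024))
  expect_true(all(lib1$compounds$hac >= 15 & lib1$compounds$hac <= 30))
  # sidecar ground truth recoverable from the fingerprints themselves
  expect_equal(lib1$truth$n_planted_bits,
               unname(rowSums(fp[, cfg$planted_bits + 1])))
})

test_that("planted-bit counts follow the binomial expectation", {
  lib <- generate_library(library_config(10000, seed = 3))
  # 8 planted bits at prevalence 0.10: mean count 0.8, binomial SE
  se <- sqrt(8 * 0.1 * 0.9 / 10000)
  expect_lt(abs(mean(lib$truth$n_planted_bits) - 0.8), 3 * se)
})

test_that("docking oracle reproduces its score formula with noise off", {
  quiet <- oracle_config(sigma_compound = 0, sigma_conformer = 0)
  r0 <- docking_oracle("A", n_conformers = 5, config = quiet, n_planted = 0)
  expect_equal(r0$conformer_scores, rep(-6.0, 5))
  expect_equal(r0$best_score, -6.0)
  r4 <- docking_oracle("A", n_conformers = 3, config = quiet, n_planted = 4)
  expect_equal(r4$best_score, -8.0)
  expect_error(docking_oracle("A", n_conformers = 0, config = quiet, n_planted = 0),
               class = "invalid_config")
  expect_error(docking_oracle("A", n_conformers = 2, config = quiet),
               class = "missing_feature")
})

test_that("oracle scores are deterministic and independent of scoring order", {
  cfg <- oracle_config(seed = 5)
  a1 <- docking_oracle("X9", n_conformers = 10, config = cfg, n_planted = 2)
  # score other compounds in between; X9 must be unchanged
  for (id in c("B", "C", "D")) docking_oracle(id, n_conformers = 3, config = cfg,
                                              n_planted = 1)
  a2 <- docking_oracle("X9", n_conformers = 10, config = cfg, n_planted = 2)
  expect_identical(a1$conformer_scores, a2$conformer_scores)
})

test_that("more conformers stochastically deepen the optimal score", {
  lib <- generate_library(library_config(1000, seed = 2))
  cfg <- oracle_config(seed = 9)
  b1 <- score_library(lib, 1, cfg)$best_score
  b50 <- score_library(lib, 50, cfg)$best_score
  # nested conformer streams: per-compound minimum can only improve
  expect_true(all(b50 <= b1))
  expect_lt(mean(b50), mean(b1))
})

test_that("ADMET profile generation honours pass rates", {
  ids <- sprintf("C%03d", 1:200)
  all_pass <- generate_admet_profiles(ids, 1.0, seed = 1)
  expect_equal(length(apply_admet_filter(all_pass)$passing_ids), 200)
  rates <- stats::setNames(rep(1.0, 13), admet_endpoints())
  rates["DILI"] <- 0.0
  none <- generate_admet_profiles(ids, rates, seed = 1)
  expect_equal(length(apply_admet_filter(none)$passing_ids), 0)
  expect_error(generate_admet_profiles(ids, c(bogus = 0.5), seed = 1),
               class = "schema_error")
})

test_that("joint ADMET pass counts follow the product of Bernoulli rates", {
  # per-endpoint rate chosen so the 13-endpoint joint pass probability is
  # ~0.003, the stringency at which 12,000 profiles leave a few dozen
  rate <- 0.003^(1 / 13)
  ids <- sprintf("C%05d", 1:12000)
  prof <- generate_admet_profiles(ids, rate, seed = 4)
  n_pass <- length(apply_admet_filter(prof)$passing_ids)
  se <- sqrt(12000 * 0.003 * 0.997)
  expect_lt(abs(n_pass - 36), 3 * se)
})

test_that("trajectory modes realize their advertised motion", {
  expect_error(trajectory_config(1, 5), class = "invalid_config")
  rigid <- generate_trajectory(trajectory_config(8, 20, "rigid", seed = 1))
  expect_true(all(rmsd_series(rigid, fit = TRUE)$rmsd <= 1e-8))
  expect_equal(dim(rigid$coords), c(8, 20, 3))

  harm <- generate_trajectory(trajectory_config(2000, 10, "harmonic",
                                                amplitudes = 0.7, seed = 2))
  rf <- rmsf(harm, fit = FALSE)$rmsf
  # isotropic Gaussian displacement of sd a per axis: RMSF = a * sqrt(3)
  expect_true(all(abs(rf - 0.7 * sqrt(3)) / (0.7 * sqrt(3)) < 0.05))

  drift <- generate_trajectory(trajectory_config(30, 15, "drift",
                                                 drift_rate = 0.02, seed = 3))
  rg <- rg_series(drift)$Rg
  expect_true(all(diff(rg) > 0))
})

test_that("library CSV round-trips records and fingerprints", {
  lib <- generate_library(library_config(20, seed = 11))
  path <- tempfile(fileext = ".csv")
  truth_path <- tempfile(fileext = ".csv")
  write_library_csv(lib, path, truth_path)
  back <- read_library_csv(path)
  expect_equal(back$compounds$id, lib$compounds$id)
  expect_equal(back$compounds$hac, lib$compounds$hac)
  expect_equal(as.matrix(back$fingerprints), as.matrix(lib$fingerprints),
               ignore_attr = TRUE)
  truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  expect_equal(truth$n_planted_bits, lib$truth$n_planted_bits)
  unlink(c(path, truth_path))
})
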