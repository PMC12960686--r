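# Lead-like filtering, fingerprint handling, optimal-score extraction,
# conformer-count sensitivity.

test_that("lead-like filter applies inclusive bounds and logs reasons", {
  tab <- tibble::tibble(id = c("a", "b", "c", "d", "e"),
                        hac = c(20L, 26L, 25L, 19L, 22L),
                        clogp = c(3.5, 0.0, -5.0, 1.0, 3.6))
  res <- filter_leadlike(tab)
  expect_equal(res$retained$id, c("a", "c"))
  expect_equal(res$rejected$reason[res$rejected$id == "b"], "hac")
  expect_equal(res$rejected$reason[res$rejected$id == "e"], "clogp")
  expect_error(filter_leadlike(tibble::tibble(id = "x", hac = NA, clogp = 1)),
               class = "missing_property")
})

test_that("lead-like retention matches the analytic expectation", {
  n <- 100000
  tab <- withr::with_seed(1, tibble::tibble(
    id = as.character(seq_len(n)),
    hac = sample(15:30, n, replace = TRUE),
    clogp = rnorm(n, 2.0, 2.5)))
  frac <- nrow(filter_leadlike(tab)$retained) / n
  p_expect <- (6 / 16) * (pnorm((3.5 - 2) / 2.5) - pnorm((-5 - 2) / 2.5))
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(frac - p_expect), 3 * se)
})

test_that("lead-like filter is idempotent", {
  lib <- generate_library(library_config(500, seed = 5))
  once <- filter_leadlike(lib$compounds)$retained
  twice <- filter_leadlike(once)$retained
  expect_identical(once, twice)
})

test_that("featurize passes stored fingerprints through and validates shape", {
  fp <- rep(c(0L, 1L), length.out = 1024)
  expect_identical(featurize(list(fingerprint = fp)), fp)
  expect_error(featurize(list(fingerprint = fp[1:100])), class = "feature_shape")
  expect_error(featurize(list(smiles = "CCO")),
               class = "featurization_unavailable")
  expect_error(featurize(list()), class = "featurization_unavailable")
})

test_that("RDKit backend computes deterministic 1024-bit circular fingerprints", {
  backend <- fp_backend_rdkit()
  bits <- backend(c("CCO", "c1ccccc1O", "CCO"), 1024L)
  expect_equal(dim(bits), c(3, 1024))
  expect_true(all(bits %in% c(0L, 1L)))
  expect_identical(bits[1, ], bits[3, ])       # same SMILES, same bits
  expect_false(identical(bits[1, ], bits[2, ]))
  expect_gt(sum(bits[2, ]), 0)
  expect_error(backend("not_a_smiles((", 1024L), class = "parse_error")
})

test_that("best score is the minimum conformer score", {
  expect_equal(best_score(c(-7.1, -7.5, -6.9)), -7.5)
  expect_equal(best_score(-8.0), -8.0)
  expect_error(best_score(numeric(0)), class = "empty_input")
  # appending a conformer can only keep or lower the optimum
  withr::with_seed(1, {
    for (i in 1:20) {
      s <- rnorm(10, -7)
      expect_lte(best_score(c(s, rnorm(1, -7))), best_score(s) + 1e-12)
    }
  })
})

test_that("paired t statistic matches hand computation and stats::t.test", {
  x <- c(1, 2, 3, 4, 5)
  y <- x; y[1] <- y[1] - 0.1
  res <- paired_t_test(x, y)
  expect_gt(res$t, 0)
  expect_equal(res$t, 0.02 / (sd(x - y) / sqrt(5)))
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  same <- paired_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
})

test_that("conformer sensitivity detects (only) conformer-level noise", {
  lib <- generate_library(library_config(300, seed = 8))
  quiet <- oracle_config(sigma_conformer = 0, seed = 2)
  res0 <- conformer_sensitivity(lib, quiet, counts = c(1, 10, 50),
                                n_compounds = 100, seed = 3)
  expect_equal(diff(res0$summary$mean_best), c(0, 0))
  expect_true(all(res0$comparisons$p_value == 1))

  noisy <- oracle_config(sigma_conformer = 0.3, seed = 2)
  res1 <- conformer_sensitivity(lib, noisy, counts = c(1, 10, 100),
                                n_compounds = 200, seed = 3)
  expect_true(all(diff(res1$summary$mean_best[order(res1$summary$k)]) < 0))
  expect_error(conformer_sensitivity(lib, noisy, counts = c(5, 5),
                                     n_compounds = 10), class = "invalid_config")
  expect_error(conformer_sensitivity(lib, noisy, counts = 5, n_compounds = 1),
               class = "insufficient_sample")
})
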