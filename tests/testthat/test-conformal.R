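# Aggregated Mondrian conformal prediction: labeling, p-values, regions,
# threshold selection, metrics, ranking.

test_that("active labeling takes the top quantile with deterministic ties", {
  lab <- label_actives(c(-10, -5, -1), c("a", "b", "c"), q = 1 / 3)
  expect_equal(lab$active_ids, "a")
  expect_equal(lab$threshold, -10)
  lab200 <- label_actives(rnorm(200, -7), q = 0.01)
  expect_equal(lab200$k, 2)
  expect_equal(sum(lab200$labels), 2)
  tie <- label_actives(rep(-7, 100), sprintf("id%03d", 100:1), q = 0.01)
  expect_equal(tie$active_ids, "id001")
  expect_error(label_actives(c(-1, -2), q = 1.5), class = "invalid_quantile")
})

test_that("conformal p-values match the counting formula at its boundaries", {
  ens <- stub_ensemble(calib_alpha1 = c(0.10, 0.20, 0.30, 0.40),
                       calib_alpha0 = c(0.5, 0.6),
                       prob_fun = function(x) x[, 1])
  # prob1 = 0.75 -> alpha1_new = 0.25: 2 of 4 calib alphas >= 0.25
  p <- predict_p(ens, matrix(0.75, 1, 1))
  expect_equal(p$p1, (2 + 1) / (4 + 1))
  # prob1 = 1 -> alpha_new = 0, smaller than all: p = 1
  expect_equal(predict_p(ens, matrix(1, 1, 1))$p1, 1.0)
  # prob1 = 0.5 -> alpha_new = 0.5 larger than all calib: p = 1/(n+1)
  expect_equal(predict_p(ens, matrix(0.5, 1, 1))$p1, 1 / 5)
  # tie counts as >=
  expect_equal(predict_p(ens, matrix(1 - 0.20, 1, 1))$p1, (3 + 1) / 5)
})

test_that("p-values are monotone non-increasing in the nonconformity score", {
  ens <- stub_ensemble(calib_alpha1 = runif(50), calib_alpha0 = runif(50),
                       prob_fun = function(x) x[, 1])
  probs <- seq(0.99, 0.01, by = -0.01)   # alpha1_new increases along this
  p1 <- predict_p(ens, matrix(probs, ncol = 1))$p1
  expect_true(all(diff(p1) <= 0))
})

test_that("ensemble training yields disjoint stratified splits, deterministically", {
  lib <- generate_library(library_config(1000, seed = 21))
  y <- as.integer(seq_len(1000) <= 100)
  ens <- train_acp(lib$fingerprints, y, n_models = 3, base_seed = 4,
                   classifier = fast_gbt())
  for (m in ens$members) {
    expect_equal(length(m$calib_alpha0) + length(m$calib_alpha1), 200)
    expect_equal(length(m$calib_alpha1), 20)  # stratified 20% of 100 actives
  }
  ens2 <- train_acp(lib$fingerprints, y, n_models = 3, base_seed = 4,
                    classifier = fast_gbt())
  expect_identical(lapply(ens$members, `[[`, "calib_alpha1"),
                   lapply(ens2$members, `[[`, "calib_alpha1"))
  expect_error(train_acp(lib$fingerprints, rep(1L, 1000)),
               class = "degenerate_split")
})

test_that("a single-bit rule is learned to low nonconformity", {
  lib <- generate_library(library_config(600, seed = 22))
  fp <- as.matrix(lib$fingerprints)
  y <- fp[, 5]  # label IS bit 5
  ens <- train_acp(fp, y, n_models = 2, base_seed = 1, classifier = fast_gbt())
  for (m in ens$members) {
    expect_true(all(m$calib_alpha0 < 0.5))
    expect_true(all(m$calib_alpha1 < 0.5))
  }
})

test_that("region classification partitions all inputs per the epsilon rule", {
  eps <- 0.143
  expect_equal(classify_region(0.05, 0.90, eps), "active")
  expect_equal(classify_region(0.90, 0.90, eps), "both")
  expect_equal(classify_region(0.05, 0.05, eps), "null")
  expect_equal(classify_region(0.90, 0.05, eps), "inactive")
  grid <- expand.grid(p0 = seq(0.01, 1, by = 0.07), p1 = seq(0.01, 1, by = 0.07))
  regions <- classify_region(grid$p0, grid$p1, eps)
  expect_true(all(regions %in% c("active", "inactive", "both", "null")))
  # monotone region growth: smaller epsilon never shrinks {active, both}
  for (e2 in c(0.05, 0.01)) {
    r2 <- classify_region(grid$p0, grid$p1, e2)
    was_pos <- regions %in% c("active", "both")
    now_pos <- r2 %in% c("active", "both")
    expect_true(all(now_pos[was_pos]))
  }
})

test_that("epsilon selection maximizes TPR with smallest-epsilon ties", {
  preds <- tibble::tibble(p0 = c(rep(0.01, 10), rep(1.0, 20)),
                          p1 = c(rep(1.0, 10), rep(0.01, 20)))
  y <- c(rep(1, 10), rep(0, 20))
  sel <- select_epsilon(preds, y)
  expect_equal(sel$epsilon, 0.010)  # smallest grid value with p0 <= eps
  expect_equal(max(sel$curves$tpr), 1)
  # nothing exceeds a threshold above every p1
  low <- tibble::tibble(p0 = rep(0.2, 5), p1 = rep(0.3, 5))
  sel2 <- select_epsilon(low, rep(1, 5))
  expect_equal(sel2$curves$tpr[sel2$curves$epsilon == 0.4], 0)
  expect_error(select_epsilon(preds, rep(0, 30)), class = "undefined_tpr")
})

test_that("screening metrics reproduce hand-counted confusion and AUC", {
  # positives: rows 1, 2, 4 via region; labels 1 1 1 0 0
  preds <- tibble::tibble(
    compound_id = letters[1:5],
    p0 = c(0.05, 0.05, 0.90, 0.05, 0.90),
    p1 = c(0.90, 0.90, 0.05, 0.90, 0.05))
  preds$delta_p <- preds$p1 - preds$p0
  m <- evaluate_screen(preds, c(1, 1, 1, 0, 0), epsilon = 0.143)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(2, 1, 1, 1))
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 3)

  auc_preds <- tibble::tibble(compound_id = letters[1:4],
                              p0 = rep(0.5, 4), p1 = rep(0.5, 4),
                              delta_p = c(0.9, 0.8, 0.3, 0.1))
  m2 <- evaluate_screen(auc_preds, c(1, 0, 1, 0), epsilon = 0.143)
  expect_equal(m2$roc_auc, 0.75)  # 3 of 4 discordant-free pairs
  expect_error(evaluate_screen(preds, c(1, 1, 1, 0), epsilon = 0.1),
               class = "alignment_error")
})

test_that("rank-based AUC agrees with pROC on random data", {
  withr::with_seed(9, {
    score <- rnorm(200)
    y <- as.integer(runif(200) < plogis(score))
  })
  ours <- confunnel:::roc_auc_rank(score, y)
  ref <- suppressMessages(as.numeric(pROC::auc(y, score, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ranking sorts by delta_p with id tie-breaks and flags truncation", {
  preds <- tibble::tibble(
    compound_id = c("c3", "c1", "c2", "c4"),
    delta_p = c(0.10, 0.99, 0.50, 0.50),
    region = c("active", "active", "active", "inactive"))
  top2 <- rank_and_select(preds, 2)
  expect_equal(top2$compound_id, c("c1", "c2"))
  tie <- rank_and_select(tibble::tibble(compound_id = c("b", "a"),
                                        delta_p = c(0.5, 0.5),
                                        region = "active"), 2)
  expect_equal(tie$compound_id, c("a", "b"))
  expect_warning(all3 <- rank_and_select(preds, 10), "only 3")
  expect_true(attr(all3, "truncated"))
  expect_equal(nrow(all3), 3)
  expect_error(rank_and_select(preds, 0), class = "invalid_k")
})

test_that("correlation diagnostics recover exact linear relations", {
  res <- correlation_diagnostics(c(0.9, 0.5, 0.1), c(-9, -8, -7))
  expect_equal(res$r, c(-1, -1))
  expect_error(correlation_diagnostics(rep(0.5, 5), rnorm(5)),
               class = "undefined_correlation")
  expect_error(correlation_diagnostics(c(1, 2), c(1, 2)),
               class = "invalid_config")
})

test_that("Mondrian class-conditional validity holds on an exchangeable screen", {
  lib <- generate_library(library_config(6000, seed = 31))
  scores <- score_library(lib, 10, oracle_config(seed = 32))
  lab <- label_actives(scores$best_score, scores$compound_id, 0.02)
  split <- withr::with_seed(33, sample(6000, 2500))
  ens <- train_acp(lib$fingerprints[split, ], lab$labels[split],
                   base_seed = 34, classifier = fast_gbt())
  test_idx <- setdiff(seq_len(6000), split)
  pr <- predict_p(ens, lib$fingerprints[test_idx, ])
  y <- lab$labels[test_idx]
  for (eps in c(0.05, 0.1, 0.143, 0.2)) {
    for (cl in 0:1) {
      p_true <- if (cl == 1) pr$p1[y == 1] else pr$p0[y == 0]
      err <- mean(p_true <= eps)
      bound <- eps + 3 * sqrt(eps * (1 - eps) / length(p_true))
      expect_lte(err, bound)
    }
  }
})

test_that("cross-validated diagnostics report finite fold summaries", {
  lib <- generate_library(library_config(800, seed = 41))
  scores <- score_library(lib, 5, oracle_config(seed = 42))
  lab <- label_actives(scores$best_score, scores$compound_id, 0.05)
  cv <- acp_cross_validate(lib$fingerprints, lab$labels, epsilon = 0.143,
                           n_folds = 3, seed = 43, n_models = 2,
                           classifier = fast_gbt())
  expect_equal(sort(cv$metric), sort(c("recall", "precision", "roc_auc")))
  expect_true(all(is.finite(cv$mean)))
})
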