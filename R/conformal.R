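# Aggregated Mondrian (class-conditional) inductive conformal prediction
# over a docking-score surrogate classifier.

#' Label computational actives from docking scores
#'
#' The top fraction `q` (default 1%) of compounds by docking score — the
#' most negative scores — are labeled active (1). k = max(1, floor(q * n));
#' ties at the threshold are broken by ascending compound id so labeling is
#' deterministic. The realized score threshold (the k-th lowest score) is
#' reported.
#'
#' @param best_scores Numeric vector of optimal docking scores (kcal/mol).
#' @param ids Compound ids aligned with `best_scores`.
#' @param q Active fraction in (0, 1), default 0.01.
#' @return List: `labels` (0/1 integer aligned with input), `threshold`
#'   (kcal/mol), `k`, `active_ids`.
#' @export
label_actives <- function(best_scores, ids = NULL, q = 0.01) {
  if (length(best_scores) == 0 || !all(is.finite(best_scores))) {
    abort_confunnel("`best_scores` must be non-empty and finite", "invalid_config")
  }
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort_confunnel("`q` must lie in (0, 1)", "invalid_quantile")
  }
  n <- length(best_scores)
  if (is.null(ids)) ids <- sprintf("C%07d", seq_len(n))
  k <- max(1L, floor(q * n))
  ord <- order(best_scores, ids)
  active_idx <- ord[seq_len(k)]
  labels <- integer(n)
  labels[active_idx] <- 1L
  list(labels = labels, threshold = best_scores[ord[k]], k = k,
       active_ids = ids[active_idx])
}

#' Gradient-boosted tree base classifier
#'
#' The default pluggable base learner for [train_acp()]: binary logistic
#' gradient boosting with class-weight balancing (`scale_pos_weight` =
#' n_negative / n_positive) and ROC-AUC as the internal evaluation metric.
#' Any object with `fit(x, y) -> model` and `predict_prob(model, x) ->
#' P(class 1)` works in its place.
#'
#' @param nrounds Boosting rounds (default 60).
#' @param max_depth Tree depth (default 4).
#' @param eta Learning rate (default 0.3).
#' @param nthread Threads (default 1, for reproducibility).
#' @return A classifier interface list.
#' @export
classifier_gbt <- function(nrounds = 60L, max_depth = 4L, eta = 0.3,
                           nthread = 1L) {
  as_dmat <- function(x, label = NULL) {
    if (inherits(x, "Matrix")) x <- methods::as(x, "CsparseMatrix")
    if (is.null(label)) xgboost::xgb.DMatrix(x, nthread = nthread)
    else xgboost::xgb.DMatrix(x, label = label, nthread = nthread)
  }
  list(
    fit = function(x, y) {
      spw <- sum(y == 0) / max(1, sum(y == 1))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eval_metric = "auc",
                      max_depth = max_depth, eta = eta,
                      scale_pos_weight = spw, nthread = nthread,
                      seed = 0),
        data = as_dmat(x, y), nrounds = nrounds, verbose = 0)
    },
    predict_prob = function(model, x) {
      as.numeric(stats::predict(model, as_dmat(x)))
    })
}

# Stratified proper-train / calibration split; returns calibration indices.
stratified_calib_split <- function(labels, calib_fraction, seed) {
  with_seed(seed, {
    calib <- integer(0)
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      n_cal <- max(1L, round(calib_fraction * length(idx)))
      if (length(idx) - n_cal < 1) {
        abort_confunnel(sprintf("class %d too small for a calibration split", cl),
                        "degenerate_split")
      }
      calib <- c(calib, sample(idx, n_cal))
    }
    sort(calib)
  })
}

#' Train an aggregated Mondrian conformal ensemble
#'
#' Trains `n_models` (default 5) independent inductive conformal predictors.
#' Each member stratifies the labeled data into a proper-training set
#' (1 - `calib_fraction`) and a calibration set (`calib_fraction`, default
#' 20%) with seed `base_seed + m`, fits the base classifier on the
#' proper-training set, and stores per-class calibration nonconformity
#' multisets with alpha = 1 - P_hat(true class). Calibration is Mondrian
#' (class-conditional), so validity holds within each class.
#'
#' @param features n x p 0/1 matrix (dense or sparse).
#' @param labels 0/1 integer vector.
#' @param n_models Ensemble size (default 5).
#' @param calib_fraction Calibration fraction (default 0.2).
#' @param base_seed Integer; member m uses seed `base_seed + m`.
#' @param classifier Base classifier interface (default [classifier_gbt()]).
#' @return A `conformal_ensemble` object.
#' @export
train_acp <- function(features, labels, n_models = 5L, calib_fraction = 0.2,
                      base_seed = 1L, classifier = classifier_gbt()) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2) {
    abort_confunnel("labels must contain both classes 0 and 1", "degenerate_split")
  }
  if (nrow(features) != length(labels)) {
    abort_confunnel("features/labels length mismatch", "alignment_error")
  }
  members <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    seed_m <- base_seed + m
    calib_idx <- stratified_calib_split(labels, calib_fraction, seed_m)
    train_idx <- setdiff(seq_along(labels), calib_idx)
    model <- classifier$fit(features[train_idx, , drop = FALSE], labels[train_idx])
    prob1 <- classifier$predict_prob(model, features[calib_idx, , drop = FALSE])
    y_cal <- labels[calib_idx]
    alpha_true <- ifelse(y_cal == 1L, 1 - prob1, prob1)
    members[[m]] <- list(
      model = model, seed = seed_m, calib_idx = calib_idx,
      calib_alpha0 = sort(alpha_true[y_cal == 0L]),
      calib_alpha1 = sort(alpha_true[y_cal == 1L]))
  }
  structure(list(members = members, classifier = classifier,
                 calib_fraction = calib_fraction, base_seed = base_seed,
                 epsilon = NA_real_),
            class = "conformal_ensemble")
}

#' @export
print.conformal_ensemble <- function(x, ...) {
  n1 <- length(x$members[[1]]$calib_alpha1)
  n0 <- length(x$members[[1]]$calib_alpha0)
  cat(sprintf("<conformal_ensemble> %d members, calibration %d active / %d inactive per member, epsilon = %s\n",
              length(x$members), n1, n0,
              ifelse(is.na(x$epsilon), "unset", format(x$epsilon))))
  invisible(x)
}

# #{sorted_alpha >= a} for each query a, via findInterval on the sorted
# calibration multiset.
count_geq <- function(sorted_alpha, a) {
  length(sorted_alpha) - findInterval(a, sorted_alpha, left.open = TRUE)
}

# Deterministic Mondrian p-value: (#{alpha_cal >= alpha_new} + 1) / (n + 1).
conformal_p <- function(sorted_alpha, alpha_new) {
  (count_geq(sorted_alpha, alpha_new) + 1) / (length(sorted_alpha) + 1)
}

#' Conformal p-values for new compounds
#'
#' For each ensemble member and class c, the nonconformity of a new
#' fingerprint is alpha_new = 1 - P_hat(c | fingerprint); the member's
#' class-c p-value is (#\{calibration alpha_c >= alpha_new\} + 1) /
#' (n_c + 1). Member p-values are aggregated by the median (configurable to
#' mean); delta_p = p1 - p0 is the ranking confidence margin.
#'
#' @param ensemble A trained [train_acp()] ensemble.
#' @param features m x p matrix of fingerprints (single vectors are accepted).
#' @param ids Optional compound ids.
#' @param aggregate "median" (default) or "mean" over member p-values.
#' @return Tibble: `compound_id`, `p0`, `p1`, `delta_p`.
#' @export
predict_p <- function(ensemble, features, ids = NULL,
                      aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  n <- nrow(features)
  p0_m <- matrix(NA_real_, n, length(ensemble$members))
  p1_m <- matrix(NA_real_, n, length(ensemble$members))
  for (m in seq_along(ensemble$members)) {
    mem <- ensemble$members[[m]]
    prob1 <- ensemble$classifier$predict_prob(mem$model, features)
    p1_m[, m] <- conformal_p(mem$calib_alpha1, 1 - prob1)
    p0_m[, m] <- conformal_p(mem$calib_alpha0, prob1)
  }
  agg <- if (aggregate == "median") function(x) apply(x, 1, median) else rowMeans
  p0 <- agg(p0_m); p1 <- agg(p1_m)
  if (is.null(ids)) ids <- sprintf("Q%07d", seq_len(n))
  tibble::tibble(compound_id = as.character(ids), p0 = p0, p1 = p1,
                 delta_p = p1 - p0)
}

#' Four-region conformal classification
#'
#' active: p1 > epsilon and p0 <= epsilon; inactive: p0 > epsilon and
#' p1 <= epsilon; both: both exceed epsilon (ambiguous); null: neither
#' (insufficient confidence). The four regions partition every input.
#'
#' @param p0,p1 Class p-values in (0, 1].
#' @param epsilon Significance threshold in (0, 1).
#' @return Character vector in {"active", "inactive", "both", "null"}.
#' @export
classify_region <- function(p0, p1, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 1) {
    abort_confunnel("`epsilon` must lie in (0, 1)", "invalid_config")
  }
  a <- p1 > epsilon; i <- p0 > epsilon
  dplyr::case_when(a & !i ~ "active", i & !a ~ "inactive",
                   a & i ~ "both", TRUE ~ "null")
}

#' Select the significance threshold maximizing true positive rate
#'
#' Scans an epsilon grid; at each value the TPR is the fraction of true
#' actives assigned the single-label active region (strict: the ambiguous
#' "both" region does not count), and per-class error rates are the
#' fraction of examples whose true-class p-value is <= epsilon (the
#' quantity the conformal validity guarantee bounds by epsilon). Returns
#' the smallest epsilon achieving the maximal TPR, plus both curves.
#'
#' @param predictions Tibble from [predict_p()] (`p0`, `p1`).
#' @param labels True 0/1 labels aligned with `predictions`.
#' @param grid Epsilon grid (default 0.001..0.500 step 0.001; p-value
#'   thresholds above 0.5 cannot yield single-label predictions).
#' @param count_both_as_positive Count the "both" region in TPR (default
#'   FALSE).
#' @return List: `epsilon`, `curves` (tibble `epsilon`, `tpr`,
#'   `error_active`, `error_inactive`).
#' @export
select_epsilon <- function(predictions, labels,
                           grid = seq(0.001, 0.500, by = 0.001),
                           count_both_as_positive = FALSE) {
  labels <- as.integer(labels)
  if (!any(labels == 1L)) {
    abort_confunnel("no true actives in the validation set; TPR undefined",
                    "undefined_tpr")
  }
  p0 <- predictions$p0; p1 <- predictions$p1
  p0_a <- p0[labels == 1L]; p1_a <- p1[labels == 1L]
  tpr <- vapply(grid, function(eps) {
    if (count_both_as_positive) mean(p1_a > eps)
    else mean(p1_a > eps & p0_a <= eps)
  }, numeric(1))
  err_active <- vapply(grid, function(eps) mean(p1_a <= eps), numeric(1))
  p0_i <- p0[labels == 0L]
  err_inactive <- vapply(grid, function(eps) mean(p0_i <= eps), numeric(1))
  best <- grid[which.max(tpr)]  # which.max takes the first (smallest) maximizer
  list(epsilon = best,
       curves = tibble::tibble(epsilon = grid, tpr = tpr,
                               error_active = err_active,
                               error_inactive = err_inactive))
}

# Rank-based (Mann-Whitney) ROC-AUC of `score` for 0/1 `labels`.
roc_auc_rank <- function(score, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Screening performance metrics at a threshold
#'
#' Positives are compounds in the single-label active region; ambiguous
#' ("both") and abstaining ("null") predictions count as non-positive,
#' matching a single confusion matrix per screen. ROC-AUC is rank-based
#' with delta_p as the score.
#'
#' @param predictions Tibble from [predict_p()] (needs `compound_id`, `p0`,
#'   `p1`, `delta_p`).
#' @param labels Named or aligned 0/1 vector of true labels; when named, the
#'   names are matched against `compound_id`.
#' @param epsilon Significance threshold.
#' @return List of class `screening_metrics`: confusion counts, `recall`,
#'   `precision`, `roc_auc`, `region_counts`.
#' @export
evaluate_screen <- function(predictions, labels, epsilon) {
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), predictions$compound_id)) {
      abort_confunnel("prediction ids and label names do not align",
                      "alignment_error")
    }
    labels <- labels[predictions$compound_id]
  } else if (length(labels) != nrow(predictions)) {
    abort_confunnel("labels length does not match predictions", "alignment_error")
  }
  labels <- as.integer(labels)
  region <- classify_region(predictions$p0, predictions$p1, epsilon)
  pos <- region == "active"
  tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
  fn <- sum(!pos & labels == 1L); tn <- sum(!pos & labels == 0L)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    roc_auc = roc_auc_rank(predictions$delta_p, labels),
    region_counts = table(factor(region, levels = c("active", "inactive",
                                                    "both", "null"))),
    epsilon = epsilon), class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("<screening_metrics> eps=%.3f recall=%.4f precision=%.4f AUC=%.4f\n",
              x$epsilon, x$recall, x$precision, x$roc_auc))
  cat("  regions:", paste(names(x$region_counts), as.integer(x$region_counts),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Rank predicted actives by confidence and take the top k
#'
#' Compounds in the active region are sorted by delta_p descending (ties by
#' ascending compound id) and the first `k` returned. When fewer than `k`
#' actives exist, all are returned and the `truncated` attribute is set with
#' a warning.
#'
#' @param predictions Tibble with `compound_id`, `delta_p` and `region`
#'   (or `p0`/`p1` plus `epsilon`).
#' @param k Number of candidates to keep (>= 1).
#' @param epsilon Needed only when `predictions` lacks a `region` column.
#' @return Tibble of the top-k active predictions.
#' @export
rank_and_select <- function(predictions, k, epsilon = NULL) {
  if (!is_count(k) || k < 1) abort_confunnel("`k` must be >= 1", "invalid_k")
  if (is.null(predictions$region)) {
    if (is.null(epsilon)) abort_confunnel("supply `epsilon` or a `region` column",
                                          "invalid_config")
    predictions$region <- classify_region(predictions$p0, predictions$p1, epsilon)
  }
  act <- predictions[predictions$region == "active", , drop = FALSE]
  act <- act[order(-act$delta_p, act$compound_id), , drop = FALSE]
  truncated <- nrow(act) < k
  if (truncated) {
    warning(sprintf("only %d active predictions available (k = %d)", nrow(act), k))
  }
  out <- head(act, k)
  attr(out, "truncated") <- truncated
  out
}

#' Correlation of confidence margin with docking score and score rank
#'
#' Pearson correlation of delta_p with the docking score and with the
#' ascending-score rank; a well-behaved screen shows strong negative
#' correlations (better = more negative scores attract higher confidence).
#'
#' @param delta_p Confidence margins.
#' @param best_scores Docking scores (kcal/mol), aligned.
#' @return Tibble: `quantity` ("score", "rank"), `r`, `p_value`.
#' @export
correlation_diagnostics <- function(delta_p, best_scores) {
  if (length(delta_p) < 3 || length(delta_p) != length(best_scores)) {
    abort_confunnel("need >= 3 aligned observations", "invalid_config")
  }
  if (sd(delta_p) == 0 || sd(best_scores) == 0) {
    abort_confunnel("zero variance: correlation undefined", "undefined_correlation")
  }
  ct_s <- cor.test(delta_p, best_scores, method = "pearson")
  ct_r <- cor.test(delta_p, rank(best_scores), method = "pearson")
  tibble::tibble(quantity = c("score", "rank"),
                 r = c(unname(ct_s$estimate), unname(ct_r$estimate)),
                 p_value = c(ct_s$p.value, ct_r$p.value))
}

#' Cross-validated screening diagnostics
#'
#' Optional k-fold report: refits the conformal ensemble on each training
#' fold, evaluates on the held-out fold at `epsilon`, and summarises recall,
#' precision and ROC-AUC as mean and SD across folds. A diagnostic, not part
#' of the trained artifact.
#'
#' @param features,labels As in [train_acp()].
#' @param epsilon Threshold used for fold-level metrics.
#' @param n_folds Folds (default 5).
#' @param seed Fold assignment seed.
#' @param ... Passed to [train_acp()].
#' @return Tibble: `metric`, `mean`, `sd`.
#' @export
acp_cross_validate <- function(features, labels, epsilon, n_folds = 5L,
                               seed = 1L, ...) {
  labels <- as.integer(labels)
  folds <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in 0:1) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  res <- lapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    ens <- train_acp(features[tr, , drop = FALSE], labels[tr], ...)
    pr <- predict_p(ens, features[!tr, , drop = FALSE])
    m <- evaluate_screen(pr, labels[!tr], epsilon)
    c(recall = m$recall, precision = m$precision, roc_auc = m$roc_auc)
  })
  mat <- do.call(rbind, res)
  tibble::tibble(metric = colnames(mat),
                 mean = colMeans(mat, na.rm = TRUE),
                 sd = apply(mat, 2, sd, na.rm = TRUE))
}
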