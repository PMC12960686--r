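# Study-condition experiments combining the synthetic generators with the
# conformal screen; used by the validity checks and the reproduction script.

#' Class-conditional validity experiment on an exchangeable synthetic screen
#'
#' Generates a synthetic library, scores every compound with the docking
#' oracle, labels the top `q` as active, randomly splits compounds into a
#' training subsample and an exchangeable held-out set, trains the
#' conformal ensemble, and measures the per-class error rate
#' P(true-class p-value <= epsilon) on the held-out set. Under
#' exchangeability, Mondrian conformal prediction bounds this by epsilon
#' (up to binomial fluctuation) within each class.
#'
#' @param n_compounds Screen size (default 20000).
#' @param n_train Training subsample (default 4000).
#' @param q Active labeling quantile (default 0.01).
#' @param epsilons Thresholds to probe (default c(0.05, 0.1, 0.143, 0.2)).
#' @param seed Integer seed for the whole experiment.
#' @param n_conformers Conformers per oracle call (default 50).
#' @param classifier Base classifier (default [classifier_gbt()]).
#' @return Tibble: `epsilon`, `class`, `error`, `n` (held-out class size).
#' @export
screen_validity_errors <- function(n_compounds = 20000L, n_train = 4000L,
                                   q = 0.01,
                                   epsilons = c(0.05, 0.1, 0.143, 0.2),
                                   seed = 1L, n_conformers = 50L,
                                   classifier = classifier_gbt()) {
  lib <- generate_library(library_config(n_compounds, seed = seed))
  scores <- score_library(lib, n_conformers, oracle_config(seed = seed + 1L))
  lab <- label_actives(scores$best_score, scores$compound_id, q)
  train_idx <- with_seed(seed + 2L, sample(n_compounds, n_train))
  ens <- train_acp(lib$fingerprints[train_idx, , drop = FALSE],
                   lab$labels[train_idx], base_seed = seed + 3L,
                   classifier = classifier)
  test_idx <- setdiff(seq_len(n_compounds), train_idx)
  pr <- predict_p(ens, lib$fingerprints[test_idx, , drop = FALSE])
  y <- lab$labels[test_idx]
  out <- lapply(epsilons, function(eps) {
    tibble::tibble(
      epsilon = eps, class = c(0L, 1L),
      error = c(mean(pr$p0[y == 0L] <= eps), mean(pr$p1[y == 1L] <= eps)),
      n = c(sum(y == 0L), sum(y == 1L)))
  })
  dplyr::bind_rows(out)
}
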