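#' Configuration for the planted-signal docking oracle
#'
#' Stands in for a docking engine: the "binding affinity" of a compound is a
#' linear function of how many planted fingerprint bits it carries, plus
#' compound-level and per-conformer Gaussian noise. Scores follow the docking
#' convention: kcal/mol, lower (more negative) = better binding.
#'
#' Per-conformer score for conformer c:
#' \deqn{score_c = \beta_0 + \beta_1 s + e_{compound} + e_{conformer,c}}
#' where s is the compound's planted-bit count, `e_compound` ~ N(0,
#' sigma_compound) is drawn once per compound and `e_conformer,c` ~ N(0,
#' sigma_conformer) i.i.d. The reported ("optimal") score is the minimum over
#' conformers. Separating the two noise levels gives the conformer-count
#' sensitivity experiment a known mechanism: only conformer noise makes more
#' conformers help.
#'
#' @param beta0 Baseline mean score, kcal/mol (default -6.0).
#' @param beta1 Score shift per planted bit, kcal/mol (default -0.5; more
#'   planted bits = more negative = better).
#' @param sigma_compound Compound-level noise SD, kcal/mol (default 0.4).
#' @param sigma_conformer Per-conformer noise SD, kcal/mol (default 0.3).
#' @param seed Integer seed for the oracle's noise streams.
#' @return An `oracle_config` list.
#' @export
oracle_config <- function(beta0 = -6.0, beta1 = -0.5,
                          sigma_compound = 0.4, sigma_conformer = 0.3,
                          seed = 1L) {
  if (sigma_compound < 0 || sigma_conformer < 0) {
    abort_confunnel("noise SDs must be >= 0", "invalid_config")
  }
  structure(list(beta0 = beta0, beta1 = beta1,
                 sigma_compound = sigma_compound,
                 sigma_conformer = sigma_conformer,
                 seed = as.integer(seed)),
            class = "oracle_config")
}

#' Score one compound with the synthetic docking oracle
#'
#' The per-compound noise stream is seeded by hashing (oracle seed, compound
#' id), so results are deterministic and independent of the order in which
#' compounds are scored. Conformer noise draws are a fixed stream per
#' compound: scoring the same compound at a larger `n_conformers` extends the
#' same draws, so best scores are nested (non-increasing in conformer count)
#' by construction.
#'
#' @param id Compound id (string).
#' @param fingerprint 0/1 vector, or a precomputed planted-bit count via
#'   `n_planted`.
#' @param n_conformers Number of conformer scores to draw (>= 1).
#' @param config An [oracle_config()].
#' @param planted_bits 0-based planted bit indices (needed when scoring from
#'   a fingerprint).
#' @param n_planted Optional known planted-bit count, bypassing the
#'   fingerprint.
#' @return A `docking_result` list: `compound_id`, `conformer_scores`
#'   (length `n_conformers`), `best_score` (the minimum).
#' @export
docking_oracle <- function(id, fingerprint = NULL, n_conformers, config,
                           planted_bits = NULL, n_planted = NULL) {
  if (!is_count(n_conformers) || n_conformers < 1) {
    abort_confunnel("`n_conformers` must be a positive integer", "invalid_config")
  }
  if (is.null(n_planted)) {
    if (is.null(fingerprint)) {
      abort_confunnel(sprintf("compound '%s' has no fingerprint", id), "missing_feature")
    }
    if (is.null(planted_bits)) {
      abort_confunnel("`planted_bits` required when scoring from a fingerprint",
                      "invalid_config")
    }
    n_planted <- sum(fingerprint[planted_bits + 1L])
  }
  scores <- with_seed(hash_seed(config$seed, id), {
    e_compound <- rnorm(1, 0, config$sigma_compound)
    e_conf <- rnorm(n_conformers, 0, config$sigma_conformer)
    config$beta0 + config$beta1 * n_planted + e_compound + e_conf
  })
  structure(list(compound_id = id, conformer_scores = scores,
                 best_score = min(scores)),
            class = "docking_result")
}

#' Score every compound in a library; return best scores
#'
#' @param library A `compound_library`.
#' @param n_conformers Conformers per compound (default 50, the docking
#'   campaign's chosen ensemble size).
#' @param config An [oracle_config()].
#' @param ids Optional subset of compound ids to score.
#' @return Tibble `compound_id`, `best_score` (kcal/mol), `n_planted_bits`.
#' @export
score_library <- function(library, n_conformers = 50L, config, ids = NULL) {
  truth <- library$truth
  if (is.null(truth)) {
    abort_confunnel("library lacks a ground-truth sidecar; score per compound instead",
                    "missing_feature")
  }
  if (!is.null(ids)) truth <- truth[match(ids, truth$id), ]
  best <- vapply(seq_len(nrow(truth)), function(i) {
    docking_oracle(truth$id[i], n_conformers = n_conformers, config = config,
                   n_planted = truth$n_planted_bits[i])$best_score
  }, numeric(1))
  tibble::tibble(compound_id = truth$id, best_score = best,
                 n_planted_bits = truth$n_planted_bits)
}
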