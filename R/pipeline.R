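# End-to-end screening funnel: generate -> filter -> dock subsample ->
# label -> conformal train -> predict -> rank -> re-dock -> ADMET -> report.

#' Pipeline configuration
#'
#' Desk-scale defaults emulate the study design at reduced size: a 20,000
#' compound library, a 2,000-compound docked training subsample, 50
#' conformers per compound, top-1% activity labeling, a 5-member conformal
#' ensemble with 80/20 proper-train/calibration splits, auto-selected
#' epsilon, and a top-k of 1% of the library carried into ADMET filtering.
#'
#' @param n_compounds Library size (default 20000).
#' @param n_train Docked training subsample size (default 2000).
#' @param conformer_count Conformers per docking call (default 50).
#' @param q Active labeling quantile (default 0.01).
#' @param n_models Conformal ensemble size (default 5).
#' @param calib_fraction Calibration fraction per member (default 0.2).
#' @param epsilon "auto" (select by maximizing TPR on a validation split)
#'   or a fixed value in (0, 1).
#' @param valid_fraction Fraction of the labeled subsample held out for
#'   epsilon selection and metrics (default 0.25).
#' @param top_k Predicted actives carried forward (default 1% of
#'   `n_compounds`).
#' @param admet_pass_rate Marginal per-endpoint pass probability for the
#'   synthetic ADMET profiles (default 0.75; joint pass ~2.4% over the 13
#'   endpoints).
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param library,oracle Optional pre-built [library_config()] /
#'   [oracle_config()] (defaults derive from `n_compounds` and `seed`).
#' @param classifier Base classifier (default [classifier_gbt()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_compounds = 20000L, n_train = 2000L,
                            conformer_count = 50L, q = 0.01,
                            n_models = 5L, calib_fraction = 0.2,
                            epsilon = "auto", valid_fraction = 0.25,
                            top_k = max(1L, floor(0.01 * n_compounds)),
                            admet_pass_rate = 0.75, seed = 1L,
                            library = NULL, oracle = NULL,
                            classifier = classifier_gbt()) {
  if (!is.numeric(q) || q <= 0 || q >= 1) {
    abort_confunnel("`q` must lie in (0,1)", "invalid_quantile")
  }
  if (!is_count(top_k) || top_k < 1) abort_confunnel("`top_k` must be >= 1",
                                                     "invalid_k")
  if (is.null(library)) library <- library_config(n_compounds, seed = seed)
  if (is.null(oracle)) oracle <- oracle_config(seed = seed + 1000L)
  structure(list(n_train = as.integer(n_train),
                 conformer_count = as.integer(conformer_count), q = q,
                 n_models = as.integer(n_models),
                 calib_fraction = calib_fraction, epsilon = epsilon,
                 valid_fraction = valid_fraction, top_k = as.integer(top_k),
                 admet_pass_rate = admet_pass_rate, seed = as.integer(seed),
                 library = library, oracle = oracle, classifier = classifier),
            class = "pipeline_config")
}

#' Run the screening funnel end to end
#'
#' Stages: generate (or accept) the library; lead-like filter; dock a
#' training subsample with the conformer ensemble; label the top `q` as
#' computationally active; train the aggregated Mondrian conformal
#' ensemble; predict the whole filtered library; select epsilon on the
#' held-out validation split (auto mode); rank predicted actives by
#' delta_p and keep the top k; re-score the top k with a distinct oracle
#' seed stream (the slot where re-docking plugs in); generate + filter
#' ADMET profiles; merge survivors with re-docking scores into the ranked
#' candidate table; assemble the funnel report. Fully deterministic given
#' (config, seed).
#'
#' @param config A [pipeline_config()].
#' @param library Optional pre-generated `compound_library` (must carry a
#'   ground-truth sidecar for oracle scoring).
#' @param outdir Optional directory; when given every stage artifact is
#'   persisted as CSV/JSON (append-only; existing files are not touched).
#' @return A `funnel_report` list: `stages` (funnel accounting tibble),
#'   `metrics` (validation [evaluate_screen()] + correlation and
#'   ground-truth enrichment), `candidates`, `epsilon`, `threshold`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, library = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(library)) library <- generate_library(config$library)
  n_lib <- nrow(library$compounds)

  # Stage 1: lead-like filter
  flt <- filter_leadlike(library$compounds)
  retained_ids <- flt$retained$id
  fp <- library$fingerprints[retained_ids, , drop = FALSE]

  # Stage 2: dock the training subsample and label actives
  n_train <- min(config$n_train, length(retained_ids))
  train_ids <- with_seed(config$seed + 1L, sample(retained_ids, n_train))
  docked <- score_library(library, config$conformer_count, config$oracle,
                          ids = train_ids)
  lab <- label_actives(docked$best_score, docked$compound_id, config$q)

  # Stage 3: hold out a validation split, train the conformal ensemble
  val_idx <- with_seed(config$seed + 2L, {
    v <- integer(0)
    for (cl in 0:1) {
      idx <- which(lab$labels == cl)
      v <- c(v, sample(idx, max(1L, round(config$valid_fraction * length(idx)))))
    }
    sort(v)
  })
  fit_idx <- setdiff(seq_len(n_train), val_idx)
  ens_sel <- train_acp(fp[docked$compound_id[fit_idx], , drop = FALSE],
                       lab$labels[fit_idx], n_models = config$n_models,
                       calib_fraction = config$calib_fraction,
                       base_seed = config$seed + 10L,
                       classifier = config$classifier)

  # Stage 4: epsilon selection on the validation split
  val_pred <- predict_p(ens_sel,
                        fp[docked$compound_id[val_idx], , drop = FALSE],
                        ids = docked$compound_id[val_idx])
  if (identical(config$epsilon, "auto")) {
    eps_sel <- select_epsilon(val_pred, lab$labels[val_idx])
    epsilon <- eps_sel$epsilon
  } else {
    epsilon <- as.numeric(config$epsilon)
    eps_sel <- NULL
  }
  val_metrics <- evaluate_screen(val_pred, lab$labels[val_idx], epsilon)

  # Refit the deployed ensemble on the full labeled subsample (the
  # validation split served only to pick epsilon and report metrics)
  ens <- train_acp(fp[docked$compound_id, , drop = FALSE], lab$labels,
                   n_models = config$n_models,
                   calib_fraction = config$calib_fraction,
                   base_seed = config$seed + 10L,
                   classifier = config$classifier)
  ens$epsilon <- epsilon

  # Stage 5: predict the whole filtered library, rank, keep top k
  pred <- predict_p(ens, fp, ids = retained_ids)
  pred$region <- classify_region(pred$p0, pred$p1, epsilon)
  n_active <- sum(pred$region == "active")
  top <- suppressWarnings(rank_and_select(pred, config$top_k))

  # Stage 6: re-dock the top k with a distinct oracle seed stream
  redock_oracle <- config$oracle
  redock_oracle$seed <- config$oracle$seed + 500000L
  redock <- score_library(library, config$conformer_count, redock_oracle,
                          ids = top$compound_id)

  # Stage 7: ADMET filter + merge
  profiles <- generate_admet_profiles(top$compound_id, config$admet_pass_rate,
                                      seed = config$seed + 3L)
  adm <- apply_admet_filter(profiles)
  merged <- merge_with_scores(adm$passing_ids, top, redock)

  # Diagnostics against hidden ground truth (synthetic libraries only)
  extra <- list()
  if (!is.null(library$truth)) {
    truth_scores <- score_library(library, config$conformer_count,
                                  config$oracle, ids = retained_ids)
    true_lab <- label_actives(truth_scores$best_score,
                              truth_scores$compound_id, config$q)
    hits <- sum(top$compound_id %in% true_lab$active_ids)
    extra$enrichment_factor <- (hits / nrow(top)) / config$q
    extra$n_true_active_in_topk <- hits
    # confidence-vs-affinity correlation on the held-out library (the
    # screen's analogue of test-set validation)
    held_out <- setdiff(retained_ids, train_ids)
    ho <- match(held_out, pred$compound_id)
    hs <- match(held_out, truth_scores$compound_id)
    extra$correlations <- correlation_diagnostics(pred$delta_p[ho],
                                                  truth_scores$best_score[hs])
  }

  stages <- funnel_summary(tibble::tibble(
    name = c("Lead-like Filtering", "Virtual Screening",
             "Top-ranked Selecting", "ADMET"),
    input = c(n_lib, length(retained_ids), n_active, nrow(top)),
    criteria = c("20<=HAC<=25, -5<=cLogP<=3.5",
                 "Class-specific confidence scores",
                 "Rank of prediction confidence",
                 "Toxicity filters + Docking data"),
    output = c(length(retained_ids), n_active, nrow(top),
               nrow(merged$candidates))))

  report <- structure(list(
    stages = stages,
    metrics = c(list(validation = val_metrics), extra),
    candidates = merged$candidates,
    dropped_at_merge = merged$dropped,
    epsilon = epsilon, epsilon_curves = eps_sel$curves,
    threshold = lab$threshold,
    provenance = list(seed = config$seed, n_train = n_train,
                      conformer_count = config$conformer_count,
                      q = config$q, top_k = config$top_k,
                      n_models = config$n_models,
                      package_version = as.character(utils::packageVersion("confunnel")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "funnel_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  writeLines(format_funnel_text(x$stages))
  cat(sprintf("epsilon = %.3f, labeling threshold = %.3f kcal/mol\n",
              x$epsilon, x$threshold))
  if (!is.null(x$metrics$enrichment_factor)) {
    cat(sprintf("top-k enrichment factor vs ground truth: %.2f\n",
                x$metrics$enrichment_factor))
  }
  invisible(x)
}

#' Write a funnel report to disk
#'
#' Persists the funnel table as CSV and aligned text, the candidate table
#' as CSV, and the full report (stages, scalar metrics, provenance) as
#' JSON.
#'
#' @param report A `funnel_report`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(funnel_csv = file.path(dir, "funnel.csv"),
             funnel_txt = file.path(dir, "funnel.txt"),
             candidates = file.path(dir, "candidates.csv"),
             json = file.path(dir, "report.json"))
  readr::write_csv(report$stages, paths["funnel_csv"])
  writeLines(format_funnel_text(report$stages), paths["funnel_txt"])
  readr::write_csv(report$candidates, paths["candidates"])
  vm <- report$metrics$validation
  json <- list(
    stages = report$stages,
    epsilon = report$epsilon,
    threshold = report$threshold,
    metrics = list(recall = vm$recall, precision = vm$precision,
                   roc_auc = vm$roc_auc,
                   region_counts = as.list(vm$region_counts),
                   enrichment_factor = report$metrics$enrichment_factor),
    provenance = report$provenance)
  jsonlite::write_json(json, paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a JSON funnel report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return The parsed report list (stages as a tibble).
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$stages <- tibble::as_tibble(x$stages)
  x
}
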