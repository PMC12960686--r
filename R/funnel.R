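# ADMET filter cascade and funnel accounting.

#' Default ADMET filter criteria
#'
#' Required value per endpoint: "No" for every toxicity / liability
#' endpoint (DILI, cytotoxicity, the five CYP inhibitions, BBB penetration,
#' P-glycoprotein liability, hERG blocking, mitochondrial toxicity,
#' mutagenicity) and "Yes" for human liver microsomal stability. BBB is
#' grouped with the negatives by default but is context-dependent
#' (CNS-targeted programs may want it positive), hence the override.
#'
#' @param overrides Named character vector of endpoint -> required value to
#'   override defaults (e.g. `c(BBB = "Yes")`).
#' @return Named character vector over [admet_endpoints()].
#' @export
admet_criteria <- function(overrides = NULL) {
  eps <- admet_endpoints()
  crit <- stats::setNames(rep("No", length(eps)), eps)
  crit["HLM_stability"] <- "Yes"
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), eps)
    if (length(unknown)) {
      abort_confunnel(paste("unknown endpoint(s):", paste(unknown, collapse = ", ")),
                      "schema_error")
    }
    crit[names(overrides)] <- overrides
  }
  crit
}

#' Read filter criteria from a YAML mapping
#'
#' The file maps endpoint names to required values, e.g. `BBB: "Yes"`;
#' unlisted endpoints keep their defaults.
#'
#' @param path YAML file path.
#' @return Named requirement vector as from [admet_criteria()].
#' @export
admet_criteria_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  admet_criteria(overrides = unlist(raw))
}

#' Apply the conjunctive ADMET filter
#'
#' A compound passes iff every endpoint matches its required value (logical
#' AND over all 13 endpoints). The rejection tally reports, per endpoint,
#' the number of compounds whose first failing endpoint it was (in
#' [admet_endpoints()] order) and the total number of failures.
#'
#' @param profiles Tibble from [generate_admet_profiles()] or a CSV with
#'   `compound_id` + one Yes/No column per endpoint.
#' @param criteria Named requirement vector (default [admet_criteria()]).
#' @return List: `passing_ids`, `tally` (tibble `endpoint`,
#'   `first_failures`, `total_failures`).
#' @export
apply_admet_filter <- function(profiles, criteria = admet_criteria()) {
  eps <- names(criteria)
  missing <- setdiff(eps, names(profiles))
  if (length(missing)) {
    abort_confunnel(paste("profile table missing endpoint(s):",
                          paste(missing, collapse = ", ")), "schema_error")
  }
  fail <- sapply(eps, function(ep) profiles[[ep]] != criteria[[ep]])
  if (is.null(dim(fail))) fail <- matrix(fail, nrow = nrow(profiles))
  pass <- rowSums(fail) == 0
  first_fail <- apply(fail, 1, function(f) if (any(f)) which(f)[1] else NA_integer_)
  tally <- tibble::tibble(
    endpoint = eps,
    first_failures = as.integer(tabulate(first_fail, length(eps))),
    total_failures = as.integer(colSums(fail)))
  list(passing_ids = profiles$compound_id[pass], tally = tally)
}

#' Merge ADMET-passing compounds with predictions and docking scores
#'
#' Builds the ranked candidate table: one row per passing compound with its
#' confidence margin, SMILES and docking score, sorted by delta_p descending
#' (ties by ascending score, then id). Passing compounds lacking a docking
#' score are dropped and reported in the drop log — the step at which an
#' ADMET-passing set can shrink on integration with docking data.
#'
#' @param passing_ids Ids from [apply_admet_filter()].
#' @param predictions Tibble with `compound_id`, `delta_p` (optionally
#'   `smiles`).
#' @param best_scores Tibble with `compound_id`, `best_score`.
#' @return List: `candidates` (tibble `compound_id`, `delta_p`, `smiles`,
#'   `score`), `dropped` (ids lacking a score).
#' @export
merge_with_scores <- function(passing_ids, predictions, best_scores) {
  pred <- predictions[match(passing_ids, predictions$compound_id), , drop = FALSE]
  if (anyNA(pred$compound_id)) {
    abort_confunnel("every passing id must have a prediction", "alignment_error")
  }
  score <- best_scores$best_score[match(passing_ids, best_scores$compound_id)]
  dropped <- passing_ids[is.na(score)]
  keep <- !is.na(score)
  out <- tibble::tibble(
    compound_id = passing_ids[keep],
    delta_p = pred$delta_p[keep],
    smiles = if ("smiles" %in% names(pred)) pred$smiles[keep] else NA_character_,
    score = score[keep])
  out <- out[order(-out$delta_p, out$score, out$compound_id), , drop = FALSE]
  list(candidates = out, dropped = dropped)
}

#' Funnel stage accounting
#'
#' Computes, for each (name, input, criteria, output) stage, the reduction
#' rate (1 - output/input) * 100, rounded half-up to 3 decimals — the
#' printed-table convention. Consecutive stages whose counts do not chain
#' (stage i+1 input != stage i output) must carry an annotation.
#'
#' @param stages Data frame / tibble with columns `name`, `input`,
#'   `criteria`, `output`, optional `note` explaining count discontinuities.
#' @return Tibble with `reduction_pct` added.
#' @export
funnel_summary <- function(stages) {
  stages <- tibble::as_tibble(stages)
  if (any(stages$output > stages$input)) {
    abort_confunnel("stage output exceeds input", "inconsistent_funnel")
  }
  if (any(stages$input < 0)) {
    abort_confunnel("negative stage counts", "inconsistent_funnel")
  }
  if (nrow(stages) > 1) {
    chained <- stages$input[-1] == stages$output[-nrow(stages)]
    note <- if ("note" %in% names(stages)) stages$note[-1] else
      rep(NA_character_, nrow(stages) - 1)
    if (any(!chained & (is.na(note) | !nzchar(note)))) {
      abort_confunnel("unannotated discontinuity between funnel stages",
                      "inconsistent_funnel")
    }
  }
  stages$reduction_pct <- ifelse(
    stages$input > 0,
    round_half_up((1 - stages$output / stages$input) * 100, 3),
    0)
  stages
}

#' Render a funnel summary as an aligned text table
#'
#' @param funnel Output of [funnel_summary()].
#' @return Character vector of lines (also printed invisibly usable with
#'   `writeLines`).
#' @export
format_funnel_text <- function(funnel) {
  rows <- rbind(
    c("Step", "Input", "Filtering criteria", "Output", "Reduction rate"),
    cbind(funnel$name,
          format(funnel$input, big.mark = ",", trim = TRUE),
          funnel$criteria,
          format(funnel$output, big.mark = ",", trim = TRUE),
          sprintf("%.3f%%", funnel$reduction_pct)))
  padded <- apply(rows, 2, function(col)
    formatC(col, width = max(nchar(col)), flag = "-"))
  apply(padded, 1, paste, collapse = "  ")
}
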