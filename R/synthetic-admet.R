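#' The 13 ADMET endpoints used by the filter cascade
#'
#' Toxicity/liability endpoints are required "No"; human liver microsomal
#' stability (`HLM_stability`) is required "Yes". The BBB requirement is
#' context-dependent (CNS programs may want penetration) and can be relaxed
#' via [admet_criteria()].
#'
#' @return Character vector of endpoint names.
#' @export
admet_endpoints <- function() {
  c("DILI", "cytotoxicity", "CYP1A2", "CYP3A4", "CYP2D6", "CYP2C9",
    "CYP2C19", "BBB", "Pgp_liability", "hERG", "mitochondrial_toxicity",
    "mutagenicity", "HLM_stability")
}

#' Generate binary ADMET endpoint profiles with tunable pass rates
#'
#' One profile per compound; each endpoint is drawn independently so that it
#' matches its required value ("No" for toxicity/liability endpoints, "Yes"
#' for HLM stability) with the configured probability. Stands in for an
#' external endpoint predictor; the filter logic downstream is the
#' implemented contribution.
#'
#' @param ids Compound ids.
#' @param pass_rate_per_endpoint Named numeric vector / list mapping each of
#'   the 13 endpoints to its marginal pass probability. A single unnamed
#'   value is recycled to all endpoints.
#' @param seed Integer seed.
#' @param criteria Filter criteria defining the passing value per endpoint
#'   (default [admet_criteria()]).
#' @return Tibble `compound_id` + one "Yes"/"No" column per endpoint.
#' @export
generate_admet_profiles <- function(ids, pass_rate_per_endpoint, seed = 1L,
                                    criteria = admet_criteria()) {
  eps <- admet_endpoints()
  if (length(pass_rate_per_endpoint) == 1 && is.null(names(pass_rate_per_endpoint))) {
    pass_rate_per_endpoint <- stats::setNames(rep(as.numeric(pass_rate_per_endpoint),
                                                  length(eps)), eps)
  }
  unknown <- setdiff(names(pass_rate_per_endpoint), eps)
  if (length(unknown)) {
    abort_confunnel(paste("unknown endpoint(s):", paste(unknown, collapse = ", ")),
                    "schema_error")
  }
  missing <- setdiff(eps, names(pass_rate_per_endpoint))
  if (length(missing)) {
    abort_confunnel(paste("pass rate missing for endpoint(s):",
                          paste(missing, collapse = ", ")), "schema_error")
  }
  n <- length(ids)
  prof <- tibble::tibble(compound_id = as.character(ids))
  with_seed(seed, {
    for (ep in eps) {
      pass <- runif(n) < pass_rate_per_endpoint[[ep]]
      req <- criteria[[ep]]
      other <- if (req == "Yes") "No" else "Yes"
      prof[[ep]] <- ifelse(pass, req, other)
    }
  })
  prof
}
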