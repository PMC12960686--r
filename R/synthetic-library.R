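#' Configuration for the synthetic lead-like compound library
#'
#' The generator emulates a lead-like screening library: 1024-bit binary
#' fingerprints with sparse background bits, a small set of "planted" bits
#' that carry the binding signal read by the docking oracle, and
#' heavy-atom-count / cLogP distributions that straddle the lead-like filter
#' window (20--25 heavy atoms, cLogP between -5 and 3.5).
#'
#' @param n_compounds Number of compounds to generate (>= 1).
#' @param seed Integer seed; the whole library is a deterministic function
#'   of the configuration.
#' @param n_bits Fingerprint length (default 1024).
#' @param planted_bits Integer vector of 0-based bit indices carrying the
#'   binding signal (default 8 evenly spread indices).
#' @param bit_density Probability each background bit is set (default 0.05).
#' @param planted_prevalence Probability a compound carries each planted bit
#'   (default 0.10).
#' @param hac_range Integer pair; heavy-atom counts are sampled uniformly on
#'   this inclusive range (default 15..30).
#' @param clogp_mean,clogp_sd Normal parameters for cLogP (default 2.0, 2.5).
#' @return A `library_config` list.
#' @export
library_config <- function(n_compounds,
                           seed = 1L,
                           n_bits = 1024L,
                           planted_bits = as.integer(round(seq(7, n_bits - 8, length.out = 8))),
                           bit_density = 0.05,
                           planted_prevalence = 0.10,
                           hac_range = c(15L, 30L),
                           clogp_mean = 2.0,
                           clogp_sd = 2.5) {
  if (!is_count(n_compounds) || n_compounds < 1) {
    abort_confunnel("`n_compounds` must be a positive integer", "invalid_config")
  }
  planted_bits <- as.integer(planted_bits)
  if (anyDuplicated(planted_bits) || any(planted_bits < 0) || any(planted_bits >= n_bits)) {
    abort_confunnel("`planted_bits` must be distinct indices in [0, n_bits)", "invalid_config")
  }
  stopifnot_scalar_prob(bit_density, "bit_density")
  stopifnot_scalar_prob(planted_prevalence, "planted_prevalence")
  if (length(hac_range) != 2 || hac_range[1] > hac_range[2]) {
    abort_confunnel("`hac_range` must be an ordered integer pair", "invalid_config")
  }
  structure(list(n_compounds = as.integer(n_compounds), seed = as.integer(seed),
                 n_bits = as.integer(n_bits), planted_bits = planted_bits,
                 bit_density = bit_density, planted_prevalence = planted_prevalence,
                 hac_range = as.integer(hac_range),
                 clogp_mean = clogp_mean, clogp_sd = clogp_sd),
            class = "library_config")
}

#' Generate a synthetic compound library with planted ground truth
#'
#' Produces `n_compounds` records, each with an id, heavy-atom count, cLogP,
#' and a binary fingerprint of length `n_bits`. Background bits are
#' independent Bernoulli(`bit_density`); each planted bit is present with
#' probability `planted_prevalence`. The number of planted bits carried by
#' each compound is the hidden ground truth read by [docking_oracle()]; it is
#' returned in a sidecar table (`truth`), never in the fingerprint-facing
#' record, so learners cannot leak it other than through the fingerprint
#' itself.
#'
#' @param config A [library_config()].
#' @return A `compound_library` list with elements `compounds` (tibble:
#'   `id`, `smiles`, `hac`, `clogp`), `fingerprints` (sparse n x n_bits 0/1
#'   `Matrix`, rownames = ids), `truth` (tibble: `id`, `n_planted_bits`) and
#'   `config`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "library_config"))
  n <- config$n_compounds
  nb <- config$n_bits
  with_seed(config$seed, {
    fp <- matrix(rbinom(n * nb, 1L, config$bit_density), nrow = n, ncol = nb)
    pb1 <- config$planted_bits + 1L
    fp[, pb1] <- matrix(rbinom(n * length(pb1), 1L, config$planted_prevalence),
                        nrow = n)
    hac <- sample(seq(config$hac_range[1], config$hac_range[2]), n, replace = TRUE)
    clogp <- rnorm(n, config$clogp_mean, config$clogp_sd)
  })
  ids <- sprintf("CPD-%07d", seq_len(n))
  rownames(fp) <- ids
  n_planted <- as.integer(rowSums(fp[, config$planted_bits + 1L, drop = FALSE]))
  structure(list(
    compounds = tibble::tibble(id = ids, smiles = NA_character_,
                               hac = as.integer(hac), clogp = clogp),
    fingerprints = Matrix::Matrix(fp, sparse = TRUE),
    truth = tibble::tibble(id = ids, n_planted_bits = n_planted),
    config = config
  ), class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("<compound_library> %d compounds, %d-bit fingerprints, %d planted bits (seed %d)\n",
              nrow(x$compounds), ncol(x$fingerprints),
              length(x$config$planted_bits), x$config$seed))
  invisible(x)
}

#' Write / read a compound library as CSV
#'
#' Columns: `id`, `smiles` (may be empty), `hac`, `clogp`, `fp` (fingerprint
#' as a 0/1 character string). The ground-truth sidecar (`id`,
#' `n_planted_bits`) is written alongside when `truth_path` is given.
#'
#' @param library A `compound_library`.
#' @param path Output CSV path.
#' @param truth_path Optional sidecar CSV path for the hidden ground truth.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path, truth_path = NULL) {
  fp_dense <- as.matrix(library$fingerprints)
  fp_str <- apply(fp_dense, 1, paste0, collapse = "")
  out <- dplyr::mutate(library$compounds, fp = unname(fp_str))
  readr::write_csv(out, path, na = "")
  if (!is.null(truth_path)) readr::write_csv(library$truth, truth_path)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), smiles = readr::col_character(),
    hac = readr::col_integer(), clogp = readr::col_double(),
    fp = readr::col_character()))
  nb <- nchar(tab$fp[1])
  fp <- matrix(0L, nrow(tab), nb, dimnames = list(tab$id, NULL))
  for (i in seq_len(nrow(tab))) {
    fp[i, ] <- as.integer(strsplit(tab$fp[i], "")[[1]])
  }
  structure(list(
    compounds = dplyr::select(tab, -"fp"),
    fingerprints = Matrix::Matrix(fp, sparse = TRUE),
    truth = NULL, config = NULL
  ), class = "compound_library")
}
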