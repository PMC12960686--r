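#' Lead-like filtering of a compound table
#'
#' Retains compounds with 20 <= heavy-atom count <= 25 and
#' -5 <= cLogP <= 3.5, all bounds inclusive. The window targets lead-like
#' chemistry: enough complexity for selective binding, compatibility with
#' oral absorption, and tractable conformer generation.
#'
#' @param compounds Tibble/data frame with `id`, `hac`, `clogp`.
#' @param hac_bounds Inclusive heavy-atom-count bounds (default c(20, 25)).
#' @param clogp_bounds Inclusive cLogP bounds (default c(-5, 3.5)).
#' @return List: `retained` (input rows, order preserved), `rejected`
#'   (rejection log tibble: `id`, `reason` in {"hac", "clogp"}; the first
#'   failing rule is reported).
#' @export
filter_leadlike <- function(compounds, hac_bounds = c(20, 25),
                            clogp_bounds = c(-5, 3.5)) {
  if (is.null(compounds$hac) || is.null(compounds$clogp)) {
    abort_confunnel("compound table must carry `hac` and `clogp` columns",
                    "missing_property")
  }
  bad <- is.na(compounds$hac) | is.na(compounds$clogp)
  if (any(bad)) {
    abort_confunnel(paste("missing hac/clogp for:",
                          paste(head(compounds$id[bad], 5), collapse = ", ")),
                    "missing_property")
  }
  hac_ok <- compounds$hac >= hac_bounds[1] & compounds$hac <= hac_bounds[2]
  clogp_ok <- compounds$clogp >= clogp_bounds[1] & compounds$clogp <= clogp_bounds[2]
  keep <- hac_ok & clogp_ok
  reason <- ifelse(!hac_ok, "hac", "clogp")
  list(retained = compounds[keep, , drop = FALSE],
       rejected = tibble::tibble(id = compounds$id[!keep],
                                 reason = reason[!keep]))
}

#' Fingerprint a compound record
#'
#' Returns the stored 1024-bit fingerprint verbatim when present; otherwise
#' computes a circular-substructure (Morgan) fingerprint of radius 2 folded
#' to `n_bits` from the SMILES via the supplied backend. Radius 2 / 1024 bits
#' is the conventional setting; both are configurable through the backend.
#'
#' @param record List or one-row data frame with optional `fingerprint`
#'   (0/1 vector) and optional `smiles`.
#' @param backend Optional function `(smiles, n_bits) -> 0/1 matrix` such as
#'   [fp_backend_rdkit()].
#' @param n_bits Fingerprint length (default 1024).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
featurize <- function(record, backend = NULL, n_bits = 1024L) {
  fp <- record$fingerprint
  if (!is.null(fp)) {
    fp <- as.integer(fp)
    if (length(fp) != n_bits || !all(fp %in% c(0L, 1L))) {
      abort_confunnel("stored fingerprint must be 0/1 of the configured length",
                      "feature_shape")
    }
    return(fp)
  }
  smiles <- record$smiles
  if (is.null(smiles) || is.na(smiles) || !nzchar(smiles)) {
    abort_confunnel("record has neither a fingerprint nor a SMILES",
                    "featurization_unavailable")
  }
  if (is.null(backend)) {
    abort_confunnel("no fingerprint stored and no featurization backend supplied",
                    "featurization_unavailable")
  }
  out <- backend(smiles, n_bits)
  out <- as.integer(out)
  if (length(out) != n_bits) {
    abort_confunnel("backend returned a fingerprint of the wrong length",
                    "feature_shape")
  }
  out
}

#' Morgan fingerprint backend via RDKit
#'
#' Returns a backend function for [featurize()] that shells out to a Python
#' interpreter with RDKit available and computes radius-2 Morgan fingerprints
#' folded to `n_bits`. SMILES that RDKit cannot parse raise a parse error.
#'
#' @param python Python executable (default "python").
#' @param radius Circular radius (default 2).
#' @return A function `(smiles, n_bits) -> matrix` (one row per SMILES).
#' @export
fp_backend_rdkit <- function(python = "python", radius = 2L) {
  function(smiles, n_bits = 1024L) {
    infile <- tempfile(fileext = ".txt"); outfile <- tempfile(fileext = ".txt")
    on.exit(unlink(c(infile, outfile)))
    writeLines(smiles, infile)
    script <- sprintf(paste0(
      "import sys\n",
      "from rdkit import Chem\n",
      "from rdkit.Chem import rdFingerprintGenerator\n",
      "gen = rdFingerprintGenerator.GetMorganGenerator(radius=%d, fpSize=%d)\n",
      "out = open(sys.argv[2], 'w')\n",
      "for line in open(sys.argv[1]):\n",
      "    smi = line.strip()\n",
      "    mol = Chem.MolFromSmiles(smi)\n",
      "    if mol is None:\n",
      "        sys.stderr.write('unparseable SMILES: ' + smi + chr(10))\n",
      "        sys.exit(2)\n",
      "    out.write(gen.GetFingerprint(mol).ToBitString() + chr(10))\n",
      "out.close()\n"), radius, n_bits)
    sf <- tempfile(fileext = ".py")
    writeLines(script, sf)
    status <- system2(python, c(sf, infile, outfile), stdout = FALSE, stderr = FALSE)
    unlink(sf)
    if (!identical(status, 0L)) {
      abort_confunnel("RDKit backend failed (unparseable SMILES or missing rdkit)",
                      "parse_error")
    }
    bits <- readLines(outfile)
    t(vapply(bits, function(b) as.integer(strsplit(b, "")[[1]]),
             integer(n_bits), USE.NAMES = FALSE))
  }
}

#' Optimal docking score of a conformer ensemble
#'
#' The reported score for a compound is the minimum (most negative) over its
#' conformer scores.
#'
#' @param conformer_scores Non-empty numeric vector, kcal/mol.
#' @return The minimum score.
#' @export
best_score <- function(conformer_scores) {
  if (length(conformer_scores) == 0) {
    abort_confunnel("empty conformer score sequence", "empty_input")
  }
  min(conformer_scores)
}

#' Paired t-test from its closed form
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on n - 1 degrees of freedom, two-sided p
#' from the t CDF. When every difference is zero the statistic is defined as
#' 0 with p = 1 (the no-signal case arises exactly when conformer noise is
#' switched off).
#'
#' @param x,y Paired numeric vectors.
#' @return List `t`, `p_value`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort_confunnel("paired vectors differ in length",
                                              "invalid_config")
  n <- length(x)
  if (n < 2) abort_confunnel("need at least 2 pairs", "insufficient_sample")
  d <- x - y
  md <- mean(d); sdd <- sd(d)
  if (sdd == 0) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
  } else {
    t_stat <- md / (sdd / sqrt(n))
  }
  p <- if (is.infinite(t_stat)) 0 else 2 * pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p_value = p, df = n - 1, mean_diff = md)
}

#' Conformer-count sensitivity experiment
#'
#' Scores the same compounds at each requested conformer count (paired
#' design) using the synthetic docking oracle, then summarises mean and SD
#' of the optimal scores per count and runs paired t-tests on requested
#' pairs. More conformers can only deepen the minimum, so with conformer
#' noise on the mean optimal score decreases with ensemble size; the
#' experiment quantifies the plateau used to pick a production ensemble
#' size.
#'
#' @param library A `compound_library` (first `n_compounds` rows are used).
#' @param oracle An [oracle_config()].
#' @param counts Distinct conformer counts, all >= 1.
#' @param n_compounds Compounds per count (paired; default 1000).
#' @param pairs List of 2-vectors of counts to compare (default consecutive
#'   pairs).
#' @param seed Seed for the compound subsample.
#' @return List: `summary` (tibble `k`, `mean_best`, `sd_best`, `n`),
#'   `comparisons` (tibble `k1`, `k2`, `t`, `p_value`), `scores`
#'   (n_compounds x length(counts) matrix of best scores).
#' @export
conformer_sensitivity <- function(library, oracle, counts,
                                  n_compounds = 1000L,
                                  pairs = NULL, seed = 1L) {
  if (length(counts) == 0 || any(counts < 1)) {
    abort_confunnel("`counts` must be non-empty, all >= 1", "invalid_config")
  }
  if (anyDuplicated(counts)) {
    abort_confunnel("`counts` must be distinct", "invalid_config")
  }
  if (n_compounds < 2) abort_confunnel("need >= 2 compounds", "insufficient_sample")
  truth <- library$truth
  if (nrow(truth) < n_compounds) {
    abort_confunnel("library smaller than `n_compounds`", "insufficient_sample")
  }
  idx <- with_seed(seed, sample(nrow(truth), n_compounds))
  ids <- truth$id[idx]
  npl <- truth$n_planted_bits[idx]
  kmax <- max(counts)
  # one oracle call per compound at the largest count; nested noise streams
  # make the first k draws identical across counts
  best <- matrix(NA_real_, n_compounds, length(counts),
                 dimnames = list(NULL, paste0("k", counts)))
  for (i in seq_len(n_compounds)) {
    res <- docking_oracle(ids[i], n_conformers = kmax, config = oracle,
                          n_planted = npl[i])
    best[i, ] <- vapply(counts, function(k) min(res$conformer_scores[seq_len(k)]),
                        numeric(1))
  }
  summary_tab <- tibble::tibble(
    k = as.integer(counts),
    mean_best = unname(colMeans(best)),
    sd_best = unname(apply(best, 2, sd)),
    n = as.integer(n_compounds))
  if (is.null(pairs)) {
    ord <- order(counts)
    pairs <- if (length(counts) > 1) {
      lapply(seq_len(length(counts) - 1), function(i) counts[ord][c(i, i + 1)])
    } else list()
  }
  comparisons <- dplyr::bind_rows(lapply(pairs, function(pr) {
    i1 <- match(pr[1], counts); i2 <- match(pr[2], counts)
    tt <- paired_t_test(best[, i1], best[, i2])
    tibble::tibble(k1 = pr[1], k2 = pr[2], t = tt$t, p_value = tt$p_value)
  }))
  list(summary = summary_tab, comparisons = comparisons, scores = best)
}
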