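# Internal helpers: seeded RNG streams, rounding, input checks.

#' @importFrom stats rnorm rbinom runif median sd pt cor cor.test prcomp quantile
#' @importFrom utils head
NULL

abort_confunnel <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "confunnel_error")))
}

#' Derive a per-entity RNG seed from a base seed and a string id
#'
#' Polynomial rolling hash of the id folded into the base seed, reduced
#' modulo 2^31 - 1 so results are identical across platforms and independent
#' of iteration order.
#' @keywords internal
hash_seed <- function(seed, id) {
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Round half-up to `digits` decimals (printed-table convention; base round()
# uses round-half-even).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)
}

stopifnot_scalar_prob <- function(x, name, open_low = TRUE, open_high = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_low) x > 0 else x >= 0) &&
    (if (open_high) x < 1 else x <= 1)
  if (!ok) abort_confunnel(sprintf("`%s` must be a probability in %s0, 1%s",
                                   name,
                                   if (open_low) "(" else "[",
                                   if (open_high) ")" else "]"),
                           "invalid_config")
  invisible(x)
}
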