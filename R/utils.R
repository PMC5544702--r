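#' @keywords internal
"_PACKAGE"

## Stage-prefixed logging. Messages (not cat) so callers can suppress;
## per-draw diagnostics only when options(clearscore.verbose = TRUE).
clear_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

clear_log_verbose <- function(stage, ...) {
  if (isTRUE(getOption("clearscore.verbose", FALSE))) clear_log(stage, ...)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` (Mersenne-Twister, the documented PRNG
#' for every stochastic step in this package) and restores the caller's RNG
#' state afterwards, so seeded internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Stable 31-adic string hash into [0, 2^31 - 2]; used to derive per-sample
## seeds so scores are invariant to cohort ordering and subsetting.
stable_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

per_sample_seed <- function(seed, sample_id) {
  as.integer((as.numeric(seed) + stable_hash(sample_id)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
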