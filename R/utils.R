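# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a reproducible state for the duration of `expr` and
#' restores the caller's RNG state afterwards, so library functions never
#' leak randomness into (or consume randomness from) the session.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic derivation of stage seeds from one root seed. Keeps every
# derived seed a positive 32-bit integer so set.seed() accepts it.
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (as.numeric(seed) * 48271 + h * 1009 + as.numeric(index)) %% 2147483629
  as.integer(s + 1)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("invalid parameter: `%s` must be a single integer >= %d (got %s)",
                 name, min, deparse(x)), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("invalid parameter: `%s` must be in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
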