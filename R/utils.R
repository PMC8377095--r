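# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls stay free of RNG side
#' effects. Used everywhere a contract promises determinism given a seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Counter-based seed derivation: one master seed spawns independent
# sub-streams keyed by small integer counters, so extending a cohort or
# adding repeats never reshuffles existing draws. Result stays within the
# 32-bit signed range R accepts in set.seed().
mix_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) h <- (h * 48271 + as.double(k) + 11) %% 2147483587
  as.integer(h) + 1L
}

# Deterministic small hash of a string, for per-patient seed streams.
string_key <- function(x) {
  sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 1000003
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("field '%s' must be a single proportion in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

check_positive <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok)
    stop(sprintf("field '%s' must be a single %s number", name,
                 if (allow_zero) "non-negative" else "positive"),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min &&
    x == floor(x)
  if (!ok)
    stop(sprintf("field '%s' must be an integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}
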