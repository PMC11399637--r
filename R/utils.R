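# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Leaves the caller's RNG stream untouched so package functions are
# reproducible without side effects.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# derive a distinct 32-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483647L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# log-density of a zero-mean multivariate normal (used by the reference
# likelihood implementations; the production fit evaluates this inside TMB)
dmvnorm0_log <- function(x, sigma) {
  L <- chol(sigma)
  z <- backsolve(L, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# truncated normal sampler (inverse-CDF; exact for the modest truncation
# used for broiler body weights)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", name), call. = FALSE)
  }
  invisible(x)
}
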