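# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# With seed = NULL the global stream is used untouched, so callers can
# compose repower functions inside their own set.seed() blocks.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force initialisation of the global stream
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

stop_if_not_prob <- function(x, name, upper = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= upper) {
    stop(sprintf("`%s` must be a single number in (0, %s), got %s",
                 name, format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

# Upper-u quantile of N(0,1): z_u.
z_upper <- function(u) qnorm(u, lower.tail = FALSE)
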