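#' Numerically stable log-sum-exp
#'
#' @param x Numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards; keeps fold assignment and simulators from
# perturbing the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min))
  as.integer(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x >= 1)
    stop(sprintf("`%s` must be in (0, 1)", name))
  x
}
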