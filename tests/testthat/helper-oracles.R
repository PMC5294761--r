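# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Bayes factor is recomputed by numerical
# quadrature of the Gaussian marginal-likelihood ratio, the exact binomial
# p-value by full enumeration, OLS by the normal equations, and 1-D
# likelihood maxima by interval grid search.

# Bayes factor for association: integral of N(beta_hat; beta, V) N(beta; 0, W)
# over beta, divided by N(beta_hat; 0, V), with beta_hat = z * sqrt(V).
quad_abf <- function(z, V, W) {
  if (W == 0) return(1)
  bh <- z * sqrt(V)
  mu <- bh * W / (V + W)
  sd <- sqrt(V * W / (V + W))
  num <- stats::integrate(function(b) dnorm(bh, b, sqrt(V)) * dnorm(b, 0, sqrt(W)),
                          lower = mu - 12 * sd, upper = mu + 12 * sd,
                          rel.tol = 1e-12, abs.tol = 0)$value
  num / dnorm(bh, 0, sqrt(V))
}

# Two-sided exact binomial p at p0 = 0.5 by enumerating all n+1 outcomes and
# summing those no more probable than the observed one.
enum_binom_p <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# OLS by the normal equations; returns beta, se, t, p for each column.
normal_eq_ols <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  t <- b / se
  list(beta = as.vector(b), se = se, t = as.vector(t),
       p = 2 * pt(abs(as.vector(t)), df, lower.tail = FALSE))
}

# Maximize a 1-D function by iterated grid refinement to tolerance `tol`.
grid_max <- function(f, lo, hi, tol = 1e-6) {
  for (i in 1:60) {
    xs <- seq(lo, hi, length.out = 41)
    ys <- vapply(xs, f, numeric(1))
    j <- which.max(ys)
    lo <- xs[max(1, j - 1)]
    hi <- xs[min(length(xs), j + 1)]
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Small helper: posterior table with prescribed posteriors for credible-set
# rule checks.
posterior_fixture <- function(post, ids = sprintf("v%d", seq_along(post))) {
  tibble::tibble(variant_id = ids, chrom = "chr1", pos = seq_along(post),
                 signal_id = "s1", posterior = post)
}

# z-score that yields a target Wakefield ABF at V = 1, W = 1
# (inverse of ABF = sqrt(1/2) exp(z^2 / 4)).
z_for_abf <- function(abf) sqrt(4 * log(abf * sqrt(2)))

# Analysis prior variance used for simulated z-score input throughout the
# suite: prior SD 5 on the z scale, moment-matched to the simulated causal
# z mean of 5.
W_Z <- 25
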