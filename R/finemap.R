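#' Approximate Bayes factor for association at a single variant
#'
#' Computes Wakefield's approximate Bayes factor in favour of association
#' from a z-score, the variance `V` of the effect estimate, and the prior
#' variance `W` of the true effect under the alternative. With
#' `r = W / (V + W)`,
#' \deqn{ABF = \sqrt{1 - r}\,\exp(z^2 r / 2)}
#' so values above 1 favour association. All arithmetic is done on the log
#' scale; use [wakefield_log_abf()] directly when Bayes factors may be very
#' large.
#'
#' @param z Numeric vector of z-scores (effect estimate / standard error).
#' @param V Numeric vector of sampling variances of the effect estimate
#'   (`se^2`); on the z scale this is 1. Must be positive.
#' @param W Prior variance of the effect size under the alternative; `W = 0`
#'   collapses the prior to the point null and gives `ABF = 1`. Default 0.04
#'   (prior SD 0.2 on the log-odds scale), the conventional choice.
#' @return Numeric vector of Bayes factors (natural scale for
#'   `wakefield_abf`, natural log for `wakefield_log_abf`).
#' @examples
#' wakefield_abf(z = 4, V = 0.01, W = 0.04)  # about 269
#' wakefield_abf(z = 3, V = 1, W = 0)        # exactly 1
#' @export
wakefield_abf <- function(z, V = 1, W = 0.04) {
  exp(wakefield_log_abf(z, V, W))
}

#' @rdname wakefield_abf
#' @export
wakefield_log_abf <- function(z, V = 1, W = 0.04) {
  if (any(!is.finite(z))) stop("z must be finite")
  if (any(!is.finite(V)) || any(V <= 0)) stop("V must be finite and > 0")
  if (any(!is.finite(W)) || any(W < 0)) stop("W must be finite and >= 0")
  r <- W / (V + W)
  0.5 * log1p(-r) + z^2 * r / 2
}

#' Fine-mapping configuration
#'
#' @param W Prior effect-size variance for [wakefield_abf()]; must be > 0.
#' @param level Credible-set probability level in (0, 1); default 0.99.
#' @return A list of class `abf_config`.
#' @export
abf_config <- function(W = 0.04, level = 0.99) {
  stopifnot(is.numeric(W), length(W) == 1, is.finite(W), W > 0,
            is.numeric(level), length(level) == 1, level > 0, level < 1)
  structure(list(W = W, level = level), class = "abf_config")
}

# z and V from a summary-stat table: beta/se preferred when both present,
# otherwise the z column with V fixed at 1 (W then lives on the z scale).
.stat_z_V <- function(stats) {
  has_bse <- all(c("beta", "se") %in% names(stats)) &&
    !anyNA(stats$beta) && !anyNA(stats$se)
  if (has_bse) {
    if (any(stats$se <= 0)) stop("se must be > 0")
    list(z = stats$beta / stats$se, V = stats$se^2)
  } else if ("z" %in% names(stats)) {
    if (any(!is.finite(stats$z))) stop("z must be finite")
    list(z = stats$z, V = rep(1, nrow(stats)))
  } else {
    stop("summary statistics need either a `z` column or `beta` and `se` columns")
  }
}

#' Single-causal posterior probabilities for one association signal
#'
#' Under the assumption of exactly one causal variant per signal, the
#' posterior causal probability of variant j is
#' `prior_j * ABF_j / sum_k prior_k * ABF_k`. Priors default to flat and are
#' renormalized internally; posteriors are computed through log-sum-exp so
#' arbitrarily large Bayes factors cannot overflow.
#'
#' @param stats Data frame of summary statistics for a single signal with
#'   columns `variant_id` and either `z` or `beta` + `se` (plus optional
#'   `chrom`, `pos`, `signal_id`, carried through).
#' @param priors Optional nonnegative prior weights, one per variant; not all
#'   zero. `NULL` means flat.
#' @param config An [abf_config()].
#' @return The input table plus columns `log_abf`, `prior`, `posterior`.
#' @export
signal_posteriors <- function(stats, priors = NULL, config = abf_config()) {
  stats <- tibble::as_tibble(stats)
  if (nrow(stats) == 0) stop("signal has no variants")
  if ("signal_id" %in% names(stats) && length(unique(stats$signal_id)) > 1)
    stop("signal_posteriors() expects a single signal; see finemap_signals()")
  zv <- .stat_z_V(stats)
  stats$log_abf <- wakefield_log_abf(zv$z, zv$V, config$W)
  if (is.null(priors)) priors <- rep(1, nrow(stats))
  if (length(priors) != nrow(stats))
    stop("priors length must equal the number of variants")
  if (any(priors < 0) || all(priors == 0))
    stop("priors must be nonnegative and not all zero")
  lw <- log(priors) + stats$log_abf
  stats$prior <- priors / sum(priors)
  stats$posterior <- exp(lw - logsumexp(lw))
  stats
}

#' Credible set at a probability level
#'
#' Sorts variants by descending posterior and returns the smallest prefix
#' whose cumulative posterior reaches the level (a cumulative probability
#' exactly at the level is included). Ties are broken deterministically by
#' (posterior desc, chrom, pos, variant_id).
#'
#' @param table A posterior table from [signal_posteriors()] (one signal).
#' @param level Probability level in (0, 1).
#' @return A list of class `credible_set` with elements `signal_id`, `level`,
#'   `variant_id` (ordered), `cumulative` (cumulative posterior at each
#'   member), and `size`.
#' @export
credible_set <- function(table, level = 0.99) {
  stopifnot(level > 0, level < 1)
  if (nrow(table) == 0) stop("empty posterior table")
  chrom <- if ("chrom" %in% names(table)) table$chrom else rep("", nrow(table))
  pos <- if ("pos" %in% names(table)) table$pos else rep(0L, nrow(table))
  ord <- order(-table$posterior, chrom, pos, table$variant_id)
  post <- table$posterior[ord]
  cum <- cumsum(post)
  size <- which(cum >= level - 1e-12)[1]
  if (is.na(size)) size <- length(post)  # numerical guard; cum sums to 1
  structure(list(
    signal_id = if ("signal_id" %in% names(table)) table$signal_id[1] else NA_character_,
    level = level,
    variant_id = table$variant_id[ord][seq_len(size)],
    cumulative = cum[seq_len(size)],
    size = size
  ), class = "credible_set")
}

#' @method print credible_set
#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("Credible set (level %.2f) for signal %s: %d variant(s), cumulative %.4f\n",
              x$level, x$signal_id, x$size, x$cumulative[x$size]))
  invisible(x)
}

#' Fine-map every signal in a summary-statistic table
#'
#' Splits a multi-signal table by `signal_id`, computes single-causal
#' posteriors with flat priors, and marks credible-set membership.
#'
#' @param stats Summary-statistic table with a `signal_id` column.
#' @param config An [abf_config()].
#' @return A list with `posteriors` (one tibble, all signals, with
#'   `in_credible_set` flag) and `credible_sets` (named list of
#'   [credible_set()] objects).
#' @export
finemap_signals <- function(stats, config = abf_config()) {
  stats <- tibble::as_tibble(stats)
  if (!"signal_id" %in% names(stats)) stop("missing required column `signal_id`")
  parts <- split(stats, factor(stats$signal_id, levels = unique(stats$signal_id)))
  out <- lapply(parts, function(s) {
    p <- signal_posteriors(s, config = config)
    cs <- credible_set(p, config$level)
    p$in_credible_set <- p$variant_id %in% cs$variant_id
    list(posteriors = p, cs = cs)
  })
  list(
    posteriors = dplyr::bind_rows(lapply(out, `[[`, "posteriors")),
    credible_sets = lapply(out, `[[`, "cs")
  )
}
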