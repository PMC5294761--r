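#' Library-size normalization to a fixed total
#'
#' Scales each sample's column so its counts sum to `target_total` reads
#' (the usual pre-step before the low-expression filter and rank
#' normalization).
#'
#' @param mat Numeric matrix, features x samples.
#' @param target_total Target column sum; default 20 million.
#' @return Matrix of the same shape.
#' @export
normalize_library_size <- function(mat, target_total = 2e7) {
  totals <- colSums(mat)
  if (any(totals <= 0)) stop("every sample must have positive total counts")
  sweep(mat, 2, target_total / totals, `*`)
}

#' Drop features expressed too rarely
#'
#' Excludes features whose value is below `min_count` in strictly more than
#' `max_frac_below` of the samples: with the defaults, a feature below 1
#' count in more than 20% of samples is dropped, so 2 of 10 samples below
#' threshold keeps the feature and 3 of 10 drops it.
#'
#' @param mat Numeric matrix, features x samples (rownames = feature ids).
#' @param min_count Value a sample must reach; default 1.
#' @param max_frac_below Tolerated fraction of samples below `min_count`
#'   (strict inequality); default 0.20.
#' @return The filtered matrix (possibly zero rows, with a message).
#' @export
filter_low_expression <- function(mat, min_count = 1, max_frac_below = 0.20) {
  frac_below <- rowMeans(mat < min_count)
  keep <- frac_below <= max_frac_below
  if (!any(keep)) message("filter_low_expression: no feature passed the filter")
  mat[keep, , drop = FALSE]
}

#' Rank-based inverse-normal transform
#'
#' Maps the rank r (of n, average ranks for ties) of each value to the
#' standard-normal quantile at (r - 0.5) / n, the usual per-feature rank
#' normalization for expression traits.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Numeric vector of the same length.
#' @export
rank_inverse_normal <- function(values) {
  if (anyNA(values)) stop("values must not contain NA")
  if (length(unique(values)) < 2)
    stop("rank_inverse_normal() requires at least two distinct values")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Candidate cis feature-variant pairs
#'
#' Two window conventions: `gene_window_100kb` pairs a variant with a
#' feature when it lies within 100 kb of the feature's anchor position
#' (`cisDist`-style), `tss_flank_1mb` when it lies within 1 Mb of the
#' feature's TSS. Both bounds are inclusive; the chromosome must match.
#'
#' @param features Tibble with `feature_id`, `chrom`, and `pos` (anchor) or
#'   `tss`; `tss` is used for the 1 Mb mode and `pos` (falling back to
#'   `tss`) for the 100 kb mode.
#' @param variants Tibble with `variant_id`, `chrom`, `pos`.
#' @param mode `"gene_window_100kb"` or `"tss_flank_1mb"`.
#' @return Tibble of `feature_id`, `variant_id`, `distance` pairs.
#' @export
cis_pairs <- function(features, variants,
                      mode = c("gene_window_100kb", "tss_flank_1mb")) {
  mode <- match.arg(mode)
  features <- tibble::as_tibble(features)
  variants <- tibble::as_tibble(variants)
  window <- if (mode == "gene_window_100kb") 1e5 else 1e6
  anchor <- if (mode == "tss_flank_1mb") {
    if (!"tss" %in% names(features)) stop("tss_flank_1mb mode needs a `tss` column")
    features$tss
  } else if ("pos" %in% names(features)) features$pos else features$tss
  out <- lapply(seq_len(nrow(features)), function(i) {
    same <- variants$chrom == features$chrom[i]
    d <- abs(variants$pos - anchor[i])
    hit <- same & d <= window
    if (!any(hit)) return(NULL)
    tibble::tibble(feature_id = features$feature_id[i],
                   variant_id = variants$variant_id[hit],
                   distance = d[hit])
  })
  dplyr::bind_rows(out)
}

#' Covariate-adjusted linear cis-eQTL fit for one pair
#'
#' Ordinary least squares of expression on genotype dosage with an intercept
#' and the supplied covariates (age and sex in the canonical setup); reports
#' the dosage term's effect, standard error, t statistic, and two-sided
#' p-value on the residual degrees of freedom. A numerically exact fit
#' (zero residual variance) reports the p-value at the double-precision
#' floor; a rank-deficient design is rejected with the offending column
#' named.
#'
#' @param expression Numeric response vector.
#' @param dosage Numeric genotype vector in [0, 2], same length.
#' @param covariates Optional data frame of numeric covariates (same rows).
#' @return One-row tibble: `beta`, `se`, `t`, `p`, `n`.
#' @export
fit_cis_eqtl <- function(expression, dosage, covariates = NULL) {
  n <- length(expression)
  stopifnot(length(dosage) == n)
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, as.matrix(covariates))
  }
  ok <- stats::complete.cases(X) & is.finite(expression)
  X <- X[ok, , drop = FALSE]
  y <- expression[ok]
  n <- length(y)
  if (n < ncol(X) + 1)
    stop(sprintf("need at least %d complete samples, have %d", ncol(X) + 1, n))
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    drop_col <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop(sprintf("collinear design: column(s) %s", paste(drop_col, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  s2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(pmax(s2 * diag(XtX_inv), 0))
  beta <- fit$coefficients["dosage"]
  se_b <- se[which(colnames(X) == "dosage")]
  if (se_b == 0 || s2 == 0) {
    tstat <- sign(beta) * Inf
    p <- .Machine$double.xmin
  } else {
    tstat <- beta / se_b
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
  }
  tibble::tibble(beta = unname(beta), se = unname(se_b), t = unname(tstat),
                 p = p, n = n)
}

#' cis-eQTL scan over all window pairs
#'
#' @param expression Matrix features x samples, with a `meta` attribute or a
#'   separate `features` tibble giving `feature_id`, `chrom`, `pos`/`tss`.
#' @param genotypes Matrix variants x samples (dosages 0-2).
#' @param features,variants Position tibbles as in [cis_pairs()].
#' @param covariates Data frame of per-sample covariates aligned to the
#'   shared sample order, or NULL.
#' @param mode Window mode, as in [cis_pairs()].
#' @return Tibble with `feature_id`, `variant_id`, `distance`, `beta`, `se`,
#'   `t`, `p`, `n`, sorted by p.
#' @export
run_cis_eqtl <- function(expression, genotypes, features, variants,
                         covariates = NULL,
                         mode = "gene_window_100kb") {
  common <- intersect(colnames(expression), colnames(genotypes))
  if (!length(common)) stop("expression and genotype matrices share no samples")
  expression <- expression[, common, drop = FALSE]
  genotypes <- genotypes[, common, drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("sample_id" %in% names(covariates)) {
      rownames(covariates) <- covariates$sample_id
      covariates$sample_id <- NULL
    }
    covariates <- covariates[common, , drop = FALSE]
  }
  pairs <- cis_pairs(features, variants, mode)
  pairs <- pairs[pairs$feature_id %in% rownames(expression) &
                 pairs$variant_id %in% rownames(genotypes), , drop = FALSE]
  if (!nrow(pairs))
    return(tibble::tibble(feature_id = character(0), variant_id = character(0),
                          distance = numeric(0), beta = numeric(0),
                          se = numeric(0), t = numeric(0), p = numeric(0),
                          n = integer(0)))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    fit_cis_eqtl(expression[pairs$feature_id[i], ],
                 genotypes[pairs$variant_id[i], ], covariates)
  })
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(res))
  out[order(out$p), , drop = FALSE]
}

#' Analytic power of a cis-eQTL test
#'
#' Per-allele standardized-effect convention: for an additive variant with
#' minor allele frequency `maf` and effect `beta` in phenotype-SD units per
#' allele, the association chi-square (1 df) has non-centrality
#' `n * beta^2 * 2 * maf * (1 - maf)`; power is the probability that it
#' exceeds the central critical value at level `alpha`. `beta = 0` returns
#' exactly `alpha`.
#'
#' @param n Sample size.
#' @param maf Minor allele frequency in (0, 1).
#' @param beta Per-allele effect in phenotype-SD units.
#' @param alpha Significance level.
#' @return Power in [alpha, 1].
#' @export
eqtl_power <- function(n, maf, beta, alpha) {
  stopifnot(n >= 1, maf > 0, maf < 1, alpha > 0, alpha < 1, is.finite(beta))
  ncp <- n * beta^2 * 2 * maf * (1 - maf)
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
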