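.check_counts <- function(records) {
  records <- tibble::as_tibble(records)
  req <- c("variant_id", "sample_id", "ref_count", "alt_count", "het_flag")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop(sprintf("allele-count table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(records$ref_count < 0) || any(records$alt_count < 0) ||
      any(records$ref_count != round(records$ref_count)) ||
      any(records$alt_count != round(records$alt_count)))
    stop("ref_count and alt_count must be nonnegative integers")
  records
}

#' Retain variants testable for allelic imbalance
#'
#' A variant is testable when enough heterozygote samples individually carry
#' enough reads over the variant base: by default at least 5 reads
#' (`ref_count + alt_count`) in each of at least 3 distinct heterozygote
#' samples. Non-heterozygote records are ignored. The alternative pooled
#' reading of the depth rule (at least `min_reads` reads summed across at
#' least `min_het_samples` covered het samples) is available via
#' `pool_filter = TRUE`.
#'
#' @param records Allele-count tibble: `variant_id`, `sample_id`,
#'   `ref_count`, `alt_count`, `het_flag`.
#' @param min_reads Per-sample read minimum; default 5.
#' @param min_het_samples Minimum qualifying het samples; default 3
#'   (a strict reading of "more than 2").
#' @param pool_filter Use the pooled-depth reading instead.
#' @return Character vector of retained variant ids, in first-seen order.
#' @export
filter_testable_variants <- function(records, min_reads = 5,
                                     min_het_samples = 3,
                                     pool_filter = FALSE) {
  records <- .check_counts(records)
  het <- records[records$het_flag, , drop = FALSE]
  if (!nrow(het)) return(character(0))
  het$depth <- het$ref_count + het$alt_count
  parts <- split(het, factor(het$variant_id, levels = unique(het$variant_id)))
  keep <- vapply(parts, function(p) {
    if (pool_filter) sum(p$depth) >= min_reads &&
      sum(p$depth > 0) >= min_het_samples
    else sum(p$depth >= min_reads) >= min_het_samples
  }, logical(1))
  names(parts)[keep]
}

#' Exact binomial test of pooled allelic imbalance at one variant
#'
#' Pools ref and alt read counts across qualifying heterozygote samples and
#' tests the alt fraction against 0.5 with an exact binomial test. The
#' two-sided p-value follows the minimum-likelihood convention (sum of
#' probabilities of all outcomes no more probable than the observed one,
#' as in [stats::binom.test()]); `sided = "double"` instead doubles the
#' smaller tail and caps at 1. The direction field compares the pooled count
#' of the designated risk allele with the other allele: `risk_lower` when
#' the risk allele has fewer reads (lower accessibility), `risk_higher` when
#' more, `none` on an exact tie.
#'
#' @param records Allele-count rows for a single variant.
#' @param risk_allele `"ref"` or `"alt"`: which allele increases disease
#'   risk. `NA` suppresses the direction call.
#' @param min_reads Per-sample depth required for a het sample to enter the
#'   pool (the same threshold used by [filter_testable_variants()]).
#' @param sided `"minlik"` (default) or `"double"`.
#' @return A one-row tibble: `variant_id`, `n_het_samples_passing`,
#'   `pooled_ref`, `pooled_alt`, `p_value`, `direction`.
#' @export
pooled_binomial_test <- function(records, risk_allele = NA_character_,
                                 min_reads = 5,
                                 sided = c("minlik", "double")) {
  sided <- match.arg(sided)
  records <- .check_counts(records)
  if (length(unique(records$variant_id)) != 1)
    stop("pooled_binomial_test() expects records for exactly one variant")
  het <- records[records$het_flag, , drop = FALSE]
  het <- het[het$ref_count + het$alt_count >= min_reads, , drop = FALSE]
  ref <- sum(het$ref_count); alt <- sum(het$alt_count)
  n <- ref + alt
  if (n == 0) stop("pooled depth is zero; variant should not have passed the filter")
  p <- if (sided == "minlik") {
    stats::binom.test(alt, n, p = 0.5)$p.value
  } else {
    min(1, 2 * min(stats::pbinom(alt, n, 0.5),
                   stats::pbinom(alt - 1, n, 0.5, lower.tail = FALSE)))
  }
  risk_count <- if (is.na(risk_allele)) NA_real_
                else if (risk_allele == "alt") alt else ref
  other <- if (is.na(risk_allele)) NA_real_ else n - risk_count
  direction <- if (is.na(risk_allele) || risk_count == other) "none"
               else if (risk_count < other) "risk_lower" else "risk_higher"
  tibble::tibble(variant_id = records$variant_id[1],
                 n_het_samples_passing = nrow(het),
                 pooled_ref = ref, pooled_alt = alt,
                 p_value = min(p, 1), direction = direction)
}

#' Allelic-imbalance analysis over an allele-count table
#'
#' Applies the retention filter, then the pooled exact binomial test per
#' retained variant, annotating direction relative to each variant's risk
#' allele.
#'
#' @inheritParams filter_testable_variants
#' @param variants Optional tibble with `variant_id` and `risk_allele`
#'   (`"ref"`/`"alt"`); variants absent from it get no direction call.
#' @param sided Passed to [pooled_binomial_test()].
#' @return Tibble of [pooled_binomial_test()] rows, one per retained variant.
#' @export
test_allelic_imbalance <- function(records, variants = NULL, min_reads = 5,
                                   min_het_samples = 3, pool_filter = FALSE,
                                   sided = "minlik") {
  records <- .check_counts(records)
  keep <- filter_testable_variants(records, min_reads, min_het_samples,
                                   pool_filter)
  if (!length(keep))
    return(tibble::tibble(variant_id = character(0),
                          n_het_samples_passing = integer(0),
                          pooled_ref = numeric(0), pooled_alt = numeric(0),
                          p_value = numeric(0), direction = character(0)))
  risk <- if (is.null(variants)) NULL
          else stats::setNames(variants$risk_allele, variants$variant_id)
  rows <- lapply(keep, function(v) {
    ra <- if (is.null(risk) || is.na(risk[v])) NA_character_ else unname(risk[v])
    pooled_binomial_test(records[records$variant_id == v, , drop = FALSE],
                         risk_allele = ra, min_reads = min_reads,
                         sided = sided)
  })
  dplyr::bind_rows(rows)
}

#' Sorted allelic-imbalance report
#'
#' @param results Output of [test_allelic_imbalance()].
#' @param fdr Add a Benjamini-Hochberg adjusted column? Off by default
#'   (small candidate sets are conventionally reported with raw p-values).
#' @return The results sorted by ascending p-value (ties by variant_id),
#'   optionally with a `p_bh` column.
#' @export
imbalance_report <- function(results, fdr = FALSE) {
  if (!nrow(results)) return(results)
  out <- results[order(results$p_value, results$variant_id), , drop = FALSE]
  if (fdr) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
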