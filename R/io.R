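# Shared readers/writers. All tabular interchange is TSV with explicit
# headers; BED is 0-based half-open; VCF is 1-based with GT genotypes.
# Floating-point columns are written at full precision (the 6-significant-
# digit convention applies to printed reports, not interchange files).

.read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column `%s` at data row %d",
                   path, col, bad[1]))
    df[[col]] <- v
  }
  tibble::as_tibble(df)
}

.write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write association summary statistics
#'
#' The summary-stat TSV carries `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#' `risk_allele`, `signal_id` and either `z` or `beta` + `se`. Errors name
#' the missing column or the offending row.
#'
#' @param path File path.
#' @param stats Summary-stat tibble (for the writer).
#' @return Tibble of typed records (reader) or the path, invisibly (writer).
#' @export
read_summary_stats <- function(path) {
  df <- .read_tsv_checked(path, c("variant_id", "signal_id"),
                          numeric_cols = c("pos", "z", "beta", "se"))
  if (!("z" %in% names(df)) && !all(c("beta", "se") %in% names(df)))
    stop(sprintf("%s: need a `z` column or `beta` and `se` columns", path))
  df
}

#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(stats, path) .write_tsv(stats, path)

#' Read / write a binary annotation matrix
#'
#' Stored as TSV with a leading `variant_id` column and one 0/1 column per
#' annotation.
#'
#' @param path File path.
#' @param mat Integer 0/1 matrix with variant_id rownames (writer).
#' @return Matrix with rownames (reader) or the path (writer).
#' @export
read_annotation_matrix <- function(path) {
  df <- .read_tsv_checked(path, "variant_id")
  m <- as.matrix(df[, setdiff(names(df), "variant_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$variant_id
  m
}

#' @rdname read_annotation_matrix
#' @export
write_annotation_matrix <- function(mat, path) {
  df <- data.frame(variant_id = rownames(mat), mat, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read / write per-sample allelic read counts
#'
#' @param path File path.
#' @param counts Allele-count tibble (writer).
#' @return Tibble (reader) or the path (writer).
#' @export
read_allele_counts <- function(path) {
  df <- .read_tsv_checked(path,
                          c("variant_id", "sample_id", "ref_count",
                            "alt_count", "het_flag"),
                          numeric_cols = c("ref_count", "alt_count"))
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  df$het_flag <- as.logical(df$het_flag)
  df
}

#' @rdname read_allele_counts
#' @export
write_allele_counts <- function(counts, path) .write_tsv(counts, path)

#' Read / write chromatin-state segments as BED
#'
#' BED4 (`chrom`, `start`, `end`, `state`) when a single cell type is given,
#' BED5 with the cell type in column 5 otherwise; 0-based half-open.
#'
#' @param path File path.
#' @param segments Segment tibble (writer).
#' @param cell_type Cell-type label for BED4 files lacking column 5.
#' @return Segment tibble (reader) or the path (writer).
#' @export
read_bed_states <- function(path, cell_type = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop(sprintf("%s: BED must have at least 4 columns", path))
  out <- tibble::tibble(chrom = df[[1]], start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]), state = df[[4]])
  out$cell_type <- if (ncol(df) >= 5) df[[5]]
                   else if (!is.null(cell_type)) cell_type
                   else stop(sprintf("%s: BED4 needs an explicit cell_type", path))
  out
}

#' @rdname read_bed_states
#' @export
write_bed_states <- function(segments, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(segments[, c("chrom", "start", "end", "state", "cell_type")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read genotype dosages as a GT-only VCF
#'
#' The writer emits a minimal VCFv4.2 with unphased GT calls (dosage 0/1/2
#' as 0/0, 0/1, 1/1); the reader parses any GT-bearing VCF back into a
#' variants x samples dosage matrix.
#'
#' @param genotypes Variants x samples matrix of dosages in \{0, 1, 2\}.
#' @param variants Tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param path File path (plain text, `.vcf`).
#' @return The path (writer); a dosage matrix (reader).
#' @export
write_genotypes_vcf <- function(genotypes, variants, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  stopifnot(all(genotypes %in% 0:2))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  samples <- colnames(genotypes)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(genotypes)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt_code[as.character(genotypes[i, ])]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  rownames(dos) <- vcfR::getID(v)
  dos
}

#' Read / write an expression matrix with feature positions
#'
#' TSV layout: `feature_id`, `chrom`, `tss`, then one column per sample.
#'
#' @param path File path.
#' @param mat Features x samples matrix (writer).
#' @param features Tibble with `feature_id`, `chrom`, `tss` (writer).
#' @return List `expression` + `features` (reader) or the path (writer).
#' @export
read_expression <- function(path) {
  df <- .read_tsv_checked(path, c("feature_id", "chrom", "tss"),
                          numeric_cols = "tss")
  sample_cols <- setdiff(names(df), c("feature_id", "chrom", "tss"))
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(m) <- df$feature_id
  list(expression = m,
       features = tibble::tibble(feature_id = df$feature_id, chrom = df$chrom,
                                 pos = df$tss, tss = df$tss))
}

#' @rdname read_expression
#' @export
write_expression <- function(mat, features, path) {
  df <- data.frame(feature_id = features$feature_id, chrom = features$chrom,
                   tss = features$tss, mat, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read / write a covariate table
#'
#' @param path File path.
#' @param covariates Tibble with `sample_id` plus numeric covariates.
#' @return Tibble (reader) or the path (writer).
#' @export
read_covariates <- function(path) .read_tsv_checked(path, "sample_id")

#' @rdname read_covariates
#' @export
write_covariates <- function(covariates, path) .write_tsv(covariates, path)

#' Write / read simulation ground truth as JSON
#'
#' @param truth Named list from a `simulate_*` generator.
#' @param path File path (`.json`).
#' @return The path (writer); the truth list (reader).
#' @export
write_sim_truth <- function(truth, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # named atomic vectors become JSON objects so names survive the round trip
  as_obj <- function(x) {
    if (is.list(x)) lapply(x, as_obj)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(as_obj(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out
}

#' Write a posterior table (interchange format)
#'
#' Columns: `variant_id`, `signal_id`, `abf_log10`, `prior`, `posterior`,
#' `in_credible_set` (plus `chrom`/`pos` when present). The natural-log
#' `log_abf` used internally is converted to log10 on disk; the reader
#' converts back.
#'
#' @param posteriors Posterior tibble with `log_abf`.
#' @param path File path.
#' @return The path (writer); the tibble with `log_abf` restored (reader).
#' @export
write_posteriors <- function(posteriors, path) {
  df <- posteriors
  df$abf_log10 <- df$log_abf / log(10)
  df$log_abf <- NULL
  .write_tsv(df, path)
}

#' @rdname write_posteriors
#' @export
read_posteriors <- function(path) {
  df <- .read_tsv_checked(path, c("variant_id", "signal_id", "abf_log10",
                                  "posterior"),
                          numeric_cols = c("abf_log10", "prior", "posterior"))
  df$log_abf <- df$abf_log10 * log(10)
  df$abf_log10 <- NULL
  df
}

#' Write credible sets as JSON
#'
#' @param credible_sets Named list of `credible_set` objects.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_credible_sets <- function(credible_sets, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  payload <- lapply(credible_sets, function(cs)
    list(signal_id = cs$signal_id, level = cs$level, size = cs$size,
         variant_id = cs$variant_id, cumulative = cs$cumulative))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
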