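.default_cell_types <- c("PancIslt", "Gm12878", "HepG2", "HUVEC", "Hsmm",
                         "hESC", "Hmec", "NHLF", "NHEK", "K562",
                         "hASCt1", "hASCt4")

#' Simulation configuration with known ground truth
#'
#' Bundles every parameter of the synthetic-data generators and validates
#' it. The defaults emulate the canonical study design this pipeline was
#' built around: 49 association signals (as at 39 dense-genotyping T2D
#' loci), 50 variants per signal, 36 chromatin annotations (12 cell types x
#' EnhA/EnhWk/TssA) of which the first carries a four-fold true enrichment,
#' a causal z-score mean of 5, 23 heterozygote ATAC samples with a true
#' allelic ratio of 0.3 (risk allele on the less accessible haplotype), and
#' an islet-scale eQTL cohort (n = 174, MAF 0.15, per-allele effect 0.15 SD
#' with age and sex covariates).
#'
#' @param n_signals Number of independent association signals.
#' @param n_variants_per_signal Variants per signal.
#' @param n_annotations Number of binary annotations.
#' @param true_log_enrichments Log prior-odds multiplier per annotation.
#' @param annotation_frequency Bernoulli membership probability.
#' @param causal_z_mean Mean z of the causal variant (SD 1).
#' @param null_z_sd SD of non-causal z-scores.
#' @param rho Optional AR(1) autocorrelation on the z noise (0 = none).
#' @param region_length Simulated region length per signal, bp.
#' @param n_cell_types Cell types for the chromatin-state generator.
#' @param states Chromatin-state vocabulary to emit.
#' @param state_probs Sampling probabilities per state (same order).
#' @param mean_segment_length Mean segment length, bp.
#' @param min_segment_length,max_segment_length Length clamp, bp.
#' @param ase_true_ratio True alt-allele read fraction at het sites.
#' @param ase_depth_mean,ase_depth_size Negative-binomial depth parameters.
#' @param n_het_samples Heterozygote samples per variant.
#' @param eqtl_beta Per-allele expression effect, phenotype-SD units.
#' @param maf Minor allele frequency.
#' @param n_individuals eQTL cohort size.
#' @param n_genes Genes in the simulated eQTL dataset.
#' @param age_effect,sex_effect Covariate effects on expression.
#' @param age_genotype_conf Added age shift per alt allele; nonzero values
#'   confound genotype with age so covariate adjustment matters.
#' @param seed Integer seed (< 2^31 - 10); fixes every draw.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_signals = 49,
                       n_variants_per_signal = 50,
                       n_annotations = 36,
                       true_log_enrichments = c(log(4), rep(0, n_annotations - 1)),
                       annotation_frequency = 0.1,
                       causal_z_mean = 5,
                       null_z_sd = 1,
                       rho = 0,
                       region_length = 2e5,
                       n_cell_types = 12,
                       states = c("EnhA", "EnhWk", "TssA", "Quies"),
                       state_probs = c(0.12, 0.10, 0.08, 0.70),
                       mean_segment_length = 1500,
                       min_segment_length = 200,
                       max_segment_length = Inf,
                       ase_true_ratio = 0.3,
                       ase_depth_mean = 20,
                       ase_depth_size = 5,
                       n_het_samples = 23,
                       eqtl_beta = 0.15,
                       maf = 0.15,
                       n_individuals = 174,
                       n_genes = 1,
                       age_effect = 0.02,
                       sex_effect = 0.1,
                       age_genotype_conf = 0,
                       seed = 1) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed > 2^31 - 10)
    stop("seed must be an integer below 2^31 - 10")
  cfg <- list(
    n_signals = .check_count(n_signals, "n_signals"),
    n_variants_per_signal = .check_count(n_variants_per_signal, "n_variants_per_signal"),
    n_annotations = .check_count(n_annotations, "n_annotations", min = 0),
    true_log_enrichments = true_log_enrichments,
    annotation_frequency = .check_prob(annotation_frequency, "annotation_frequency"),
    causal_z_mean = causal_z_mean, null_z_sd = null_z_sd, rho = rho,
    region_length = .check_count(region_length, "region_length"),
    n_cell_types = .check_count(n_cell_types, "n_cell_types"),
    states = states, state_probs = state_probs,
    mean_segment_length = mean_segment_length,
    min_segment_length = min_segment_length,
    max_segment_length = max_segment_length,
    ase_true_ratio = .check_prob(ase_true_ratio, "ase_true_ratio"),
    ase_depth_mean = ase_depth_mean, ase_depth_size = ase_depth_size,
    n_het_samples = .check_count(n_het_samples, "n_het_samples", min = 0),
    eqtl_beta = eqtl_beta,
    maf = .check_prob(maf, "maf"),
    n_individuals = .check_count(n_individuals, "n_individuals"),
    n_genes = .check_count(n_genes, "n_genes"),
    age_effect = age_effect, sex_effect = sex_effect,
    age_genotype_conf = age_genotype_conf,
    seed = .check_count(seed, "seed", min = 0)
  )
  nums <- c(cfg$true_log_enrichments, cfg$causal_z_mean, cfg$null_z_sd,
            cfg$rho, cfg$mean_segment_length, cfg$min_segment_length,
            cfg$ase_depth_mean, cfg$ase_depth_size, cfg$eqtl_beta,
            cfg$age_effect, cfg$sex_effect, cfg$age_genotype_conf)
  if (anyNA(nums) || any(!is.finite(nums)))
    stop("config values must be finite")
  if (length(cfg$true_log_enrichments) != cfg$n_annotations)
    stop("true_log_enrichments must have one entry per annotation")
  if (cfg$null_z_sd <= 0) stop("null_z_sd must be > 0")
  if (abs(cfg$rho) >= 1) stop("rho must lie in (-1, 1)")
  if (length(cfg$states) != length(cfg$state_probs))
    stop("states and state_probs must align")
  structure(cfg, class = "sim_config")
}

#' Simulate association signals with annotation-driven causal placement
#'
#' For each signal, binary annotations are drawn i.i.d.
#' Bernoulli(`annotation_frequency`), the causal variant is drawn with
#' probability proportional to `exp(sum of true log-enrichments over its
#' annotations)`, the causal z is Normal(`causal_z_mean`, 1) and non-causal
#' z are Normal(0, `null_z_sd`) (optionally AR(1)-correlated with `rho`).
#' Each variant carries an explicit risk allele (the alt allele when its z
#' is nonnegative).
#'
#' @param config A [sim_config()].
#' @return List: `stats` (summary-stat tibble: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `risk_allele`, `z`, `signal_id`), `annotations` (0/1
#'   matrix, rownames = variant ids), `truth` (causal variant per signal and
#'   the true coefficients).
#' @export
simulate_signals <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_variants_per_signal
    k <- config$n_annotations
    bases <- c("A", "C", "G", "T")
    res <- lapply(seq_len(config$n_signals), function(s) {
      A <- matrix(stats::rbinom(n * k, 1L, config$annotation_frequency),
                  nrow = n, ncol = k)
      w <- exp(as.vector(A %*% config$true_log_enrichments))
      causal <- sample.int(n, 1, prob = w)
      eps <- stats::rnorm(n)
      if (config$rho != 0) {
        for (j in seq_len(n)[-1])
          eps[j] <- config$rho * eps[j - 1] + sqrt(1 - config$rho^2) * eps[j]
      }
      z <- eps * config$null_z_sd
      z[causal] <- config$causal_z_mean + eps[causal]  # causal z has SD 1
      pos <- sort(sample.int(config$region_length, n))
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
      stats <- tibble::tibble(
        variant_id = sprintf("sig%03d_var%03d", s, seq_len(n)),
        chrom = sprintf("chr%d", s), pos = pos, ref = ref, alt = unname(alt),
        risk_allele = ifelse(z >= 0, "alt", "ref"),
        z = z, signal_id = sprintf("signal%03d", s))
      rownames(A) <- stats$variant_id
      list(stats = stats, A = A, causal = stats$variant_id[causal],
           causal_index = causal)
    })
    A <- do.call(rbind, lapply(res, `[[`, "A"))
    colnames(A) <- if (k) sprintf("ann%02d", seq_len(k)) else character(0)
    list(
      stats = dplyr::bind_rows(lapply(res, `[[`, "stats")),
      annotations = A,
      truth = list(
        causal_variant = stats::setNames(vapply(res, `[[`, character(1), "causal"),
                                         sprintf("signal%03d", seq_len(config$n_signals))),
        causal_index = vapply(res, `[[`, numeric(1), "causal_index"),
        true_log_enrichments = stats::setNames(config$true_log_enrichments,
                                               colnames(A)),
        causal_z_mean = config$causal_z_mean)
    )
  })
}

#' Simulate chromatin-state segmentations per cell type
#'
#' Tiles each signal's region, for each cell type, with non-overlapping
#' sorted half-open segments whose lengths are exponential around
#' `mean_segment_length` (clamped to the configured range) and whose states
#' are sampled from `state_probs`. With the default mean some active-
#' enhancer runs exceed 3 kb, so stretch enhancers exist downstream;
#' capping `max_segment_length` at 2,999 bp (with sub-3kb runs unmerged)
#' removes them.
#'
#' @param config A [sim_config()].
#' @return Tibble `chrom`, `start`, `end`, `state`, `cell_type` tiling each
#'   region per cell type with no gaps or overlaps.
#' @export
simulate_chromatin_states <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cell_types <- if (config$n_cell_types == 12) .default_cell_types
                else sprintf("cell%02d", seq_len(config$n_cell_types))
  with_seed(config$seed + 1L, {
    out <- list()
    for (ct in cell_types) {
      for (s in seq_len(config$n_signals)) {
        len <- config$region_length
        # draw more than enough segments, then cut at the region end
        n_draw <- max(10L, ceiling(3 * len / config$mean_segment_length))
        lens <- pmin(pmax(round(stats::rexp(n_draw, 1 / config$mean_segment_length)),
                          config$min_segment_length),
                     config$max_segment_length)
        while (sum(lens) < len) {
          extra <- pmin(pmax(round(stats::rexp(n_draw, 1 / config$mean_segment_length)),
                             config$min_segment_length),
                        config$max_segment_length)
          lens <- c(lens, extra)
        }
        ends <- pmin(cumsum(lens), len)
        keep <- which(ends > c(0, utils::head(ends, -1)))
        starts <- c(0, utils::head(ends[keep], -1))
        # consecutive segments never share a state (a segmentation would
        # have merged them), so run lengths equal segment lengths
        st <- character(length(keep))
        st[1] <- sample(config$states, 1, prob = config$state_probs)
        if (length(config$states) > 1) {
          for (i in seq_along(st)[-1]) {
            p <- config$state_probs
            p[config$states == st[i - 1]] <- 0
            st[i] <- sample(config$states, 1, prob = p)
          }
        } else st[] <- config$states
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = sprintf("chr%d", s), start = starts, end = ends[keep],
          state = st, cell_type = ct)
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate per-sample allelic read counts at heterozygous variants
#'
#' For every variant and heterozygote sample, total depth is negative-
#' binomial and the alt count Binomial(depth, `ase_true_ratio`). Because the
#' simulated ratio is the alt-read fraction, the alt allele is the lower-
#' accessibility allele whenever the ratio is below 0.5 and is then
#' designated the risk allele (ties at 0.5 are assigned alt as well).
#' Zero-depth rows are emitted deliberately; the downstream filter must
#' handle them.
#'
#' @param config A [sim_config()].
#' @param variants Tibble with at least `variant_id`.
#' @return List: `counts` (tibble `variant_id`, `sample_id`, `ref_count`,
#'   `alt_count`, `het_flag`), `variants` (input plus the assigned
#'   `risk_allele`), `truth` (the true ratio and risk-allele rule).
#' @export
simulate_allele_counts <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  variants <- tibble::as_tibble(variants)
  risk <- if (config$ase_true_ratio <= 0.5) "alt" else "ref"
  variants$risk_allele <- rep(risk, nrow(variants))
  if (config$n_het_samples == 0 || nrow(variants) == 0) {
    counts <- tibble::tibble(variant_id = character(0), sample_id = character(0),
                             ref_count = integer(0), alt_count = integer(0),
                             het_flag = logical(0))
    return(list(counts = counts, variants = variants,
                truth = list(ase_true_ratio = config$ase_true_ratio,
                             risk_allele = risk)))
  }
  with_seed(config$seed + 2L, {
    grid <- expand.grid(sample_id = sprintf("islet%02d", seq_len(config$n_het_samples)),
                        variant_id = variants$variant_id,
                        stringsAsFactors = FALSE)
    depth <- stats::rnbinom(nrow(grid), mu = config$ase_depth_mean,
                            size = config$ase_depth_size)
    alt <- stats::rbinom(nrow(grid), depth, config$ase_true_ratio)
    counts <- tibble::tibble(variant_id = grid$variant_id,
                             sample_id = grid$sample_id,
                             ref_count = as.integer(depth - alt),
                             alt_count = as.integer(alt),
                             het_flag = TRUE)
    list(counts = counts, variants = variants,
         truth = list(ase_true_ratio = config$ase_true_ratio,
                      risk_allele = risk))
  })
}

#' Simulate a cis-eQTL dataset with covariates
#'
#' Genotypes are Binomial(2, `maf`) (Hardy-Weinberg dosages), and each
#' gene's expression is `eqtl_beta * dosage + age_effect * age +
#' sex_effect * sex + Normal(0, 1)`. Ages are Normal(50, 10) plus
#' `age_genotype_conf` per alt allele (zero by default; nonzero values make
#' age a genuine confounder), sex is Bernoulli(0.5) coded 0/1. Each gene
#' gets its own variant 5 kb from its TSS, genes spaced 2.5 Mb apart so cis
#' windows do not cross.
#'
#' @param config A [sim_config()].
#' @return List: `expression` (genes x samples matrix), `genotypes`
#'   (variants x samples dosage matrix), `features` / `variants` (position
#'   tibbles), `covariates` (tibble `sample_id`, `age`, `sex`), `truth`.
#' @export
simulate_eqtl_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    n <- config$n_individuals
    g <- config$n_genes
    samples <- sprintf("ind%04d", seq_len(n))
    geno <- matrix(stats::rbinom(n * g, 2L, config$maf), nrow = g,
                   dimnames = list(sprintf("rsSim%03d", seq_len(g)), samples))
    age <- stats::rnorm(n, 50, 10)
    sex <- stats::rbinom(n, 1L, 0.5)
    if (config$age_genotype_conf != 0 && g >= 1)
      age <- age + config$age_genotype_conf * geno[1, ]
    expr <- matrix(NA_real_, nrow = g, ncol = n,
                   dimnames = list(sprintf("gene%03d", seq_len(g)), samples))
    for (j in seq_len(g)) {
      expr[j, ] <- config$eqtl_beta * geno[j, ] +
        config$age_effect * age + config$sex_effect * sex + stats::rnorm(n)
    }
    tss <- 1e6 + (seq_len(g) - 1) * 2.5e6
    features <- tibble::tibble(feature_id = rownames(expr), chrom = "chr1",
                               pos = tss, tss = tss)
    variants <- tibble::tibble(variant_id = rownames(geno), chrom = "chr1",
                               pos = tss + 5000, ref = "A", alt = "G")
    covariates <- tibble::tibble(sample_id = samples, age = age, sex = sex)
    list(expression = expr, genotypes = geno, features = features,
         variants = variants, covariates = covariates,
         truth = list(eqtl_beta = stats::setNames(rep(config$eqtl_beta, g),
                                                  rownames(expr)),
                      maf = config$maf))
  })
}
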