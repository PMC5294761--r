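test_that("configs are validated and reject non-finite values", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(annotation_frequency = 1.2), "annotation_frequency")
  expect_error(sim_config(maf = 0), "maf")
  expect_error(sim_config(n_signals = 0), "n_signals")
  expect_error(sim_config(causal_z_mean = Inf), "finite")
  expect_error(sim_config(n_annotations = 2, true_log_enrichments = 1),
               "one entry per annotation")
  expect_error(sim_config(seed = 2^31), "seed")
})

test_that("identical configs give identical outputs across all generators", {
  cfg <- sim_config(n_signals = 4, n_variants_per_signal = 12,
                    n_annotations = 3, true_log_enrichments = c(1, 0, 0),
                    n_het_samples = 5, n_individuals = 40, seed = 123)
  a <- simulate_signals(cfg); b <- simulate_signals(cfg)
  expect_identical(a, b)
  expect_identical(simulate_chromatin_states(cfg), simulate_chromatin_states(cfg))
  v <- a$stats[1:5, ]
  expect_identical(simulate_allele_counts(cfg, v), simulate_allele_counts(cfg, v))
  expect_identical(simulate_eqtl_dataset(cfg), simulate_eqtl_dataset(cfg))
  # a different seed actually changes the draws
  cfg2 <- sim_config(n_signals = 4, n_variants_per_signal = 12,
                     n_annotations = 3, true_log_enrichments = c(1, 0, 0),
                     n_het_samples = 5, n_individuals = 40, seed = 124)
  expect_false(identical(simulate_signals(cfg2), a))
})

test_that("causal placement is uniform without enrichment and follows the closed form with it", {
  # no enrichment: chi-square goodness of fit over causal indices
  cfg <- sim_config(n_signals = 2000, n_variants_per_signal = 10,
                    n_annotations = 0, true_log_enrichments = numeric(0),
                    seed = 42)
  sig <- simulate_signals(cfg)
  tab <- tabulate(sig$truth$causal_index, nbins = 10)
  expect_gt(chisq.test(tab)$p.value, 0.01)
  # one annotation at ln 4, frequency 0.1: P(causal annotated) ~ 0.3077
  cfg2 <- sim_config(n_signals = 5000, n_variants_per_signal = 50,
                     n_annotations = 1, true_log_enrichments = log(4),
                     annotation_frequency = 0.1, seed = 43)
  sig2 <- simulate_signals(cfg2)
  frac <- mean(sig2$annotations[cbind(
    match(sig2$truth$causal_variant, rownames(sig2$annotations)), 1)])
  expect_equal(frac, 0.1 * 4 / (0.1 * 4 + 0.9), tolerance = 0.02 / 0.3077)
})

test_that("causal_z_mean = 0 yields a global null z distribution", {
  cfg <- sim_config(n_signals = 100, n_variants_per_signal = 20,
                    n_annotations = 0, true_log_enrichments = numeric(0),
                    causal_z_mean = 0, seed = 7)
  sig <- simulate_signals(cfg)
  expect_gt(ks.test(sig$stats$z, pnorm)$p.value, 0.01)
})

test_that("chromatin segmentations tile each region without gaps or overlaps", {
  cfg <- sim_config(n_signals = 3, n_cell_types = 2, region_length = 50000,
                    n_annotations = 0, true_log_enrichments = numeric(0),
                    seed = 10)
  seg <- simulate_chromatin_states(cfg)
  for (ct in unique(seg$cell_type)) for (chr in unique(seg$chrom)) {
    s <- seg[seg$cell_type == ct & seg$chrom == chr, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], 50000)
    expect_equal(s$start[-1], s$end[-nrow(s)])  # book-ended tiling
    # adjacent records never share a state, so runs are single segments
    expect_true(all(s$state[-1] != s$state[-nrow(s)]))
  }
})

test_that("capping segment length below 3 kb removes stretch enhancers", {
  cfg <- sim_config(n_signals = 2, n_cell_types = 2, region_length = 1e5,
                    max_segment_length = 2999, n_annotations = 0,
                    true_log_enrichments = numeric(0), seed = 11)
  seg <- simulate_chromatin_states(cfg)
  expect_equal(nrow(derive_stretch_enhancers(seg)), 0)
  # while the default config does produce them
  cfg2 <- sim_config(n_signals = 2, n_cell_types = 2, region_length = 2e5,
                     n_annotations = 0, true_log_enrichments = numeric(0),
                     mean_segment_length = 2000, seed = 12)
  expect_gt(nrow(derive_stretch_enhancers(simulate_chromatin_states(cfg2))), 0)
})

test_that("allelic counts follow the configured ratio and handle edge cases", {
  vars <- tibble::tibble(variant_id = sprintf("v%02d", 1:40))
  # null ratio pools to ~0.5 (ratio of exactly 0.5 via a hair below is
  # indistinguishable at this depth)
  cfg <- sim_config(ase_true_ratio = 0.5 - 1e-9, n_het_samples = 20,
                    ase_depth_mean = 15, seed = 21)
  ase <- simulate_allele_counts(cfg, vars)
  frac <- sum(ase$counts$alt_count) / sum(ase$counts$alt_count + ase$counts$ref_count)
  expect_gt(sum(ase$counts$alt_count + ase$counts$ref_count), 10000)
  expect_equal(frac, 0.5, tolerance = 0.02 / 0.5)
  # ratio 0.3 at depth ~1000 lands inside the exact binomial 99% interval
  cfg3 <- sim_config(ase_true_ratio = 0.3, n_het_samples = 5,
                     ase_depth_mean = 10, seed = 22)
  ase3 <- simulate_allele_counts(cfg3, tibble::tibble(variant_id = sprintf("w%02d", 1:20)))
  tot <- sum(ase3$counts$ref_count + ase3$counts$alt_count)
  alt <- sum(ase3$counts$alt_count)
  expect_gte(alt, qbinom(0.005, tot, 0.3))
  expect_lte(alt, qbinom(0.995, tot, 0.3))
  # risk allele is the lower-accessibility (alt) allele when ratio < 0.5
  expect_true(all(ase3$variants$risk_allele == "alt"))
  expect_true(all(simulate_allele_counts(
    sim_config(ase_true_ratio = 0.7, seed = 1),
    vars)$variants$risk_allele == "ref"))
  # zero het samples: empty table, no error
  empty <- simulate_allele_counts(sim_config(n_het_samples = 0, seed = 1), vars)
  expect_equal(nrow(empty$counts), 0)
  # zero-depth rows are emitted, not silently dropped
  cfg0 <- sim_config(ase_depth_mean = 1, ase_depth_size = 0.2,
                     n_het_samples = 30, seed = 23)
  ase0 <- simulate_allele_counts(cfg0, vars[1:5, ])
  expect_gt(sum(ase0$counts$ref_count + ase0$counts$alt_count == 0), 0)
})

test_that("eQTL genotypes sit at Hardy-Weinberg dosages", {
  cfg <- sim_config(maf = 0.5, n_individuals = 10000, seed = 33)
  d <- simulate_eqtl_dataset(cfg)
  expect_true(all(d$genotypes %in% 0:2))
  expect_equal(mean(d$genotypes), 1.0, tolerance = 0.03)
  expect_equal(d$truth$eqtl_beta[["gene001"]], cfg$eqtl_beta)
})
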