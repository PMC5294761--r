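#!/usr/bin/env Rscript
# Stage 1: generate the full synthetic study with known ground truth.
#
# The design mirrors the canonical fine-mapping setting this package was
# built for: 49 association signals of 50 variants each, 36 binary
# chromatin annotations (12 cell types x EnhA/EnhWk/TssA) with the first
# annotation carrying a true four-fold prior-odds enrichment, chromatin
# segmentations per cell type, allelic ATAC read counts from 23
# heterozygote donors with a true alt-read fraction of 0.3, and an
# islet-scale eQTL cohort (n = 174, MAF 0.15) with age and sex covariates.

suppressPackageStartupMessages(library(credset))

out <- "results/synthetic"
cfg <- sim_config(seed = 1, eqtl_beta = 0.5)  # planted eQTL large enough to see at n = 174

sig <- simulate_signals(cfg)
seg <- simulate_chromatin_states(cfg)
ase <- simulate_allele_counts(cfg, sig$stats[sig$stats$signal_id == "signal001",
                                             c("variant_id", "ref", "alt")])
eq <- simulate_eqtl_dataset(cfg)

write_summary_stats(sig$stats, file.path(out, "summary_stats.tsv"))
write_annotation_matrix(sig$annotations, file.path(out, "annotations.tsv"))
write_bed_states(seg, file.path(out, "chromatin_states.bed"))
write_allele_counts(ase$counts, file.path(out, "allele_counts.tsv"))
write.table(ase$variants, file.path(out, "ase_variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_genotypes_vcf(eq$genotypes, eq$variants, file.path(out, "genotypes.vcf"))
write_expression(eq$expression, eq$features, file.path(out, "expression.tsv"))
write_covariates(eq$covariates, file.path(out, "covariates.tsv"))
write_sim_truth(list(signals = sig$truth, ase = ase$truth, eqtl = eq$truth),
                file.path(out, "sim_truth.json"))

cat(sprintf("signals: %d x %d variants; causal variant annotated in %.0f%% of signals\n",
            cfg$n_signals, cfg$n_variants_per_signal,
            100 * mean(sig$annotations[cbind(match(sig$truth$causal_variant,
                                                   rownames(sig$annotations)), 1)])))
cat(sprintf("chromatin: %d segments over %d cell types\n",
            nrow(seg), length(unique(seg$cell_type))))
cat(sprintf("ATAC: %d allele-count rows at %d variants, true alt fraction %.2f\n",
            nrow(ase$counts), nrow(ase$variants), cfg$ase_true_ratio))
cat(sprintf("eQTL cohort: n = %d, MAF %.2f, planted beta %.2f SD/allele\n",
            cfg$n_individuals, cfg$maf, cfg$eqtl_beta))
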