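#!/usr/bin/env Rscript
# Stage 5: allelic imbalance in chromatin accessibility.
#
# Applies the retention rule (>= 5 reads at the variant base in each of
# >= 3 heterozygote donors), pools ref/alt read counts across qualifying
# donors, and tests the alt fraction against 0.5 with an exact two-sided
# binomial test, calling direction relative to each variant's risk allele.

suppressPackageStartupMessages(library(credset))

counts <- read_allele_counts("results/synthetic/allele_counts.tsv")
vars <- read.delim("results/synthetic/ase_variants.tsv")

res <- test_allelic_imbalance(counts, vars, min_reads = 5, min_het_samples = 3)
report <- imbalance_report(res)
dir.create("results/imbalance", recursive = TRUE, showWarnings = FALSE)
write.table(report, "results/imbalance/imbalance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_sig <- sum(report$p_value < 0.05)
cat(sprintf("%d of %d variants retained by the read filter; %d imbalanced at p < 0.05\n",
            nrow(report), length(unique(counts$variant_id)), n_sig))
cat(sprintf("direction: %d/%d risk_lower (risk allele on the less accessible haplotype)\n",
            sum(report$direction == "risk_lower"), nrow(report)))
cat("strongest imbalance:\n")
print(as.data.frame(report[1, ]), row.names = FALSE)
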