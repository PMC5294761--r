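# credset

Statistical machinery for localizing causal variants at GWAS loci, built
as a tested R package plus a numbered analysis workflow. It implements,
end to end on synthetic data with known ground truth:

- **Bayesian fine-mapping** from summary statistics: Wakefield approximate
  Bayes factors, single-causal posterior probabilities, and 99% credible
  sets. With `r = W/(V+W)`, `ABF = sqrt(1-r) * exp(z^2 r / 2)`, and the
  posterior causal probability of variant *j* within its signal is
  `pi_j = p_j ABF_j / sum_k p_k ABF_k`.
- **Chromatin annotation**: binary variant × (cell type, state) membership
  from BED segmentations, including derived *stretch enhancers* (merged
  active-enhancer runs > 3 kb).
- **Hierarchical enrichment modelling**: within-signal multinomial-logistic
  priors `p_j ∝ exp(sum_a gamma_a A_ja)`, fit by forward selection,
  cross-validated ridge penalty, and backward elimination; the fitted
  log-enrichments reweight fine-mapping posteriors and typically shrink
  credible sets.
- **Allelic chromatin-accessibility imbalance**: the read-depth retention
  rule (≥ 5 reads in each of ≥ 3 heterozygote samples), pooled exact
  two-sided binomial tests against 0.5, and direction calls relative to
  the risk allele.
- **Covariate-adjusted cis-eQTL analysis**: expression filtering and
  rank-based inverse-normal transformation, 100 kb / 1 Mb cis windows,
  OLS with age and sex covariates, and an analytic power calculator
  (noncentral chi-square, per-allele standardized effects).
- **Synthetic data generators** for all of the above, with ground truth
  saved beside every dataset so recovery is measurable.

Intended for statistical geneticists who want a compact, fully tested
reference implementation of this fine-mapping-to-function pipeline whose
every stage can be validated against simulated truth.

## Worked example

```r
library(credset)

cfg <- sim_config(n_signals = 49, n_variants_per_signal = 50,
                  n_annotations = 1, true_log_enrichments = log(4),
                  annotation_frequency = 0.1, causal_z_mean = 5, seed = 1)
sig <- simulate_signals(cfg)

fm <- finemap_signals(sig$stats, abf_config(W = 25, level = 0.99))
mean(sapply(fm$credible_sets, `[[`, "size"))
#> [1] 13.73469

model <- fit_enrichment_model(fm$posteriors, sig$annotations,
                              fit_config(seed = 1))
model
#> Enrichment model (lambda = 0.5, loglik = 308.768):
#>   ann01: gamma = +0.750

rw_sizes <- sapply(split(fm$posteriors, fm$posteriors$signal_id), function(p)
  reweight_posteriors(p, sig$annotations, model, 0.99)$credible_set$size)
mean(rw_sizes)
#> [1] 13.02041
```

The mean 99% credible set holds about 14 of 50 variants under flat priors.
Forward selection keeps the single true annotation; with only 49 signals
the cross-validated ridge penalty lands on a strong weight (lambda = 0.5),
so the enrichment estimate (0.75) is a deliberately shrunken version of
the true `log(4) = 1.386` — the acceptance run, which fits 400-signal
replicates without shrinkage, recovers the coefficient to within 0.3 in
at least 90% of replicates. Reweighting with the fitted prior then trims
the average credible set from 13.7 to 13.0 variants, concentrating
posterior mass on annotated variants.

The `analysis/` directory holds the same workflow as six numbered
scripts — simulate, fine-map, annotate, enrich + reweight, imbalance,
eQTL — each a thin narrative driver over package functions that prints
what it found and writes its tables under `results/`. For example,
`analysis/05_imbalance.R` prints:

```
50 of 50 variants retained by the read filter; 50 imbalanced at p < 0.05
direction: 50/50 risk_lower (risk allele on the less accessible haplotype)
```

meaning every simulated variant (true alt-read fraction 0.3, 23
heterozygote donors) shows significant imbalance with the risk allele on
the less accessible haplotype, as planted.

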