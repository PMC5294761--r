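#!/usr/bin/env Rscript
# Stage 4: annotation-enrichment model and posterior reweighting.
#
# Fits the hierarchical prior model across all signals: greedy forward
# selection of annotations by penalized marginal likelihood, ridge penalty
# chosen by 10-fold cross-validation over signals, then backward
# elimination against the held-out likelihood. The fitted log-enrichments
# become functional priors that reweight the posteriors of the target
# signal (signal001 here), typically shrinking its 99% credible set.

suppressPackageStartupMessages(library(credset))

post <- read_posteriors("results/finemap/posteriors.tsv")
amat <- read_annotation_matrix("results/synthetic/annotations.tsv")

model <- fit_enrichment_model(post, amat, fit_config(seed = 1))
print(model)

target <- post[post$signal_id == "signal001", ]
rw <- reweight_posteriors(target, amat, model, level = 0.99)

write_posteriors(rw$posteriors, "results/enrich/posteriors_reweighted.tsv")
write_credible_sets(list(signal001 = rw$credible_set),
                    "results/enrich/credible_set_reweighted.json")
jsonlite::write_json(list(annotations = model$annotations,
                          gamma = as.list(model$gamma), lambda = model$lambda,
                          loglik = model$loglik, cv_loglik = model$cv_loglik),
                     "results/enrich/enrichment_model.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

base_size <- sum(target$in_credible_set)
cat(sprintf("target signal001: credible set %d variants (flat prior) -> %d (reweighted)\n",
            base_size, rw$credible_set$size))
cat(sprintf("top reweighted posterior: %s at %.3f\n",
            rw$credible_set$variant_id[1], max(rw$posteriors$posterior)))
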