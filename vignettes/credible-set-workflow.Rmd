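---
title: "Fine-mapping with functional priors: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping with functional priors: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credset)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The fine-mapping model

Each association *signal* (a locus may contain several) is assumed to
contain exactly one causal variant. For a variant with effect estimate
$\hat\beta$, standard error $se$ (so $z = \hat\beta/se$, $V = se^2$), and a
Gaussian prior $\beta \sim N(0, W)$ under the alternative, Wakefield's
approximation gives a closed-form Bayes factor in favour of association:

$$
\mathrm{ABF} = \sqrt{1 - r}\; \exp\!\left(\tfrac{z^2 r}{2}\right),
\qquad r = \frac{W}{V + W}.
$$

Under the single-causal assumption the posterior causal probability of
variant $j$ in its signal is
$\pi_j = p_j\,\mathrm{ABF}_j / \sum_k p_k\,\mathrm{ABF}_k$ with prior
weights $p_j$ (flat by default). The **99% credible set** is the smallest
set of variants, taken in decreasing posterior order, whose cumulative
posterior reaches 0.99; a cumulative probability landing exactly on the
level is included, and ties are broken by (posterior, chromosome, position,
variant id) so the set is reproducible.

Numerical choices: all Bayes-factor arithmetic is carried in log space and
posteriors are normalized by log-sum-exp, so $z$-scores far into the
hundreds cannot overflow. Posteriors within a signal sum to 1 to within
$10^{-12}$.

### The prior variance W

`W` is the one tunable that matters and the literature rarely prints it.

* With `beta`/`se` input the default is `W = 0.04` (prior SD 0.2 on the
  log-odds scale), the conventional choice for case-control effect sizes.
  It is a default, not a claim about any particular published analysis.
* With `z`-only input, `V` is fixed at 1 and `W` lives on the z scale, so
  it must be of the order of the squared non-centrality of real signals;
  0.04 would make all Bayes factors nearly equal and the posterior nearly
  flat. The simulation studies in this package use `W = 25` (prior SD 5),
  moment-matched a priori to the generator's causal z mean of 5: under the
  alternative the marginal second moment of z is $1 + W = 26 \approx
  E[z_\text{causal}^2] = 26$. This choice is part of the study design, made
  on that analytic ground and not revisited.

Because the analysis prior ($\beta$ centred at zero with SD 5) is wider
than the generative truth (z centred at 5 with SD 1), credible sets are
mildly conservative: the acceptance suite measures coverage of the true
causal variant at or above the nominal 99% rather than exactly at it.

## The annotation-enrichment model

Binary annotations $A_{ja}$ (variant $j$ in annotation $a$) enter as a
multinomial-logistic prior within each signal:

$$
p_j \propto \exp\!\Big(\sum_a \gamma_a A_{ja}\Big), \qquad
\ell(\gamma) = \sum_s \log \sum_{j \in s} p_j\,\mathrm{ABF}_j
  \;-\; \lambda \lVert\gamma\rVert^2 .
$$

$\gamma_a$ is the log prior-odds enrichment of annotation $a$; with
$\gamma = 0$ the model collapses exactly (bitwise, not approximately) to
flat-prior fine-mapping, which the tests assert. Model selection follows
the three-step procedure used by hierarchical GWAS-enrichment tools:

1. **Forward selection.** Starting empty, refit every candidate jointly
   with the current set and add the one with the largest gain in (possibly
   penalized) log-likelihood; stop when the best gain is below
   `forward_tolerance` (default 2 log-units, an AIC-like free choice —
   there is no principled universal value, and the tests treat noise
   rejection as a majority property across seeds, since chance
   correlations occasionally clear any fixed gate). The penalty is off
   during this stage by default — the ridge weight has not been chosen yet
   at this point in the procedure — and a `lambda` argument exposes the
   alternative.
2. **Penalty selection.** Ridge weights from the grid
   {0.01, 0.05, 0.1, 0.25, 0.5, 1} are scored by 10-fold cross-validation
   *over signals* (signals, not variants, are the independent units):
   fit on nine folds, sum the unpenalized log-likelihood on the held-out
   fold, pick the argmax; ties go to the stronger penalty. Fold assignment
   is a pure function of the seed and the sorted signal ids.
3. **Backward elimination.** At the selected penalty, drop whichever
   annotation most improves the cross-validated likelihood, refit, and
   repeat until no removal helps. The last annotation is only removed if
   the empty model genuinely scores higher out-of-fold.

The optimizer is BFGS with the analytic gradient
$\nabla\ell = \sum_s A_s^\top(w_s - q_s) - 2\lambda\gamma$, where $w_s$ and
$q_s$ are the posterior and prior weight vectors of signal $s$; its
correctness is asserted against an optimizer-independent grid-search oracle
on one- and two-parameter problems, not against any specific algorithm.

Whether enrichment should be estimated with the target locus held out was
an open choice; the default fits on all signals (the target contributes one
signal among dozens, and holding it out changes estimates negligibly at
that scale), and `reweight_posteriors()` accepts any model object, so a
leave-one-out fit can be supplied where wanted.

## Chromatin annotations and stretch enhancers

Segmentations are consumed, never inferred. Coordinates follow the two
standards: BED intervals are 0-based half-open, variant positions 1-based,
so position $p$ overlaps $[s, e)$ iff $s < p \le e$ — the boundary cases
are tested exactly. Adjacent or book-ended same-state records are merged
before any length logic, making stretch-enhancer derivation invariant to
how a segmentation tool fragments a run; **stretch enhancers** are merged
active-enhancer (EnhA) runs *strictly longer* than 3 kb, kept per cell
type. Twelve cell types crossed with the three active states
(EnhA, EnhWk, TssA) give the canonical 36 annotation columns; stretch
columns are appended as extras by default (`stretch_mode = "add"`) because
treating them as replacements for EnhA is equally defensible — both modes
are implemented and tested. Indels annotate by their single anchor
position; no span rule is imposed.

## Allelic imbalance

A variant is testable when at least `min_het_samples = 3` heterozygote
donors each carry at least `min_reads = 5` reads over the variant base —
the strict reading of "more than 2 samples"; the alternative pooled
reading is available via `pool_filter`. Read counts are pooled across the
qualifying donors and the alt fraction tested against 0.5 with an exact
binomial test; the two-sided p-value follows the minimum-likelihood
convention (probabilities of all outcomes no more likely than the observed
one), with double-one-sided-capped-at-one as an option, and one-sided
available through the same switch. Direction is reported relative to the
designated risk allele: `risk_lower` when the risk allele carries fewer
reads. No overdispersion (beta-binomial) is modelled, and reference-mapping
bias is assumed handled upstream; both are stated limitations. Exactness
is verified against full enumeration for every pooled total up to 20, and
null calibration by simulation — the test's discreteness makes it exactly
valid but slightly conservative, so empirical rejection sits at or just
under the nominal level.

## cis-eQTL analysis

Expression preprocessing mirrors standard practice: library-size scaling
to a fixed total (20M by default), exclusion of features below 1 count in
strictly more than 20% of samples, then a rank-based inverse-normal
transform per feature, mapping rank $r$ of $n$ to $\Phi^{-1}((r-0.5)/n)$
with average ranks on ties. Two cis-window conventions are implemented,
both inclusive at the boundary and chromosome-aware: 100 kb around the
feature anchor and 1 Mb around the TSS. The association model is ordinary
least squares of expression on dosage plus intercept and covariates (age
numeric, sex 0/1, no interactions); hidden-factor covariates such as PEER
are accepted through the same covariate table but never inferred here.
Rank-deficient designs are rejected naming the offending column; an exact
fit reports its p-value at the double-precision floor rather than zero.
A plain Bonferroni per feature is the only built-in multiplicity option,
off by default.

**Power.** The calculator uses the per-allele standardized-effect
convention: non-centrality $n\,\beta^2\,2\,\mathrm{maf}(1-\mathrm{maf})$
against the central $\chi^2_1$ critical value. Published power figures
computed with other tools' internal conventions (expression-level scaling,
variance explained, etc.) are generally not recoverable from this
convention, and this package documents rather than forces such numbers:
for example, a design with $n = 186$, MAF 0.15, $\beta = 0.15$ SD/allele
at $\alpha = 2.5\times10^{-7}$ has power near zero under this convention,
not 90%.

## What the synthetic data emulate — and what they do not

The generator produces every input the pipeline consumes, with ground
truth stored alongside (`SimTruth`), under a single validated config whose
seed fixes every draw (identical configs give byte-identical outputs).
Defaults are the package's canonical study design: 49 signals of 50
variants, 36 annotations with the first carrying a true fourfold
enrichment at membership frequency 0.1, causal z mean 5 (a free parameter
of the design; effect-size distributions of real loci are rarely
published), 12 cell types segmented with exponential segment lengths
(mean 1.5 kb, so a realistic minority of EnhA runs exceed 3 kb), 23
heterozygote ATAC donors with negative-binomial depth (mean 20, size 5)
and true alt fraction 0.3, and an eQTL cohort of 174 individuals at
MAF 0.15 with age and sex covariates.

Deliberate simplifications, hence limits on what passing tests show about
real data:

* **No linkage disequilibrium.** z-scores are simulated directly (V = 1)
  rather than through genotypes; an optional AR(1) correlation (`rho`)
  exists to stress credible-set behaviour but defaults to 0. Real credible
  sets are driven by LD; synthetic ones are not.
* **No read-level realism.** Allele counts are binomial draws, with no
  mapping bias, no overdispersion between donors, no indel ambiguity.
* **Segmentations are i.i.d. state sequences** (with the constraint that
  adjacent segments never share a state, as a segmentation tool would have
  merged them), not learned chromatin landscapes; cell types are
  independent of each other.
* **Covariates confound only on request.** Age affects expression but is
  independent of genotype unless `age_genotype_conf` is set; the
  demonstration that covariate-free fitting inflates type-I error uses a
  nonzero value, because without genotype-covariate correlation the naive
  model is noisy but not biased.
* The risk-allele bookkeeping is explicit: when the true alt fraction is
  below 0.5 the alt allele is the less accessible haplotype and is
  designated the risk allele (matching the direction convention the
  imbalance test reports); the tie at exactly 0.5 is assigned arbitrarily
  to alt and flagged as such.

## Problem sizes

The simulation studies use 2,000 signals for credible-set coverage, 50
replicates of 400 signals × 50 variants for enrichment recovery (20 in the
acceptance script's summary run), 1,000 signals for reweighting shrinkage,
2,000 variants for imbalance calibration, and 2,000/500 simulated genes
for eQTL calibration and effect recovery — sizes at which the binomial
noise on each reported rate is well below the margins being asserted.
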