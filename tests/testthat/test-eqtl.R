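test_that("low-expression filter applies the strict > rule per feature", {
  m <- rbind(drop3 = c(rep(0, 3), rep(5, 7)),   # below 1 in 30% of samples
             keep2 = c(rep(0, 2), rep(5, 8)),   # 20% exactly: kept
             high = rep(9, 10))
  f <- filter_low_expression(m)
  expect_equal(rownames(f), c("keep2", "high"))
  # all features passing is the identity transform
  expect_identical(filter_low_expression(m[2:3, , drop = FALSE]),
                   m[2:3, , drop = FALSE])
  expect_message(filter_low_expression(m[1, , drop = FALSE]), "no feature")
})

test_that("library-size normalization hits the target total", {
  m <- matrix(rpois(40, 50), 4, 10)
  norm <- normalize_library_size(m, 2e7)
  expect_equal(unname(colSums(norm)), rep(2e7, 10))
})

test_that("rank inverse-normal maps ranks to (r - 0.5)/n quantiles", {
  expect_equal(rank_inverse_normal(c(3, 1, 2)),
               c(qnorm(5 / 6), qnorm(1 / 6), 0), tolerance = 1e-12)
  expect_equal(round(rank_inverse_normal(c(3, 1, 2)), 4),
               c(0.9674, -0.9674, 0))
  # invariance under strictly monotone transforms
  set.seed(4)
  x <- rnorm(50)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(exp(2 * x)))
  # symmetric quantiles for a tie-free vector
  expect_equal(mean(rank_inverse_normal(x)), 0, tolerance = 1e-9)
  # ties share the average rank
  expect_equal(rank_inverse_normal(c(1, 1, 2))[1:2],
               rep(qnorm(1 / 3), 2))
  expect_error(rank_inverse_normal(rep(1, 5)), "distinct")
})

test_that("cis windows are inclusive and chromosome-aware", {
  feats <- tibble::tibble(feature_id = "g", chrom = "chr1", pos = 5e5,
                          tss = 5e5)
  vars <- tibble::tibble(variant_id = c("in", "edge", "out", "otherchr"),
                         chrom = c("chr1", "chr1", "chr1", "chr2"),
                         pos = c(5e5 + 1, 5e5 + 1e5, 5e5 + 1e5 + 1, 5e5))
  p <- cis_pairs(feats, vars, "gene_window_100kb")
  expect_setequal(p$variant_id, c("in", "edge"))
  # 1 Mb TSS mode widens the window
  p2 <- cis_pairs(feats, vars, "tss_flank_1mb")
  expect_setequal(p2$variant_id, c("in", "edge", "out"))
  edge1mb <- tibble::tibble(variant_id = c("a", "b"), chrom = "chr1",
                            pos = c(5e5 + 1e6, 5e5 + 1e6 + 1))
  expect_equal(cis_pairs(feats, edge1mb, "tss_flank_1mb")$variant_id, "a")
})

test_that("the eQTL OLS matches the normal-equations oracle to 1e-10", {
  set.seed(21)
  for (i in 1:10) {
    n <- 80
    g <- rbinom(n, 2, 0.3)
    cov <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
    y <- 0.4 * g + 0.02 * cov$age + 0.1 * cov$sex + rnorm(n)
    fit <- fit_cis_eqtl(y, g, cov)
    X <- cbind(1, g, cov$age, cov$sex)
    oracle <- normal_eq_ols(X, y)
    expect_equal(fit$beta, oracle$beta[2], tolerance = 1e-10)
    expect_equal(fit$se, unname(oracle$se[2]), tolerance = 1e-10)
    expect_equal(fit$p, oracle$p[2], tolerance = 1e-10)
  }
})

test_that("degenerate and ill-posed designs are handled explicitly", {
  g <- rbinom(50, 2, 0.4)
  fit <- fit_cis_eqtl(2 * g, g)
  expect_equal(fit$beta, 2)
  expect_equal(fit$p, .Machine$double.xmin)
  dup <- data.frame(gcopy = g)
  expect_error(fit_cis_eqtl(rnorm(50), g, dup), "gcopy")
  expect_error(fit_cis_eqtl(rnorm(2), rbinom(2, 2, 0.5)), "samples")
})

test_that("covariate adjustment removes confounding the naive model absorbs", {
  naive_p <- adj_p <- numeric(150)
  for (r in seq_len(150)) {
    cfg <- sim_config(n_individuals = 100, eqtl_beta = 0, age_effect = 0.5,
                      age_genotype_conf = 4, maf = 0.3, seed = 5000 + r)
    d <- simulate_eqtl_dataset(cfg)
    y <- d$expression[1, ]; g <- d$genotypes[1, ]
    naive_p[r] <- fit_cis_eqtl(y, g)$p
    adj_p[r] <- fit_cis_eqtl(y, g, d$covariates[, c("age", "sex")])$p
  }
  naive_rate <- mean(naive_p < 0.05)
  adj_rate <- mean(adj_p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 150)
  expect_gt(naive_rate, 0.15)          # inflated without the age covariate
  expect_lt(adj_rate, ci[2] + 0.02)    # calibrated once adjusted
})

test_that("run_cis_eqtl aligns samples and recovers a planted effect", {
  cfg <- sim_config(n_individuals = 300, eqtl_beta = 0.8, maf = 0.3,
                    n_genes = 2, seed = 31)
  d <- simulate_eqtl_dataset(cfg)
  res <- run_cis_eqtl(d$expression, d$genotypes, d$features, d$variants,
                      d$covariates)
  expect_equal(nrow(res), 2)  # genes 2.5 Mb apart: one cis variant each
  expect_equal(res$beta, rep(0.8, 2), tolerance = 0.25)
  expect_true(all(res$p < 1e-6))
})

test_that("analytic power obeys its limits and matches Monte Carlo", {
  expect_equal(eqtl_power(100, 0.3, 0, 0.05), 0.05)
  expect_gt(eqtl_power(1e5, 0.5, 1, 0.05), 0.9999)
  # monotone in n, |beta|, and maf(1-maf)
  expect_true(all(diff(sapply(c(50, 100, 200, 400),
                              function(n) eqtl_power(n, 0.3, 0.3, 0.05))) > 0))
  expect_true(all(diff(sapply(c(0.1, 0.2, 0.4),
                              function(b) eqtl_power(100, 0.3, b, 0.05))) > 0))
  expect_true(all(diff(sapply(c(0.05, 0.15, 0.3, 0.5),
                              function(m) eqtl_power(200, m, 0.3, 0.05))) > 0))
  # Monte-Carlo oracle at the n = 100, maf 0.3, beta 0.5 design
  set.seed(8)
  reps <- 4000
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    g <- rbinom(100, 2, 0.3)
    y <- 0.5 * g + rnorm(100)
    rho <- suppressWarnings(cor(g, y))
    t <- rho * sqrt(98 / (1 - rho^2))
    hits[r] <- 2 * pt(abs(t), 98, lower.tail = FALSE) < 0.05
  }
  mc <- mean(hits)  # MC standard error ~ 0.005
  expect_equal(eqtl_power(100, 0.3, 0.5, 0.05), mc, tolerance = 0.02)
  expect_equal(eqtl_power(100, 0.3, 0.5, 0.05), 0.90, tolerance = 0.01)
})
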