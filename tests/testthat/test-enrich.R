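# small hand-built posterior table: one signal, ABFs (2, 1), annotation (1, 0)
two_variant_tbl <- function() {
  tibble::tibble(variant_id = c("v1", "v2"), signal_id = "s1",
                 log_abf = log(c(2, 1)))
}
two_variant_A <- function() {
  matrix(c(1L, 0L), 2, 1, dimnames = list(c("v1", "v2"), "ann01"))
}

test_that("marginal log-likelihood reduces to log mean ABF at gamma = 0", {
  expect_equal(model_loglik(two_variant_tbl(), two_variant_A(), 0, 0),
               log(1.5))
  # two signals: contributions add
  tbl2 <- dplyr::bind_rows(two_variant_tbl(),
                           tibble::tibble(variant_id = c("w1", "w2"),
                                          signal_id = "s2",
                                          log_abf = log(c(4, 2))))
  A2 <- rbind(two_variant_A(),
              matrix(c(0L, 1L), 2, 1, dimnames = list(c("w1", "w2"), "ann01")))
  expect_equal(model_loglik(tbl2, A2, 0, 0), log(1.5) + log(3))
  expect_error(model_loglik(two_variant_tbl(), two_variant_A(), c(1, 2), 0),
               "length")
})

test_that("unpenalized likelihood increases in gamma toward log(best ABF)", {
  tbl <- two_variant_tbl(); A <- two_variant_A()
  lls <- vapply(c(0, 1, 2, 5, 10), function(g) model_loglik(tbl, A, g, 0),
                numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_true(all(lls < log(2)))
  expect_equal(model_loglik(tbl, A, 30, 0), log(2), tolerance = 1e-6)
})

test_that("the penalized optimum matches a grid-search oracle", {
  tbl <- two_variant_tbl(); A <- two_variant_A()
  g_star <- grid_max(function(g) model_loglik(tbl, A, g, 0.1), -2, 6,
                     tol = 1e-8)
  fit <- fit_enrichment(tbl, A, lambda = 0.1)
  expect_equal(unname(fit$gamma), g_star, tolerance = 1e-4)
  # and on a 2-parameter problem, the fitted point beats every grid point
  A2 <- cbind(two_variant_A(), ann02 = c(0L, 1L))
  fit2 <- fit_enrichment(tbl, A2, lambda = 0.25)
  grid <- expand.grid(g1 = seq(-2, 3, 0.05), g2 = seq(-2, 3, 0.05))
  best_grid <- max(apply(grid, 1, function(g)
    model_loglik(tbl, A2, as.numeric(g), 0.25)))
  expect_gte(fit2$loglik + 1e-8, best_grid)
})

sim_enriched <- function(n_signals, n_annotations, gamma0, seed,
                         frequency = 0.1) {
  cfg <- sim_config(n_signals = n_signals, n_variants_per_signal = 50,
                    n_annotations = n_annotations,
                    true_log_enrichments = c(gamma0,
                                             rep(0, n_annotations - 1)),
                    annotation_frequency = frequency, causal_z_mean = 5,
                    seed = seed)
  sig <- simulate_signals(cfg)
  fm <- finemap_signals(sig$stats, abf_config(W = W_Z))
  list(post = fm$posteriors, A = sig$annotations, truth = sig$truth)
}

test_that("forward selection finds a true enrichment and ignores duplicates", {
  d <- sim_enriched(200, 1, log(4), seed = 301)
  # duplicate the informative column: only one of the pair may enter, and the
  # fit must equal the single-column fit
  A2 <- cbind(d$A, ann01copy = d$A[, "ann01"])
  m2 <- forward_select(d$post, A2)
  expect_equal(m2$annotations, "ann01")
  m1 <- forward_select(d$post, d$A)
  expect_equal(unname(m1$gamma), unname(m2$gamma))
  expect_equal(unname(m1$gamma), log(4), tolerance = 0.45)
})

test_that("forward selection usually returns the empty model on pure noise", {
  # chance correlations can clear the 2-log-unit gate occasionally, so this
  # is a majority property, not a per-seed guarantee
  n_kept <- vapply(302:307, function(s) {
    d <- sim_enriched(150, 5, 0, seed = s)
    length(forward_select(d$post, d$A)$annotations)
  }, numeric(1))
  expect_gte(sum(n_kept == 0), 4)
  # and an empty model's likelihood is the flat-prior one
  d <- sim_enriched(150, 5, 0, seed = 303)
  m <- forward_select(d$post, d$A)
  expect_length(m$annotations, 0)
  expect_equal(m$loglik, model_loglik(d$post, d$A[, 0, drop = FALSE],
                                      numeric(0), 0))
})

test_that("fold assignment is a pure function of seed and signal ids", {
  ids <- sprintf("signal%03d", 1:40)
  f1 <- cv_folds(ids, 10, seed = 7)
  f2 <- cv_folds(sample(ids), 10, seed = 7)
  expect_identical(f1, f2[names(f1)])
  expect_false(identical(f1, cv_folds(ids, 10, seed = 8)))
  expect_true(all(table(f1) == 4))
})

test_that("penalty selection returns a degenerate grid unchanged and shrinks noise", {
  d <- sim_enriched(60, 1, 0, seed = 303)
  m <- structure(list(annotations = "ann01", gamma = c(ann01 = 0.3),
                      lambda = 0, loglik = NA_real_, cv_loglik = NA_real_),
                 class = "enrichment_model")
  expect_equal(select_penalty(d$post, d$A, m,
                              fit_config(lambda_grid = 0.5)), 0.5)
  # a noise annotation wants the strongest shrinkage on offer (majority rule)
  lams <- vapply(401:405, function(s) {
    dn <- sim_enriched(150, 1, 0, seed = s)
    select_penalty(dn$post, dn$A, m,
                   fit_config(lambda_grid = c(0.01, 5), n_folds = 5, seed = 1))
  }, numeric(1))
  expect_gte(sum(lams == 5), 3)
})

test_that("backward elimination drops noise, keeps truth, and is a no-op when empty", {
  start <- structure(list(annotations = c("ann01", "ann02"),
                          gamma = c(ann01 = 1.3, ann02 = 0),
                          lambda = 0.1, loglik = NA_real_,
                          cv_loglik = NA_real_),
                     class = "enrichment_model")
  cfg <- fit_config(n_folds = 5, seed = 1)
  kept <- lapply(601:605, function(s) {
    d <- sim_enriched(400, 2, log(4), seed = s)
    backward_eliminate(d$post, d$A, start, lambda = 0.1, config = cfg)$annotations
  })
  # the true annotation survives every time; the noise one goes most times
  expect_true(all(vapply(kept, function(k) "ann01" %in% k, logical(1))))
  expect_gte(sum(vapply(kept, function(k) !"ann02" %in% k, logical(1))), 3)
  # a lone noise annotation is dropped entirely: held-out likelihood improves
  d0 <- sim_enriched(200, 1, 0, seed = 501)
  noisy <- structure(list(annotations = "ann01", gamma = c(ann01 = 0.5),
                          lambda = 0.1, loglik = NA_real_,
                          cv_loglik = NA_real_),
                     class = "enrichment_model")
  out0 <- backward_eliminate(d0$post, d0$A, noisy, lambda = 0.1, config = cfg)
  expect_length(out0$annotations, 0)
  # empty in, empty out
  empty <- structure(list(annotations = character(0), gamma = numeric(0),
                          lambda = 0.1, loglik = NA_real_,
                          cv_loglik = NA_real_),
                     class = "enrichment_model")
  expect_length(backward_eliminate(d0$post, d0$A, empty, 0.1, cfg)$annotations, 0)
})

test_that("reweighting applies exp(gamma) priors and preserves flat-prior identity", {
  # two variants, equal ABFs, one annotated with gamma = ln 4: priors 4:1
  tbl <- tibble::tibble(variant_id = c("v1", "v2"), signal_id = "s1",
                        log_abf = c(1.7, 1.7))
  A <- two_variant_A()
  m4 <- structure(list(annotations = "ann01", gamma = c(ann01 = log(4)),
                       lambda = 0, loglik = NA_real_, cv_loglik = NA_real_),
                  class = "enrichment_model")
  rw <- reweight_posteriors(tbl, A, m4)
  expect_equal(rw$posteriors$posterior, c(0.8, 0.2), tolerance = 1e-12)
  # gamma = 0 must reproduce the flat-prior posteriors bitwise
  base <- signal_posteriors(tibble::tibble(variant_id = c("v1", "v2"),
                                           signal_id = "s1", z = c(2.3, 1.1)),
                            config = abf_config(W = W_Z))
  m0 <- structure(list(annotations = "ann01", gamma = c(ann01 = 0),
                       lambda = 0, loglik = NA_real_, cv_loglik = NA_real_),
                  class = "enrichment_model")
  rw0 <- reweight_posteriors(base, A, m0)
  expect_identical(rw0$posteriors$posterior, base$posterior)
  # missing annotation columns are named in the error
  expect_error(reweight_posteriors(tbl, A[, 0, drop = FALSE], m4), "ann01")
})

test_that("reweighting never reorders variants with identical annotation rows", {
  set.seed(11)
  n <- 30
  tbl <- tibble::tibble(variant_id = sprintf("v%02d", 1:n), signal_id = "s1",
                        log_abf = rnorm(n, 2, 2))
  A <- matrix(rbinom(n * 3, 1L, 0.3), n, 3,
              dimnames = list(tbl$variant_id, sprintf("ann%02d", 1:3)))
  m <- structure(list(annotations = colnames(A),
                      gamma = setNames(c(1.2, -0.7, 0.4), colnames(A)),
                      lambda = 0, loglik = NA_real_, cv_loglik = NA_real_),
                 class = "enrichment_model")
  rw <- reweight_posteriors(tbl, A, m)
  key <- apply(A, 1, paste, collapse = "")
  for (k in unique(key)) {
    i <- which(key == k)
    if (length(i) < 2) next
    base_order <- order(tbl$log_abf[i])
    expect_identical(order(rw$posteriors$posterior[i]), base_order)
  }
})
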