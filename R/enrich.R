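#' Enrichment-fit configuration
#'
#' Knobs for the hierarchical annotation-enrichment fit. Defaults: ridge
#' grid {0.01, 0.05, 0.1, 0.25, 0.5, 1}, 10-fold cross-validation over
#' signals (signals, not variants, are the independent units), a forward
#' tolerance of 2 log-likelihood units (an AIC-like free choice), and a
#' gradient-norm convergence tolerance of 1e-8.
#'
#' @param lambda_grid Positive ridge penalties to consider.
#' @param n_folds Number of CV folds over signals (>= 2).
#' @param forward_tolerance Minimum log-likelihood gain to add an annotation.
#' @param max_iter Optimizer iteration cap.
#' @param convergence_tol Gradient-norm tolerance at the reported optimum.
#' @param seed Integer seed controlling fold assignment.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lambda_grid = c(0.01, 0.05, 0.1, 0.25, 0.5, 1),
                       n_folds = 10, forward_tolerance = 2,
                       max_iter = 200, convergence_tol = 1e-8, seed = 1) {
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid >= 0),
            n_folds >= 2, forward_tolerance >= 0, max_iter >= 1)
  structure(list(lambda_grid = lambda_grid, n_folds = as.integer(n_folds),
                 forward_tolerance = forward_tolerance,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol,
                 seed = as.integer(seed)),
            class = "fit_config")
}

# Internal working representation: log_abf vector plus a list of row-index
# blocks, one per signal, aligned with the annotation matrix rows.
.signal_blocks <- function(posteriors) {
  stopifnot(all(c("signal_id", "log_abf", "variant_id") %in% names(posteriors)))
  split(seq_len(nrow(posteriors)),
        factor(posteriors$signal_id, levels = unique(posteriors$signal_id)))
}

.align_annotations <- function(posteriors, annotations) {
  if (is.null(rownames(annotations)))
    stop("annotation matrix must carry variant_id rownames")
  miss <- setdiff(posteriors$variant_id, rownames(annotations))
  if (length(miss))
    stop(sprintf("annotation rows missing for variant(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  annotations[posteriors$variant_id, , drop = FALSE]
}

#' Penalized marginal log-likelihood of the enrichment model
#'
#' Within each signal, the causal prior of variant j is proportional to
#' `exp(sum_a gamma_a A_ja)`; the signal's marginal-likelihood contribution
#' is `log sum_j prior_j ABF_j` with the prior normalized within the signal,
#' and the total is the sum over signals minus a ridge penalty
#' `lambda * ||gamma||^2`. With `gamma = 0` this reduces to
#' `sum_s log(mean ABF in signal s)`.
#'
#' @param posteriors Tibble with `variant_id`, `signal_id`, `log_abf`
#'   (natural log), e.g. from [finemap_signals()].
#' @param annotations 0/1 matrix with variant_id rownames covering all
#'   variants; columns are annotations.
#' @param gamma Numeric coefficient vector aligned to `colnames(annotations)`.
#' @param lambda Ridge penalty (>= 0).
#' @return The penalized log-likelihood (finite scalar).
#' @export
model_loglik <- function(posteriors, annotations, gamma, lambda = 0) {
  if (length(gamma) != ncol(annotations))
    stop(sprintf("gamma has length %d but annotations has %d column(s)",
                 length(gamma), ncol(annotations)))
  A <- .align_annotations(posteriors, annotations)
  blocks <- .signal_blocks(posteriors)
  eta <- if (ncol(A)) as.vector(A %*% gamma) else rep(0, nrow(posteriors))
  la <- posteriors$log_abf
  ll <- sum(vapply(blocks, function(i) {
    logsumexp(eta[i] + la[i]) - logsumexp(eta[i])
  }, numeric(1)))
  ll - lambda * sum(gamma^2)
}

# Penalized log-likelihood and analytic gradient for optim().
.loglik_grad <- function(eta_fun, A, la, blocks, lambda) {
  list(
    fn = function(g) {
      eta <- eta_fun(g)
      sum(vapply(blocks, function(i)
        logsumexp(eta[i] + la[i]) - logsumexp(eta[i]), numeric(1))) -
        lambda * sum(g^2)
    },
    gr = function(g) {
      eta <- eta_fun(g)
      grad <- numeric(length(g))
      for (i in blocks) {
        a <- eta[i] + la[i]
        w <- exp(a - logsumexp(a))       # posterior weights
        q <- exp(eta[i] - logsumexp(eta[i]))  # prior weights
        grad <- grad + as.vector(crossprod(A[i, , drop = FALSE], w - q))
      }
      grad - 2 * lambda * g
    }
  )
}

#' Fit enrichment coefficients for a fixed annotation set
#'
#' Maximizes the penalized marginal log-likelihood over `gamma` by BFGS with
#' the analytic gradient. The objective is smooth and, for `lambda > 0`,
#' strictly concave in the penalty direction.
#'
#' @inheritParams model_loglik
#' @param config A [fit_config()].
#' @param gamma_init Optional start values (default zero).
#' @return List with `gamma` (named), `loglik` (penalized, at the optimum),
#'   and `convergence` info.
#' @export
fit_enrichment <- function(posteriors, annotations, lambda = 0,
                           config = fit_config(), gamma_init = NULL) {
  A <- .align_annotations(posteriors, annotations)
  p <- ncol(A)
  blocks <- .signal_blocks(posteriors)
  la <- posteriors$log_abf
  if (p == 0)
    return(list(gamma = numeric(0),
                loglik = model_loglik(posteriors, annotations, numeric(0), lambda),
                convergence = 0L))
  fg <- .loglik_grad(function(g) as.vector(A %*% g), A, la, blocks, lambda)
  g0 <- if (is.null(gamma_init)) rep(0, p) else gamma_init
  opt <- stats::optim(g0, fn = fg$fn, gr = fg$gr, method = "BFGS",
                      control = list(fnscale = -1, maxit = config$max_iter,
                                     reltol = 1e-14))
  gnorm <- sqrt(sum(fg$gr(opt$par)^2))
  if (gnorm > max(config$convergence_tol, 1e-5) * max(1, abs(opt$value))) {
    # polish from the BFGS solution if the gradient is not yet flat
    opt2 <- stats::optim(opt$par, fn = fg$fn, gr = fg$gr, method = "BFGS",
                         control = list(fnscale = -1, maxit = config$max_iter,
                                        reltol = 1e-14))
    if (opt2$value >= opt$value) opt <- opt2
  }
  gamma <- stats::setNames(opt$par, colnames(A))
  list(gamma = gamma, loglik = opt$value, convergence = opt$convergence)
}

#' Greedy forward selection of enriched annotations
#'
#' Starting from the empty model, each round refits every candidate jointly
#' with the current set and adds the annotation with the largest penalized
#' log-likelihood gain; selection stops when the best gain falls below
#' `forward_tolerance`. Duplicated columns tie; the earlier column wins.
#'
#' @inheritParams fit_enrichment
#' @return An `enrichment_model` list: `annotations` (selected names),
#'   `gamma`, `lambda`, `loglik`, `cv_loglik` (NA until CV is run).
#' @export
forward_select <- function(posteriors, annotations, config = fit_config(),
                           lambda = 0) {
  candidates <- colnames(annotations)
  selected <- character(0)
  fit0 <- fit_enrichment(posteriors, annotations[, selected, drop = FALSE],
                         lambda, config)
  cur_ll <- fit0$loglik
  cur_fit <- fit0
  repeat {
    rest <- setdiff(candidates, selected)
    if (!length(rest)) break
    trial <- lapply(rest, function(a) {
      fit_enrichment(posteriors, annotations[, c(selected, a), drop = FALSE],
                     lambda, config)
    })
    lls <- vapply(trial, `[[`, numeric(1), "loglik")
    best <- which.max(lls)  # first max: earlier column wins ties
    if (lls[best] - cur_ll < config$forward_tolerance) break
    selected <- c(selected, rest[best])
    cur_ll <- lls[best]
    cur_fit <- trial[[best]]
  }
  structure(list(annotations = selected, gamma = cur_fit$gamma,
                 lambda = lambda, loglik = cur_ll, cv_loglik = NA_real_),
            class = "enrichment_model")
}

#' @method print enrichment_model
#' @export
print.enrichment_model <- function(x, ...) {
  if (!length(x$annotations)) {
    cat("Enrichment model: empty (no annotation retained)\n")
  } else {
    cat(sprintf("Enrichment model (lambda = %g, loglik = %.3f):\n",
                x$lambda, x$loglik))
    for (i in seq_along(x$annotations))
      cat(sprintf("  %s: gamma = %+.3f\n", x$annotations[i], x$gamma[i]))
  }
  invisible(x)
}

#' Deterministic fold assignment over signals
#'
#' @param signal_ids Character vector of unique signal ids.
#' @param n_folds Number of folds.
#' @param seed Integer seed; the assignment is a pure function of
#'   (seed, sorted signal ids).
#' @return Named integer vector of fold labels in `1..n_folds`.
#' @export
cv_folds <- function(signal_ids, n_folds, seed) {
  ids <- sort(unique(signal_ids))
  if (n_folds > length(ids)) n_folds <- length(ids)
  perm <- with_seed(seed, sample.int(length(ids)))
  stats::setNames(((perm - 1L) %% n_folds) + 1L, ids)
}

# Sum over folds of held-out unpenalized log-likelihood for a given lambda.
.cv_loglik <- function(posteriors, annotations, lambda, folds, config) {
  fold_of <- folds[as.character(posteriors$signal_id)]
  total <- 0
  for (k in sort(unique(folds))) {
    train <- posteriors[fold_of != k, , drop = FALSE]
    test <- posteriors[fold_of == k, , drop = FALSE]
    if (!nrow(test)) next
    fit <- fit_enrichment(train, annotations, lambda, config)
    total <- total + model_loglik(test, annotations, fit$gamma, lambda = 0)
  }
  total
}

#' Cross-validated ridge-penalty selection
#'
#' For each penalty in the grid, refits the selected-annotation model on
#' k-1 folds of signals and scores the held-out fold by its unpenalized
#' log-likelihood; returns the penalty with the highest summed held-out
#' likelihood. Ties break toward the larger (more shrinking) penalty. Fold
#' assignment is deterministic given the config seed.
#'
#' @inheritParams fit_enrichment
#' @param model An `enrichment_model` from [forward_select()].
#' @return The selected lambda (scalar).
#' @export
select_penalty <- function(posteriors, annotations, model,
                           config = fit_config()) {
  grid <- sort(config$lambda_grid)
  if (length(grid) == 1) return(grid)
  if (!length(model$annotations)) return(max(grid))
  A <- annotations[, model$annotations, drop = FALSE]
  folds <- cv_folds(unique(posteriors$signal_id), config$n_folds, config$seed)
  cv <- vapply(grid, function(l)
    .cv_loglik(posteriors, A, l, folds, config), numeric(1))
  grid[max(which(cv >= max(cv) - 1e-9))]
}

#' Backward elimination against the cross-validation likelihood
#'
#' At the selected penalty, iteratively removes the annotation whose removal
#' most increases the summed held-out log-likelihood, refitting after each
#' removal; stops when no removal improves it. The last annotation is only
#' dropped if the empty model's CV likelihood is genuinely higher.
#'
#' @inheritParams select_penalty
#' @param lambda Penalty from [select_penalty()].
#' @return An `enrichment_model` refit on all signals at `lambda`, with
#'   `cv_loglik` filled in.
#' @export
backward_eliminate <- function(posteriors, annotations, model, lambda,
                               config = fit_config()) {
  selected <- model$annotations
  folds <- cv_folds(unique(posteriors$signal_id), config$n_folds, config$seed)
  cv_of <- function(sel)
    .cv_loglik(posteriors, annotations[, sel, drop = FALSE], lambda, folds, config)
  cur_cv <- cv_of(selected)
  while (length(selected)) {
    drops <- vapply(selected, function(a)
      cv_of(setdiff(selected, a)), numeric(1))
    best <- which.max(drops)
    if (drops[best] <= cur_cv) break
    selected <- setdiff(selected, selected[best])
    cur_cv <- drops[best]
  }
  fit <- fit_enrichment(posteriors, annotations[, selected, drop = FALSE],
                        lambda, config)
  structure(list(annotations = selected, gamma = fit$gamma, lambda = lambda,
                 loglik = fit$loglik, cv_loglik = cur_cv),
            class = "enrichment_model")
}

#' Full enrichment-model selection
#'
#' Convenience wrapper running forward selection, penalty selection by
#' cross-validation, and backward elimination, in that order.
#'
#' @inheritParams forward_select
#' @return An `enrichment_model`.
#' @export
fit_enrichment_model <- function(posteriors, annotations,
                                 config = fit_config()) {
  fwd <- forward_select(posteriors, annotations, config)
  lambda <- select_penalty(posteriors, annotations, fwd, config)
  backward_eliminate(posteriors, annotations, fwd, lambda, config)
}

#' Reweight fine-mapping posteriors with fitted functional priors
#'
#' Replaces the flat causal prior of a target signal with
#' `prior_j proportional to exp(sum_a gamma_a A_ja)` using the fitted
#' log-enrichments, renormalizes posteriors, and recomputes the credible set
#' at the configured level. With an empty model (or `gamma = 0`) the output
#' equals the flat-prior posteriors exactly.
#'
#' @param target Posterior table for one signal (needs `variant_id`,
#'   `log_abf`).
#' @param annotations Annotation matrix covering the target's variants.
#' @param model An `enrichment_model`.
#' @param level Credible-set level; default 0.99.
#' @return List with `posteriors` (tibble with updated `prior`, `posterior`,
#'   `in_credible_set`) and `credible_set`.
#' @export
reweight_posteriors <- function(target, annotations, model, level = 0.99) {
  target <- tibble::as_tibble(target)
  stopifnot(all(c("variant_id", "log_abf") %in% names(target)))
  miss <- setdiff(model$annotations, colnames(annotations))
  if (length(miss))
    stop(sprintf("annotation column(s) missing from target: %s",
                 paste(miss, collapse = ", ")))
  A <- .align_annotations(target, annotations)[, model$annotations, drop = FALSE]
  eta <- if (length(model$annotations)) as.vector(A %*% model$gamma)
         else rep(0, nrow(target))
  target$prior <- exp(eta - logsumexp(eta))
  lw <- eta + target$log_abf
  target$posterior <- exp(lw - logsumexp(lw))
  cs <- credible_set(target, level)
  target$in_credible_set <- target$variant_id %in% cs$variant_id
  list(posteriors = target, credible_set = cs)
}
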