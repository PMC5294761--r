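#' Pipeline configuration
#'
#' Collects the stage toggles, the output directory, the global seed and
#' the statistical defaults for a full synthetic run: simulate, fine-map,
#' annotate, enrich + reweight, allelic imbalance, cis-eQTL, report. Every
#' default the underlying methods leave open (prior variance W, credible
#' level, ridge grid, folds, filter thresholds) is recorded in the run
#' report so any run is auditable.
#'
#' @param out_dir Output directory for every stage artifact.
#' @param seed Global seed propagated to every stochastic stage.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param abf An [abf_config()].
#' @param fit A [fit_config()] (fold seed defaults to `seed`).
#' @param stages Character vector of stages to run, in pipeline order.
#' @param target_signal Signal whose posteriors are reweighted; default the
#'   first simulated signal.
#' @param min_reads,min_het_samples Imbalance filter thresholds.
#' @param eqtl_mode cis-window mode for the eQTL stage.
#' @param config_file Optional YAML/JSON file whose entries override the
#'   defaults above (flag-style arguments still win over the file).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "results/pipeline",
                            seed = 1,
                            sim = NULL, abf = abf_config(), fit = NULL,
                            stages = c("simulate", "finemap", "annotate",
                                       "enrich", "imbalance", "eqtl",
                                       "report"),
                            target_signal = NULL,
                            min_reads = 5, min_het_samples = 3,
                            eqtl_mode = "gene_window_100kb",
                            config_file = NULL) {
  if (!is.null(config_file)) {
    ov <- yaml::read_yaml(config_file)
    for (nm in intersect(names(ov), c("out_dir", "seed", "stages",
                                      "target_signal", "min_reads",
                                      "min_het_samples", "eqtl_mode")))
      assign(nm, ov[[nm]])
    if (!is.null(ov$sim)) sim <- do.call(sim_config, ov$sim)
    if (!is.null(ov$abf)) abf <- do.call(abf_config, ov$abf)
    if (!is.null(ov$fit)) fit <- do.call(fit_config, ov$fit)
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (is.null(fit)) fit <- fit_config(seed = seed)
  structure(list(out_dir = out_dir, seed = seed, sim = sim, abf = abf,
                 fit = fit, stages = stages, target_signal = target_signal,
                 min_reads = min_reads, min_het_samples = min_het_samples,
                 eqtl_mode = eqtl_mode),
            class = "pipeline_config")
}

.stage_path <- function(config, ...) file.path(config$out_dir, ...)

.require_stage_output <- function(path, stage, needed_by) {
  if (!file.exists(path))
    stop(sprintf("stage `%s` needs `%s` from stage `%s`, which did not run",
                 needed_by, path, stage))
  path
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order, writing every intermediate to
#' `out_dir` in the package's interchange formats, and collates a JSON +
#' markdown report: baseline and reweighted credible sets, the selected
#' annotations with their log-enrichments, the allelic-imbalance table with
#' direction calls, and the cis-eQTL table. Outputs contain no timestamps,
#' so identical configs produce byte-identical artifacts. A stage that is
#' missing an upstream input aborts naming the stage and the dependency.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly (a named list).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(s) s %in% config$stages
  report <- list(seed = config$seed,
                 parameters = list(W = config$abf$W, level = config$abf$level,
                                   lambda_grid = config$fit$lambda_grid,
                                   n_folds = config$fit$n_folds,
                                   forward_tolerance = config$fit$forward_tolerance,
                                   min_reads = config$min_reads,
                                   min_het_samples = config$min_het_samples,
                                   eqtl_mode = config$eqtl_mode))

  if (on_stage("simulate")) {
    message("[simulate] seed = ", config$sim$seed)
    sig <- simulate_signals(config$sim)
    seg <- simulate_chromatin_states(config$sim)
    ase <- simulate_allele_counts(
      config$sim, utils::head(sig$stats[, c("variant_id", "ref", "alt")], 20))
    eq <- simulate_eqtl_dataset(config$sim)
    write_summary_stats(sig$stats, .stage_path(config, "summary_stats.tsv"))
    write_annotation_matrix(sig$annotations, .stage_path(config, "annotations.tsv"))
    write_bed_states(seg, .stage_path(config, "chromatin_states.bed"))
    write_allele_counts(ase$counts, .stage_path(config, "allele_counts.tsv"))
    .write_tsv(ase$variants, .stage_path(config, "ase_variants.tsv"))
    write_genotypes_vcf(eq$genotypes, eq$variants,
                        .stage_path(config, "genotypes.vcf"))
    write_expression(eq$expression, eq$features,
                     .stage_path(config, "expression.tsv"))
    write_covariates(eq$covariates, .stage_path(config, "covariates.tsv"))
    write_sim_truth(list(signals = sig$truth, ase = ase$truth,
                         eqtl = eq$truth),
                    .stage_path(config, "sim_truth.json"))
  }

  if (on_stage("finemap")) {
    path <- .require_stage_output(.stage_path(config, "summary_stats.tsv"),
                                  "simulate", "finemap")
    stats <- read_summary_stats(path)
    fm <- finemap_signals(stats, config$abf)
    write_posteriors(fm$posteriors, .stage_path(config, "posteriors.tsv"))
    write_credible_sets(fm$credible_sets, .stage_path(config, "credible_sets.json"))
    report$baseline_credible_sizes <-
      vapply(fm$credible_sets, `[[`, numeric(1), "size")
    message("[finemap] mean credible-set size ",
            sprintf("%.2f", mean(report$baseline_credible_sizes)))
  }

  if (on_stage("annotate")) {
    bed <- .require_stage_output(.stage_path(config, "chromatin_states.bed"),
                                 "simulate", "annotate")
    stats <- read_summary_stats(.require_stage_output(
      .stage_path(config, "summary_stats.tsv"), "simulate", "annotate"))
    seg <- read_bed_states(bed)
    amat <- build_annotation_matrix(stats, seg, stretch = TRUE)
    write_annotation_matrix(amat, .stage_path(config, "annotations_chromatin.tsv"))
    stretch <- derive_stretch_enhancers(seg)
    write_bed_states(stretch, .stage_path(config, "stretch_enhancers.bed"))
    report$n_chromatin_annotations <- ncol(amat)
    report$n_stretch_enhancers <- nrow(stretch)
    message("[annotate] ", ncol(amat), " annotation columns, ",
            nrow(stretch), " stretch enhancers")
  }

  if (on_stage("enrich")) {
    post <- read_posteriors(.require_stage_output(
      .stage_path(config, "posteriors.tsv"), "finemap", "enrich"))
    amat <- read_annotation_matrix(.require_stage_output(
      .stage_path(config, "annotations.tsv"), "simulate", "enrich"))
    model <- fit_enrichment_model(post, amat, config$fit)
    target_id <- if (is.null(config$target_signal)) post$signal_id[1]
                 else config$target_signal
    target <- post[post$signal_id == target_id, , drop = FALSE]
    rw <- reweight_posteriors(target, amat, model, config$abf$level)
    write_posteriors(rw$posteriors, .stage_path(config, "posteriors_reweighted.tsv"))
    write_credible_sets(list(rw$credible_set),
                        .stage_path(config, "credible_set_reweighted.json"))
    jsonlite::write_json(
      list(annotations = model$annotations,
           gamma = as.list(model$gamma), lambda = model$lambda,
           loglik = model$loglik, cv_loglik = model$cv_loglik),
      .stage_path(config, "enrichment_model.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$enrichment <- list(annotations = model$annotations,
                              gamma = unname(model$gamma),
                              lambda = model$lambda)
    report$reweighted_credible_size <- rw$credible_set$size
    message("[enrich] selected {",
            paste(model$annotations, collapse = ", "), "}, lambda = ",
            model$lambda)
  }

  if (on_stage("imbalance")) {
    counts <- read_allele_counts(.require_stage_output(
      .stage_path(config, "allele_counts.tsv"), "simulate", "imbalance"))
    vars <- .read_tsv_checked(.require_stage_output(
      .stage_path(config, "ase_variants.tsv"), "simulate", "imbalance"),
      c("variant_id", "risk_allele"))
    res <- test_allelic_imbalance(counts, vars, config$min_reads,
                                  config$min_het_samples)
    rep_tbl <- imbalance_report(res)
    .write_tsv(rep_tbl, .stage_path(config, "imbalance.tsv"))
    report$imbalance <- list(n_tested = nrow(rep_tbl),
                             n_risk_lower = sum(rep_tbl$direction == "risk_lower"))
    message("[imbalance] ", nrow(rep_tbl), " variants tested")
  }

  if (on_stage("eqtl")) {
    ex <- read_expression(.require_stage_output(
      .stage_path(config, "expression.tsv"), "simulate", "eqtl"))
    geno <- read_genotypes_vcf(.require_stage_output(
      .stage_path(config, "genotypes.vcf"), "simulate", "eqtl"))
    cov <- read_covariates(.require_stage_output(
      .stage_path(config, "covariates.tsv"), "simulate", "eqtl"))
    vars <- tibble::tibble(variant_id = rownames(geno), chrom = "chr1",
                           pos = ex$features$tss + 5000)
    res <- run_cis_eqtl(ex$expression, geno, ex$features, vars, cov,
                        mode = config$eqtl_mode)
    .write_tsv(res, .stage_path(config, "eqtl.tsv"))
    report$eqtl <- list(n_pairs = nrow(res),
                        top_beta = if (nrow(res)) res$beta[1] else NA_real_)
    message("[eqtl] ", nrow(res), " cis pairs tested")
  }

  if (on_stage("report")) {
    jsonlite::write_json(report, .stage_path(config, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    md <- c("# Pipeline report", "",
            sprintf("- seed: %d", config$seed),
            sprintf("- W = %g, credible level = %g", config$abf$W,
                    config$abf$level),
            if (!is.null(report$baseline_credible_sizes))
              sprintf("- mean baseline credible-set size: %.6g",
                      mean(report$baseline_credible_sizes)),
            if (!is.null(report$reweighted_credible_size))
              sprintf("- reweighted credible-set size (target signal): %d",
                      report$reweighted_credible_size),
            if (!is.null(report$enrichment))
              sprintf("- selected annotations: %s",
                      paste(report$enrichment$annotations, collapse = ", ")),
            if (!is.null(report$imbalance))
              sprintf("- imbalance: %d tested, %d risk-lower",
                      report$imbalance$n_tested, report$imbalance$n_risk_lower),
            if (!is.null(report$eqtl))
              sprintf("- eQTL: %d cis pairs, top beta %.6g",
                      report$eqtl$n_pairs, report$eqtl$top_beta))
    writeLines(md, .stage_path(config, "report.md"))
  }
  invisible(report)
}
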