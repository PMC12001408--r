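#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by [run_pipeline()].
#' Either `otu_table`/`metadata` paths or a `simulate` block (a
#' [synthetic_config()] or a list of its arguments) must be given.  The
#' resolved configuration is serialized next to a run's outputs so any run
#' can be reproduced from its output directory alone.
#'
#' @param otu_table,metadata input paths (dense TSV dialect; see
#'   [read_otu_table()]), or `NULL` when simulating.
#' @param otu_dialect dialect for `otu_table`.
#' @param taxonomy optional taxonomy TSV path.
#' @param simulate `NULL`, or a [synthetic_config()] / list of arguments.
#' @param coverage_threshold Good's coverage gate, percent (default 85).
#' @param rarefaction_depth,rarefaction_iterations alpha-diversity settings
#'   (defaults 1000, 1000).
#' @param permutations PERMANOVA permutation count (default 999).
#' @param permanova_terms variables tested one at a time against the
#'   Bray-Curtis matrix.
#' @param model_terms decay-model predictors (see [decay_model()]).
#' @param split_months interval split for the subgroup analysis (default 15).
#' @param seed master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table = NULL, metadata = NULL,
                            otu_dialect = "tsv_dense", taxonomy = NULL,
                            simulate = NULL,
                            coverage_threshold = 85,
                            rarefaction_depth = 1000,
                            rarefaction_iterations = 1000,
                            permutations = 999,
                            permanova_terms = c("subject_id", "interval_months",
                                                "sex", "cancer", "method"),
                            model_terms = c("months", "age", "sex", "cancer"),
                            split_months = 15,
                            seed = 1) {
  if (is.null(simulate) && (is.null(otu_table) || is.null(metadata)))
    ur_stop("either input paths or a simulate block is required",
            "urostab_config_error")
  if (!is.null(simulate) && !inherits(simulate, "synthetic_config"))
    simulate <- do.call(synthetic_config, as.list(simulate))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order qc -> alpha -> overlap -> beta -> models on
#' real or simulated inputs and writes per-stage TSVs, a JSON summary of the
#' headline aggregates, the resolved configuration and a run log into
#' `out_dir`.  Stage outputs are pure functions of (inputs, configuration,
#' seed): rerunning with the same seed reproduces every file byte-for-byte.
#' A stage failure aborts with a stage-named error; files already written are
#' retained.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return The headline summary (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message("[urostab] ", line)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ur_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "urostab_stage_error")
    })
  }
  note("urostab %s, R %s, seed %s",
       as.character(utils::packageVersion("urostab")),
       paste(R.version$major, R.version$minor, sep = "."),
       format(config$seed))

  cohort <- stage("input", {
    if (!is.null(config$simulate)) {
      gen <- generate_cohort(config$simulate, seed = config$seed)
      if (!is.null(out_dir)) {
        write_otu_table(gen$cohort$table, file.path(out_dir, "simulated_counts.tsv"))
        truth_report(gen$truth, path = file.path(out_dir, "truth.tsv"))
      }
      note("simulated cohort: %d subjects, %d OTUs (clamp fired %d times)",
           n_subjects(gen$cohort), ncol(gen$cohort$table), gen$truth$n_clamped)
      gen$cohort
    } else {
      tab <- read_otu_table(config$otu_table, dialect = config$otu_dialect,
                            taxonomy = config$taxonomy)
      md <- read_metadata(config$metadata)
      build_paired_cohort(tab, md)
    }
  })

  qc <- stage("qc", qc_cohort(cohort, coverage_threshold = config$coverage_threshold))
  note("qc: %d subjects excluded by coverage gate, %d retained; %d OTUs after singleton removal",
       qc$report$n_excluded_subjects, qc$report$n_retained_subjects,
       ncol(qc$cohort$table))
  emit(qc$report$per_sample, "coverage_report.tsv")
  cohort <- qc$cohort

  alpha <- stage("alpha", iterated_alpha(
    cohort, depth = config$rarefaction_depth,
    iterations = config$rarefaction_iterations, seed = config$seed))
  note("alpha: %d samples rarefied to %d reads x %d iterations",
       nrow(alpha), config$rarefaction_depth, config$rarefaction_iterations)
  emit(as.data.frame(alpha), "alpha_diversity.tsv")

  ov <- stage("overlap", cohort_overlap(cohort))
  emit(ov$summary, "overlap_per_subject.tsv")
  prev <- stage("overlap", tryCatch(prevalence_table(cohort),
                                    urostab_validation_error = function(e) NULL))
  if (!is.null(prev)) emit(prev, "prevalence_table.tsv")

  beta <- stage("beta", {
    rel <- to_relative_abundance(cohort)
    d <- distance_matrix(rel)
    design <- merge(cohort$samples, cohort$subjects, by = "subject_id",
                    sort = FALSE)
    design <- design[match(labels(d), design$sample_id), , drop = FALSE]
    fits <- lapply(config$permanova_terms, function(tm)
      permanova(d, design, terms = tm, permutations = config$permutations,
                seed = config$seed))
    stats::setNames(fits, config$permanova_terms)
  })
  beta_df <- do.call(rbind, lapply(names(beta), function(tm) {
    df <- as.data.frame(beta[[tm]])
    cbind(model = tm, df)
  }))
  emit(beta_df, "permanova.tsv")

  models <- stage("models", {
    fit <- decay_model(ov, terms = config$model_terms)
    sub <- interval_subgroup_analysis(ov, split_months = config$split_months)
    chao_by_tp <- stats::setNames(alpha$chao1_mean, alpha$sample_id)
    paired <- split(alpha, alpha$subject_id)
    diffs <- vapply(paired, function(g)
      g$chao1_mean[g$timepoint == 2] - g$chao1_mean[g$timepoint == 1],
      numeric(1))
    chao_test <- tryCatch(wilcoxon_signed_rank(diffs),
                          urostab_error = function(e) NULL)
    cor_test <- tryCatch(
      pearson_r2(ov$summary$n_shared, ov$summary$shared_abund_mean),
      urostab_error = function(e) NULL)
    list(fit = fit, subgroups = sub, chao_test = chao_test, cor_test = cor_test)
  })
  emit(models$fit$coefficients, "decay_model.tsv")
  emit(models$subgroups$groups, "interval_subgroups.tsv")

  agg <- ov$aggregates$overall
  gx <- function(stat, col) agg[agg$statistic == stat, col]
  slope_row <- models$fit$coefficients[models$fit$coefficients$term == "months", ]
  summary <- list(
    n_subjects_retained = n_subjects(cohort),
    n_subjects_excluded = qc$report$n_excluded_subjects,
    mean_otus_per_sample = gx("n_otus_per_sample", "mean"),
    sd_otus_per_sample = gx("n_otus_per_sample", "sd"),
    mean_n_shared = gx("n_shared", "mean"),
    sd_n_shared = gx("n_shared", "sd"),
    mean_frac_shared = gx("frac_shared", "mean"),
    mean_shared_abund_pct = 100 * gx("shared_abund_mean", "mean"),
    sd_shared_abund_pct = 100 * gx("shared_abund_mean", "sd"),
    mean_chao1 = mean(alpha$chao1_mean),
    mean_shannon = mean(alpha$shannon_mean),
    permanova_r2 = lapply(beta, function(b) b$R2[1]),
    permanova_p = lapply(beta, function(b) b$Pr_perm[1]),
    decay_intercept_pct = models$fit$coefficients$estimate[1],
    decay_slope_pct_per_month = slope_row$estimate,
    decay_slope_ci = c(slope_row$ci_lo, slope_row$ci_hi),
    decay_slope_p = slope_row$p,
    decay_marginal_r2 = models$fit$marginal_r2,
    subgroup_means_pct = models$subgroups$groups$mean_pct,
    pearson_r2_shared = if (!is.null(models$cor_test)) models$cor_test$r_squared else NA,
    seed = config$seed)
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg <- config
    cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved_config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(summary)
}
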