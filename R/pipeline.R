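# End-to-end orchestration: simulate -> day labeling -> QC -> screen ->
# train -> evaluate -> project -> recovery -> inflammation, with file-based
# stage outputs and a JSON + Markdown report.

#' Pipeline configuration
#'
#' @param generator a [generator_config()]
#' @param qc a [qc_config()], or `NULL` to skip sample filtering
#' @param selection a [selection_config()]
#' @param recovery a [recovery_config()]
#' @param folds,repeats cross-validation settings
#' @param permutation_runs permutation runs for the AUC significance test
#'   (0 disables the permutation stage)
#' @param n_outliers,outlier_magnitude inject this many displaced rows
#'   (QC fixtures) into the simulated table before filtering
#' @param seed master seed; stage seeds are derived from it
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(generator = generator_config(),
                            qc = qc_config(),
                            selection = selection_config(),
                            recovery = recovery_config(),
                            folds = 5, repeats = 10,
                            permutation_runs = 0,
                            n_outliers = 0, outlier_magnitude = 50,
                            seed = 1L) {
  generator$seed <- derive_seed(seed, "generator")
  structure(list(generator = generator, qc = qc, selection = selection,
                 recovery = recovery, folds = folds, repeats = repeats,
                 permutation_runs = permutation_runs,
                 n_outliers = n_outliers,
                 outlier_magnitude = outlier_magnitude,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_stage_csv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

#' Run the full phenoreversion analysis pipeline
#'
#' Simulates a cohort, labels days since disease onset, filters samples by
#' density-based QC, screens the variable panel, fits and cross-validates
#' the O-PLS-DA discrimination model, sets the Youden cutoff from the
#' training-score ROC, projects the longitudinal samples, estimates
#' per-subject recovery days, fits the GEV recovery-time distribution and
#' its age/severity sub-models, computes recovered fractions per day bin,
#' and runs the cytokine fold-change and MCP-1 coupling analysis. Stage
#' outputs are written as CSV, plus a JSON and Markdown report carrying a
#' provenance block (package version, seed, configuration hash); reports
#' contain no timestamps, so identical runs are byte-identical.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   file output
#' @return the report as a list (invisibly, with all stage objects attached
#'   as attribute `"objects"`)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # -- simulate ---------------------------------------------------------
  pop <- generate_population(config$generator)
  long <- generate_longitudinal(config$generator)
  all_samples <- rbind(pop, long)

  outlier_ids <- character(0)
  if (config$n_outliers > 0) {
    inj <- inject_outliers(all_samples, config$n_outliers,
                           config$outlier_magnitude,
                           seed = derive_seed(config$seed, "outliers"))
    all_samples <- inj$samples
    outlier_ids <- inj$outlier_ids
  }

  # -- day labeling -----------------------------------------------------
  all_samples <- assign_days_since_covid(all_samples)
  .write_stage_csv(all_samples, out_dir, "samples")

  # -- sample QC --------------------------------------------------------
  if (!is.null(config$qc)) {
    qc_res <- qc_filter_dbscan(all_samples, config$qc)
    samples <- qc_res$kept
    discarded <- qc_res$discarded_ids
  } else {
    samples <- all_samples
    discarded <- character(0)
  }

  # -- screen -----------------------------------------------------------
  train <- samples[samples$cohort == "HC" | samples$acute, , drop = FALSE]
  y <- as.integer(train$acute)
  logx <- log(sample_matrix(train))
  selection <- screen_panel(logx, y,
                            covariates = train[, c("age", "sex")],
                            cfg = config$selection)
  panel <- kept_variables(selection)
  if (length(panel) < 2) stop("screen kept fewer than 2 variables")
  .write_stage_csv(selection, out_dir, "selection")

  # -- train + evaluate -------------------------------------------------
  ls_train <- log_standardize(train, variables = panel)
  model <- fit_oplsda(ls_train$matrix, y, scaling = ls_train$stats)
  cv <- cross_validate(logx[, panel, drop = FALSE], y,
                       folds = config$folds, repeats = config$repeats,
                       seed = derive_seed(config$seed, "cv"))
  roc_oof <- roc_auc(cv$aggregate, y)
  roc_train <- roc_auc(model$scores$t_pred, y)
  model$cutoff_tpred <- roc_train$youden_cutoff

  perm <- NULL
  if (config$permutation_runs > 0) {
    perm <- permutation_test(logx[, panel, drop = FALSE], y, "auc",
                             n_runs = config$permutation_runs,
                             seed = derive_seed(config$seed, "perm"),
                             folds = config$folds, repeats = 1)
  }

  # -- project longitudinal samples ------------------------------------
  followup <- samples[samples$cohort %in% c("AC", "RE") &
                        is.finite(samples$day), , drop = FALSE]
  z_fu <- log_standardize(followup, stats = ls_train$stats)$matrix
  scores <- project_scores(model, z_fu)
  scores$subject_id <- followup$subject_id
  scores$day <- followup$day
  .write_stage_csv(scores, out_dir, "scores")

  # -- recovery ---------------------------------------------------------
  d_stats <- distance_to_recovery(scores, model)
  fractions <- recovered_fraction(d_stats)
  estimates <- estimate_recovery_days(scores, model$hc_mean_tpred,
                                      config$recovery)
  valid_days <- estimates$recovery_days[estimates$valid]
  gev <- fit_gev(valid_days)
  meta <- followup[!duplicated(followup$subject_id),
                   c("subject_id", "age", "severity")]
  sub_age <- subgroup_models(estimates, meta, "age", config$recovery)
  sub_sev <- subgroup_models(estimates, meta, "severity", config$recovery)
  .write_stage_csv(estimates, out_dir, "recovery_estimates")
  .write_stage_csv(fractions, out_dir, "recovered_fractions")

  # -- inflammation -----------------------------------------------------
  cyto_samples <- samples[samples$cohort %in% c("HC", "AC", "RE"), ,
                          drop = FALSE]
  cyto <- generate_cytokines(config$generator, cyto_samples)
  groups <- data.frame(
    sample_id = cyto_samples$sample_id,
    group = factor(ifelse(cyto_samples$acute, "case", "control"),
                   levels = c("control", "case")))
  groups <- groups[cyto_samples$cohort == "HC" | cyto_samples$acute, ]
  fc <- fold_change_analysis(cyto, groups)
  hc_ids <- samples$sample_id[samples$cohort == "HC"]
  mcp1_healthy <- mean(cyto$level[cyto$marker == "MCP-1" &
                                    cyto$sample_id %in% hc_ids])
  decays <- subject_marker_decays(
    cyto[cyto$sample_id %in% followup$sample_id, ], "MCP-1", mcp1_healthy)
  infl_cor <- tryCatch(correlate_recovery(decays, estimates),
                       error = function(e) NULL)
  .write_stage_csv(fc, out_dir, "cytokine_fold_changes")

  # -- report -----------------------------------------------------------
  gev_par <- c(location = gev$location, scale = gev$scale, shape = gev$shape)
  report <- list(
    provenance = list(
      package = "phenorevert",
      version = as.character(utils::packageVersion("phenorevert")),
      seed = config$seed,
      config_hash = fnv1a32(paste(deparse(config), collapse = ""))),
    n_samples = nrow(all_samples),
    n_discarded_qc = length(discarded),
    discarded_ids = discarded,
    injected_outlier_ids = outlier_ids,
    panel = panel,
    panel_size = length(panel),
    auc_out_of_fold = roc_oof$auc,
    auc_training = roc_train$auc,
    cutoff_tpred = model$cutoff_tpred,
    sensitivity = roc_train$sensitivity,
    specificity = roc_train$specificity,
    permutation_p_auc = if (!is.null(perm)) perm$p_value else NA,
    n_subjects_eligible = sum(estimates$valid),
    gev = as.list(gev_par),
    gev_mode_days = gev_mode(gev$location, gev$scale, gev$shape),
    gev_median_days = qgev(0.5, gev$location, gev$scale, gev$shape),
    gev_q95_days = qgev(0.95, gev$location, gev$scale, gev$shape),
    empirical_q95_days = unname(stats::quantile(valid_days, 0.95)),
    subgroup_age = lapply(sub_age, function(f)
      list(location = f$location, scale = f$scale, shape = f$shape, n = f$n)),
    subgroup_severity = lapply(sub_sev, function(f)
      list(location = f$location, scale = f$scale, shape = f$shape, n = f$n)),
    recovered_fractions = fractions,
    cytokine_fold_changes = fc,
    mcp1_recovery_correlation = if (!is.null(infl_cor)) {
      list(r = infl_cor$r, p_value = infl_cor$p_value, n = infl_cor$n)
    } else NULL)

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    md <- c(
      "# Phenoreversion pipeline report",
      "",
      sprintf("- seed: %d; config hash: %s", config$seed,
              report$provenance$config_hash),
      sprintf("- samples: %d (%d discarded by QC)", report$n_samples,
              report$n_discarded_qc),
      sprintf("- selected panel: %d variables", report$panel_size),
      sprintf("- out-of-fold AUC: %.4f (training AUC %.4f, cutoff %.3f)",
              report$auc_out_of_fold, report$auc_training,
              report$cutoff_tpred),
      sprintf("- GEV recovery-time fit: location %.2f, scale %.2f, shape %.3f (n = %d)",
              gev$location, gev$scale, gev$shape, gev$n),
      sprintf("- mode %.1f d, median %.1f d, model 95%% quantile %.1f d, empirical 95%% quantile %.1f d",
              report$gev_mode_days, report$gev_median_days,
              report$gev_q95_days, report$empirical_q95_days))
    writeLines(md, file.path(out_dir, "report.md"))
  }

  attr(report, "objects") <- list(
    samples = all_samples, selection = selection, model = model, cv = cv,
    roc_oof = roc_oof, roc_train = roc_train, scores = scores,
    d_stats = d_stats, estimates = estimates, gev = gev,
    sub_age = sub_age, sub_sev = sub_sev, cytokines = cyto,
    decays = decays, infl_cor = infl_cor, permutation = perm)
  invisible(report)
}
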