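# Variable panel selection: covariate-adjusted linear models per variable,
# Benjamini-Hochberg FDR across variables, an absolute effect-size floor in
# control-SD units, and greedy correlation pruning.

#' Selection configuration
#'
#' @param alpha_adj BH-adjusted p-value threshold (default 0.05)
#' @param effect_floor minimum absolute effect in control-SD units (default 0.5)
#' @param prune_r Pearson correlation threshold for pruning (default 0.8)
#' @param covariates adjustment covariates (default age and sex)
#' @return object of class `selection_config`
#' @export
selection_config <- function(alpha_adj = 0.05, effect_floor = 0.5,
                             prune_r = 0.8, covariates = c("age", "sex")) {
  if (alpha_adj <= 0 || alpha_adj >= 1) stop_config("alpha_adj", "must be in (0, 1)")
  if (effect_floor < 0) stop_config("effect_floor", "must be >= 0")
  if (prune_r <= 0 || prune_r > 1) stop_config("prune_r", "must be in (0, 1]")
  structure(list(alpha_adj = alpha_adj, effect_floor = effect_floor,
                 prune_r = prune_r, covariates = covariates),
            class = "selection_config")
}

#' Covariate-adjusted univariate screen
#'
#' Fits, per variable, an ordinary least squares model
#' `log value ~ group + covariates` and tests the group coefficient
#' (two-sided). The effect size is the group coefficient divided by the
#' control group's log-scale SD of that variable, so it reads as a shift in
#' control-SD units; positive values mean elevated in the case group.
#' P-values are Benjamini-Hochberg adjusted across all tested variables, and
#' a variable passes the univariate stage when the adjusted p-value is below
#' `alpha_adj` and the absolute effect reaches `effect_floor`.
#'
#' @param logx numeric matrix of log-transformed values (samples x variables)
#' @param group factor/vector with two levels; the first level (or `FALSE`/0)
#'   is the control group
#' @param covariates data.frame of per-sample covariates named as in `cfg`
#'   (numeric, or two-level factors/character encoded as a single indicator)
#' @param cfg a [selection_config()]
#' @return `selection_result` data.frame: `variable`, `beta_group`,
#'   `effect_sd`, `p_raw`, `p_adj`, `passed_univariate`, `kept_after_prune`
#'   (NA until [correlation_prune()]), `pruned_by`
#' @export
univariate_screen <- function(logx, group, covariates = NULL,
                              cfg = selection_config()) {
  logx <- as.matrix(logx)
  if (is.null(colnames(logx))) colnames(logx) <- paste0("V", seq_len(ncol(logx)))
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(as.factor(group)) - 1L
  if (length(unique(g)) != 2L) stop("group must have exactly two levels")
  if (min(table(g)) < 3L) stop("need at least 3 samples per group")
  n <- nrow(logx)

  design_cols <- list("(Intercept)" = rep(1, n), group = as.numeric(g))
  cov_names <- cfg$covariates[cfg$covariates %in% names(covariates %||% list())]
  for (cv in cov_names) {
    v <- covariates[[cv]]
    if (any(is.na(v))) stop(sprintf("covariate '%s' has missing values", cv))
    if (is.numeric(v)) {
      design_cols[[cv]] <- as.numeric(v)
    } else {
      f <- as.factor(v)
      if (nlevels(f) != 2L) {
        stop(sprintf("covariate '%s' must be numeric or two-level", cv))
      }
      design_cols[[cv]] <- as.numeric(f) - 1
    }
  }
  design <- do.call(cbind, design_cols)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop(paste0("collinear design columns: ", paste(dropped, collapse = ", ")))
  }

  # one QR decomposition, all variables at once
  coefs <- qr.coef(qrd, logx)
  resid <- qr.resid(qrd, logx)
  df_res <- n - qrd$rank
  sigma2 <- colSums(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- coefs["group", ]
  tval <- beta / se
  p_raw <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)

  ctrl_sd <- apply(logx[g == 0L, , drop = FALSE], 2, stats::sd)
  effect <- ifelse(ctrl_sd > 0, beta / ctrl_sd, 0)

  const <- apply(logx, 2, stats::sd) == 0
  p_raw[const] <- 1
  effect[const] <- 0
  beta[const] <- 0

  p_adj <- stats::p.adjust(p_raw, method = "BH")
  passed <- p_adj < cfg$alpha_adj & abs(effect) >= cfg$effect_floor

  res <- data.frame(
    variable = colnames(logx), beta_group = unname(beta),
    effect_sd = unname(effect), p_raw = unname(p_raw), p_adj = unname(p_adj),
    passed_univariate = unname(passed), kept_after_prune = NA,
    pruned_by = NA_character_, stringsAsFactors = FALSE)
  class(res) <- c("selection_result", "data.frame")
  res
}

#' Correlation pruning of the selected panel
#'
#' Among variables that passed the univariate stage, keeps greedily by
#' descending absolute effect size (ties broken alphabetically): the top
#' candidate is kept, and any remaining candidate whose absolute Pearson
#' correlation with an already-kept variable exceeds `prune_r` is dropped,
#' recording which variable pruned it. Correlations are computed on the
#' pooled (cases + controls) log-scale data.
#'
#' @param results `selection_result` from [univariate_screen()]
#' @param logx the log matrix the screen was computed on
#' @param cfg a [selection_config()]
#' @return the `selection_result` with `kept_after_prune` and `pruned_by`
#'   finalized
#' @export
correlation_prune <- function(results, logx, cfg = selection_config()) {
  logx <- as.matrix(logx)
  cand <- results$variable[results$passed_univariate]
  results$kept_after_prune <- FALSE
  if (length(cand) == 0) return(results)
  eff <- abs(results$effect_sd[match(cand, results$variable)])
  ord <- order(-eff, cand)
  cand <- cand[ord]
  cmat <- if (length(cand) > 1) {
    suppressWarnings(stats::cor(logx[, cand, drop = FALSE]))
  } else matrix(1, 1, 1, dimnames = list(cand, cand))
  kept <- character(0)
  for (v in cand) {
    i <- match(v, results$variable)
    if (length(kept) == 0) {
      results$kept_after_prune[i] <- TRUE
      kept <- v
      next
    }
    r <- abs(cmat[v, kept])
    if (any(r > cfg$prune_r, na.rm = TRUE)) {
      results$kept_after_prune[i] <- FALSE
      results$pruned_by[i] <- kept[which.max(r)]
    } else {
      results$kept_after_prune[i] <- TRUE
      kept <- c(kept, v)
    }
  }
  results
}

#' Full selection cascade
#'
#' Convenience wrapper: [univariate_screen()] followed by
#' [correlation_prune()].
#'
#' @inheritParams univariate_screen
#' @return finalized `selection_result`
#' @export
screen_panel <- function(logx, group, covariates = NULL,
                         cfg = selection_config()) {
  res <- univariate_screen(logx, group, covariates, cfg)
  correlation_prune(res, logx, cfg)
}

#' Kept variables of a selection result
#' @param results `selection_result`
#' @return character vector of kept variable names
#' @export
kept_variables <- function(results) {
  results$variable[results$kept_after_prune %in% TRUE]
}
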