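# Phenoreversion quantification: the D distance statistic, per-subject
# recovery-day estimation from linear t_pred trajectories, recovered-fraction
# time courses, and age/severity GEV sub-models.

#' Recovery analysis configuration
#'
#' @param min_followup_days minimum days since disease onset of the latest
#'   follow-up for a subject to be eligible (default 14)
#' @param min_samples minimum samples per subject fit; 2 = acute plus one
#'   follow-up; 3 reproduces a stricter three-or-more-samples eligibility
#' @param truncate_after_recovery use only samples whose score is still above
#'   `hc_mean + truncate_margin`; samples collected after phenoreversion sit
#'   on a flat segment of the trajectory and bias the linear crossing
#'   estimate toward later days
#' @param truncate_margin score margin (same units as `t_pred`) above the
#'   healthy mean below which a sample counts as already recovered for the
#'   truncation rule
#' @param age_split age threshold (years) for subgroup models (default 65)
#' @return object of class `recovery_config`
#' @export
recovery_config <- function(min_followup_days = 14, min_samples = 2,
                            truncate_after_recovery = FALSE,
                            truncate_margin = 0, age_split = 65) {
  if (min_followup_days < 0) stop_config("min_followup_days", "must be >= 0")
  if (min_samples < 2) stop_config("min_samples", "must be >= 2")
  if (truncate_margin < 0) stop_config("truncate_margin", "must be >= 0")
  if (age_split <= 0) stop_config("age_split", "must be > 0")
  structure(list(min_followup_days = min_followup_days,
                 min_samples = as.integer(min_samples),
                 truncate_after_recovery = truncate_after_recovery,
                 truncate_margin = truncate_margin,
                 age_split = age_split),
            class = "recovery_config")
}

#' Distance to the healthy-control metabotype
#'
#' `D = t_pred - cutoff + k` with `k = cutoff - hc_mean`, i.e.
#' `D = t_pred - hc_mean`: the distance vanishes exactly at the mean
#' healthy-control score. A sample counts as recovered when its score falls
#' on the healthy side of the Youden cutoff (`t_pred <= cutoff`,
#' equivalently `D <= k`).
#'
#' @param scores data.frame with `sample_id`, `t_pred` and optionally `day`
#' @param model an `opls_model` whose `cutoff_tpred` has been set (see
#'   [roc_auc()] / [youden_cutoff()])
#' @return data.frame (`sample_id`, `day` if present, `d_value`, `k`,
#'   `recovered`)
#' @export
distance_to_recovery <- function(scores, model) {
  if (is.na(model$cutoff_tpred)) {
    stop("model has no cutoff_tpred; run the ROC evaluation first")
  }
  k <- model$cutoff_tpred - model$hc_mean_tpred
  out <- data.frame(sample_id = scores$sample_id,
                    d_value = scores$t_pred - model$hc_mean_tpred,
                    k = k,
                    recovered = scores$t_pred <= model$cutoff_tpred,
                    stringsAsFactors = FALSE)
  if ("day" %in% names(scores)) out <- cbind(out, day = scores$day)
  out
}

#' Per-subject recovery-day estimation
#'
#' For each subject with an acute (day 0) sample and at least one follow-up
#' at `min_followup_days` or later, fits ordinary least squares
#' `t_pred ~ day` and extrapolates the day at which the line reaches the
#' mean healthy-control score: `recovery_days = (hc_mean - intercept) /
#' slope`. The estimate is valid only for decreasing trajectories with a
#' positive finite crossing; rising trajectories are flagged
#' `"non-recovering trajectory"`, ineligible subjects `"eligibility"`.
#'
#' @param scores data.frame with `subject_id`, `day`, `t_pred`
#' @param hc_mean mean healthy-control predictive score (the recovery target)
#' @param cfg a [recovery_config()]
#' @return data.frame, one row per subject: `subject_id`, `slope`,
#'   `intercept`, `recovery_days`, `n_samples`, `valid`, `exclusion_reason`
#' @export
estimate_recovery_days <- function(scores, hc_mean, cfg = recovery_config()) {
  stopifnot(all(c("subject_id", "day", "t_pred") %in% names(scores)))
  subjects <- unique(scores$subject_id)
  res <- lapply(subjects, function(s) {
    d <- scores[scores$subject_id == s & is.finite(scores$day), ]
    d <- d[order(d$day), ]
    row <- data.frame(subject_id = s, slope = NA_real_, intercept = NA_real_,
                      recovery_days = NA_real_, n_samples = nrow(d),
                      valid = FALSE, exclusion_reason = NA_character_,
                      stringsAsFactors = FALSE)
    eligible <- any(d$day == 0) &&
      any(d$day >= cfg$min_followup_days) &&
      nrow(d) >= cfg$min_samples
    if (!eligible) {
      row$exclusion_reason <- "eligibility"
      return(row)
    }
    if (cfg$truncate_after_recovery) {
      d <- d[d$t_pred > hc_mean + cfg$truncate_margin, , drop = FALSE]
      row$n_samples <- nrow(d)
      if (nrow(d) < 2 || !any(d$day == 0) ||
          !any(d$day >= cfg$min_followup_days)) {
        row$exclusion_reason <- "eligibility"
        return(row)
      }
    }
    fit <- stats::lm.fit(cbind(1, d$day), d$t_pred)
    row$intercept <- fit$coefficients[1]
    row$slope <- fit$coefficients[2]
    row$recovery_days <- (hc_mean - row$intercept) / row$slope
    if (is.finite(row$slope) && row$slope < 0 &&
        is.finite(row$recovery_days) && row$recovery_days > 0) {
      row$valid <- TRUE
    } else {
      row$exclusion_reason <- "non-recovering trajectory"
    }
    row
  })
  do.call(rbind, res)
}

#' Fraction of recovered samples per day bin
#'
#' @param d_stats output of [distance_to_recovery()] with a `day` column
#' @param bins list of `c(lo, hi]` day intervals (defaults to the cohort
#'   sampling bins: (0,7], (7,14], (14,30], (30,60], >60)
#' @return data.frame (`bin`, `lo`, `hi`, `n`, `fraction`); bins without
#'   samples are absent
#' @export
recovered_fraction <- function(d_stats,
                               bins = list(c(0, 7), c(7, 14), c(14, 30),
                                           c(30, 60), c(60, Inf))) {
  stopifnot("day" %in% names(d_stats))
  rows <- lapply(bins, function(b) {
    inb <- d_stats$day > b[1] & d_stats$day <= b[2]
    if (!any(inb, na.rm = TRUE)) return(NULL)
    data.frame(bin = sprintf("(%g,%g]", b[1], b[2]), lo = b[1], hi = b[2],
               n = sum(inb, na.rm = TRUE),
               fraction = mean(d_stats$recovered[which(inb)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bin = character(0), lo = numeric(0), hi = numeric(0),
                      n = integer(0), fraction = numeric(0))
  }
  out
}

#' GEV sub-models by age class or clinical severity
#'
#' Splits valid recovery-day estimates by `age >= age_split` or by severity
#' class and fits an independent GEV to each group with at least 10
#' estimates; undersized groups are skipped with a warning.
#'
#' @param estimates output of [estimate_recovery_days()]
#' @param metadata data.frame with `subject_id` and the grouping column
#'   (`age` or `severity`)
#' @param grouping `"age"` or `"severity"`
#' @param cfg a [recovery_config()]
#' @return named list of `gev_fit` objects with attribute
#'   `"group_sizes"`
#' @export
subgroup_models <- function(estimates, metadata,
                            grouping = c("age", "severity"),
                            cfg = recovery_config()) {
  grouping <- match.arg(grouping)
  est <- estimates[estimates$valid, , drop = FALSE]
  meta <- metadata[!duplicated(metadata$subject_id), , drop = FALSE]
  est <- merge(est, meta[, c("subject_id", grouping)], by = "subject_id")
  grp <- if (grouping == "age") {
    ifelse(est$age >= cfg$age_split,
           sprintf(">=%g", cfg$age_split), sprintf("<%g", cfg$age_split))
  } else {
    est$severity
  }
  fits <- list()
  sizes <- integer(0)
  for (g in sort(unique(grp))) {
    xs <- est$recovery_days[grp == g]
    sizes[g] <- length(xs)
    if (length(xs) < 10) {
      warning(sprintf("group '%s' has %d estimates (<10); skipped", g,
                      length(xs)))
      next
    }
    fits[[g]] <- fit_gev(xs)
  }
  attr(fits, "group_sizes") <- sizes
  fits
}
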