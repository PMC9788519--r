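# Cytokine/chemokine analysis: group comparison by log2 fold change and
# Mann-Whitney test, per-marker linear decay from day 8, and the correlation
# between inflammatory and metabolic recovery times.

#' Two-sided Mann-Whitney test
#'
#' For small groups (both sizes <= `exact_max`) the p-value is exact under
#' the permutation null, handling arbitrary tie patterns: the distribution
#' of the rank sum over all subsets is computed by dynamic programming on
#' the (doubled, hence integer) midranks, and the two-sided p is the
#' probability of a rank sum at least as far from its mean as observed.
#' Larger groups use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples (x = case group)
#' @param exact_max exact-enumeration size limit per group (default 20)
#' @return list with `statistic` (U of `x`), `p_value`, `method`
#' @export
mw_test <- function(x, y, exact_max = 20) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  nn <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    # f[k+1, s+1] = number of size-k subsets of the doubled midranks with sum s
    f <- matrix(0, n1 + 1L, tot + 1L)
    f[1L, 1L] <- 1
    for (item in r2) {
      kmax <- min(n1, nn)  # rows to update, top-down to avoid reuse
      for (k in seq.int(min(n1, kmax), 1L)) {
        nzero <- which(f[k, ] > 0)
        if (length(nzero) > 0) {
          tgt <- nzero + item
          f[k + 1L, tgt] <- f[k + 1L, tgt] + f[k, nzero]
        }
      }
    }
    counts <- f[n1 + 1L, ]
    total <- sum(counts)
    s_vals <- seq_along(counts) - 1L
    mean_w2 <- n1 * tot / nn
    dev <- abs(s_vals - mean_w2)
    obs_dev <- abs(2 * w - mean_w2)
    p <- sum(counts[dev >= obs_dev - 1e-9]) / total
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    cc <- sign(u - mu) * 0.5
    z <- if (sigma2 > 0) (u - mu - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Cytokine fold-change analysis
#'
#' Per marker: the binary logarithm of the case-group mean divided by the
#' control-group mean, and a two-sided Mann-Whitney test of the group
#' difference at the 0.05 level (exact for small groups, normal
#' approximation with tie correction otherwise).
#'
#' @param panel long cytokine table (`sample_id`, `marker`, `level`)
#' @param groups data.frame (`sample_id`, `group`) whose `group` has two
#'   levels, the first being the control group
#' @param alpha significance level (default 0.05)
#' @return data.frame: `marker`, `log2_fc`, `p_mw`, `significant`, `n_case`,
#'   `n_control`; a zero control mean gives `log2_fc = NA`
#' @export
fold_change_analysis <- function(panel, groups, alpha = 0.05) {
  stopifnot(all(c("sample_id", "marker", "level") %in% names(panel)))
  g <- as.factor(groups$group)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  lev <- levels(g)
  panel$group <- g[match(panel$sample_id, groups$sample_id)]
  panel <- panel[!is.na(panel$group), ]
  rows <- lapply(sort(unique(panel$marker)), function(mk) {
    ctrl <- panel$level[panel$marker == mk & panel$group == lev[1]]
    case <- panel$level[panel$marker == mk & panel$group == lev[2]]
    if (length(ctrl) < 3 || length(case) < 3) {
      stop(sprintf("marker '%s': need at least 3 samples per group", mk))
    }
    fc <- if (mean(ctrl) > 0) log2(mean(case) / mean(ctrl)) else NA_real_
    mw <- mw_test(case, ctrl)
    data.frame(marker = mk, log2_fc = fc, p_mw = mw$p_value,
               significant = mw$p_value < alpha,
               n_case = length(case), n_control = length(ctrl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Linear decay of an inflammation marker from day 8
#'
#' Ordinary least squares on observations at `min_day` or later; the
#' half-recovery day is where the fitted line crosses the midpoint between
#' the acute mean and the healthy mean. Valid estimates have a negative
#' slope and a half-recovery day beyond `min_day`.
#'
#' @param series data.frame (`day`, `level`) for one subject (or pooled)
#' @param healthy_mean healthy-population mean level of the marker
#' @param acute_mean acute-phase mean level of the marker
#' @param min_day first day of the decay window (default 8)
#' @return one-row data.frame: `slope`, `intercept`, `half_recovery_day`,
#'   `n_obs`, `valid`
#' @export
marker_decay <- function(series, healthy_mean, acute_mean, min_day = 8) {
  d <- series[is.finite(series$day) & series$day >= min_day, , drop = FALSE]
  out <- data.frame(slope = NA_real_, intercept = NA_real_,
                    half_recovery_day = NA_real_, n_obs = nrow(d),
                    valid = FALSE)
  if (nrow(d) < 2 || length(unique(d$day)) < 2) return(out)
  fit <- stats::lm.fit(cbind(1, d$day), d$level)
  out$intercept <- fit$coefficients[1]
  out$slope <- fit$coefficients[2]
  mid <- (acute_mean + healthy_mean) / 2
  out$half_recovery_day <- (mid - out$intercept) / out$slope
  out$valid <- is.finite(out$slope) && out$slope < 0 &&
    is.finite(out$half_recovery_day) && out$half_recovery_day > min_day
  out
}

#' Per-subject decay estimates for one marker
#'
#' @param panel long cytokine table with `subject_id` and `day` columns
#' @param marker marker name
#' @param healthy_mean healthy-population mean level
#' @param acute_mean acute-phase mean level; defaults to the mean level over
#'   all samples at `day <= min_day`
#' @param min_day first day of the decay window
#' @return data.frame of [marker_decay()] rows, one per subject
#' @export
subject_marker_decays <- function(panel, marker, healthy_mean,
                                  acute_mean = NULL, min_day = 8) {
  p <- panel[panel$marker == marker & is.finite(panel$day), , drop = FALSE]
  if (nrow(p) == 0) stop(sprintf("no rows for marker '%s'", marker))
  if (is.null(acute_mean)) {
    acute_mean <- mean(p$level[p$day <= min_day])
  }
  rows <- lapply(unique(p$subject_id), function(s) {
    est <- marker_decay(p[p$subject_id == s, c("day", "level")],
                        healthy_mean, acute_mean, min_day)
    cbind(data.frame(subject_id = s, stringsAsFactors = FALSE), est)
  })
  do.call(rbind, rows)
}

#' Correlation between inflammatory and metabolic recovery
#'
#' Pearson correlation between a marker's per-subject decay quantity
#' (half-recovery day by default, or the decay slope) and the metabolic
#' recovery-day estimate, with the least-squares line and a pointwise
#' confidence band for reporting.
#'
#' @param decays output of [subject_marker_decays()]
#' @param estimates output of [estimate_recovery_days()]
#' @param measure `"half_recovery_day"` or `"slope"`
#' @param conf_level confidence level of the band
#' @return list: `r`, `p_value`, `n`, `coefficients` (intercept, slope of
#'   the fitted line), `band` (grid data.frame with fit/lwr/upr)
#' @export
correlate_recovery <- function(decays, estimates,
                               measure = c("half_recovery_day", "slope"),
                               conf_level = 0.95) {
  measure <- match.arg(measure)
  d <- merge(decays[decays$valid, c("subject_id", measure)],
             estimates[estimates$valid, c("subject_id", "recovery_days")],
             by = "subject_id")
  if (nrow(d) < 5) stop("fewer than 5 subjects with both quantities valid")
  xv <- d[[measure]]
  yv <- d$recovery_days
  ct <- stats::cor.test(xv, yv, method = "pearson")
  fit <- stats::lm(yv ~ xv)
  grid <- data.frame(xv = seq(min(xv), max(xv), length.out = 50))
  band <- cbind(grid, stats::predict(fit, grid, interval = "confidence",
                                     level = conf_level))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d),
       coefficients = stats::coef(fit), band = band)
}
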