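# ROC analysis on predictive scores, Youden-optimal cutoff, and permutation
# significance of AUC / sensitivity / specificity.

#' ROC curve and AUC on a score vector
#'
#' The AUC uses the rank (Mann-Whitney) formulation with half credit for
#' tied scores. Curve thresholds sit at midpoints between adjacent distinct
#' observed scores, plus one threshold below and one above all scores; a
#' sample is called positive when its score exceeds the threshold. The
#' Youden-optimal cutoff maximizes sensitivity + specificity - 1; among
#' tied maximizers the cutoff nearest the midpoint of the two class mean
#' scores is chosen (lowest such threshold on a residual tie).
#'
#' @param scores numeric score vector (higher = more case-like)
#' @param labels binary labels (case = 1/TRUE/second factor level)
#' @return object of class `roc_curve`: data.frame `curve` (threshold,
#'   sensitivity, specificity, youden_j), `auc`, `youden_cutoff`, `youden_j`,
#'   `class_means`
#' @export
roc_auc <- function(scores, labels) {
  yb <- if (is.factor(labels)) as.integer(labels) - 1L else
    as.integer(as.logical(labels) | labels > 0)
  n1 <- sum(yb == 1L)
  n0 <- sum(yb == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties get half credit
  auc <- (sum(r[yb == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  s <- sort(unique(scores))
  thr <- if (length(s) > 1) {
    c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  } else {
    c(s - 1, s + 1)
  }
  sens <- vapply(thr, function(t) mean(scores[yb == 1L] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[yb == 0L] <= t), numeric(1))
  j <- sens + spec - 1

  class_means <- c(control = mean(scores[yb == 0L]),
                   case = mean(scores[yb == 1L]))
  jmax <- max(j)
  ties <- which(j >= jmax - 1e-12)
  mid <- mean(class_means)
  best <- ties[order(abs(thr[ties] - mid), thr[ties])][1L]

  out <- list(curve = data.frame(threshold = thr, sensitivity = sens,
                                 specificity = spec, youden_j = j),
              auc = auc,
              youden_cutoff = thr[best],
              youden_j = j[best],
              sensitivity = sens[best],
              specificity = spec[best],
              class_means = class_means)
  class(out) <- "roc_curve"
  out
}

#' Youden-optimal cutoff of a ROC curve
#'
#' @param roc a `roc_curve` from [roc_auc()]
#' @return the score cutoff maximizing Youden's J
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  roc$youden_cutoff
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.4f; Youden cutoff %.4f (J %.3f, sens %.3f, spec %.3f)\n",
    x$auc, x$youden_cutoff, x$youden_j, x$sensitivity, x$specificity))
  invisible(x)
}

#' Permutation significance of cross-validated performance metrics
#'
#' The observed metric comes from repeated stratified cross-validation of
#' the O-PLS-DA model followed by ROC analysis of the aggregated
#' out-of-fold scores. Each permutation run shuffles the class labels,
#' reruns the whole cross-validation and records the same metric. The
#' p-value uses the add-one rule `(1 + #{permuted >= observed}) /
#' (n_runs + 1)`, so it can never be exactly zero.
#'
#' @param x numeric matrix of log-transformed values
#' @param y binary labels
#' @param metric one of `"auc"`, `"sensitivity"`, `"specificity"`
#' @param n_runs number of permutation runs (default 100)
#' @param seed RNG seed
#' @param folds,repeats cross-validation settings (see [cross_validate()])
#' @return object of class `permutation_result`: `metric`, `observed`,
#'   `permuted` (vector of length `n_runs`), `p_value`, `n_runs`
#' @export
permutation_test <- function(x, y, metric = c("auc", "sensitivity",
                                              "specificity"),
                             n_runs = 100, seed = 1, folds = 5, repeats = 10) {
  metric <- match.arg(metric)
  if (n_runs < 1) stop("n_runs must be >= 1")
  x <- as.matrix(x)
  yb <- if (is.factor(y)) as.integer(y) - 1L else
    as.integer(as.logical(y) | y > 0)

  eval_metric <- function(labels, cv_seed) {
    cv <- cross_validate(x, labels, folds = folds, repeats = repeats,
                         seed = cv_seed)
    roc <- roc_auc(cv$aggregate, labels)
    switch(metric, auc = roc$auc, sensitivity = roc$sensitivity,
           specificity = roc$specificity)
  }

  observed <- eval_metric(yb, derive_seed(seed, "observed"))
  permuted <- with_preserved_seed(seed, {
    vapply(seq_len(n_runs), function(r) {
      yp <- sample(yb)
      eval_metric(yp, derive_seed(seed, paste0("perm", r)))
    }, numeric(1))
  })
  out <- list(metric = metric, observed = observed, permuted = permuted,
              p_value = (1 + sum(permuted >= observed)) / (n_runs + 1),
              n_runs = n_runs)
  class(out) <- "permutation_result"
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed %.4f, p = %.4f (%d runs)\n",
              x$metric, x$observed, x$p_value, x$n_runs))
  invisible(x)
}
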