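# Orthogonal partial least squares discriminant analysis with a single
# predictive and a single orthogonal component (single binary response).
#
# Algorithm (orthogonal projections to latent structures, single y):
#   1. candidate predictive weight  w  = X'y / ||X'y||
#   2. loading of the X scores      p  = X't / t't,  t = Xw
#   3. orthogonal weight            wo = (p - (w'p) w) / ||...||
#   4. orthogonal scores/loading    to = X wo,  po = X'to / to'to
#   5. filtered matrix              Xf = X - to po'
#   6. final predictive component from Xf (weight, scores, loading) and the
#      regression coefficient b of y on t_pred.
# The model is oriented so the case class has the larger mean t_pred.

#' Fit a two-component O-PLS-DA discrimination model
#'
#' One predictive and one orthogonal component fitted on a standardized
#' matrix and a binary class label. The predictive weight has unit norm and
#' is orthogonal to the unit-norm orthogonal weight; predictive and
#' orthogonal score vectors are exactly orthogonal by construction.
#'
#' @param z standardized numeric matrix (samples x variables); columns
#'   centered and scaled, e.g. from [log_standardize()]
#' @param y binary labels (logical, 0/1, or two-level factor whose second
#'   level is the case class)
#' @param orthogonal fit the orthogonal component (default). With
#'   `orthogonal = FALSE` the model degenerates to single-component PLS1:
#'   no orthogonal filtering is applied.
#' @param scaling optional `scaling_stats` to store for later projection
#' @return object of class `opls_model` with elements `w_pred`, `p_pred`,
#'   `w_orth`, `p_orth`, `b`, `scores` (training t_pred/t_orth),
#'   `class_means_tpred`, `hc_mean_tpred`, `cutoff_tpred` (NA until set),
#'   `orientation`, `variables`, `scaling`
#' @export
fit_oplsda <- function(z, y, orthogonal = TRUE, scaling = NULL) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("z must be finite (no missing values)")
  yb <- if (is.factor(y)) as.integer(y) - 1L else as.integer(as.logical(y) | y > 0)
  if (length(unique(yb)) != 2L) stop("y must contain both classes")
  if (all(apply(z, 2, stats::sd) == 0)) stop("z has no variance")
  n <- nrow(z)
  p <- ncol(z)
  if (is.null(colnames(z))) colnames(z) <- paste0("V", seq_len(p))
  yc <- yb - mean(yb)

  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate weight vector")
    v / nv
  }

  w <- unit(drop(crossprod(z, yc)))
  t1 <- drop(z %*% w)
  pl <- drop(crossprod(z, t1)) / sum(t1^2)

  if (orthogonal && p >= 2) {
    wo_raw <- pl - drop(crossprod(w, pl)) * w
    if (sqrt(sum(wo_raw^2)) < 1e-10 * sqrt(sum(pl^2)) ||
        sqrt(sum(wo_raw^2)) < 1e-12) {
      # no structured orthogonal variation in the loading: take any unit
      # direction orthogonal to w so the model shape is preserved
      basis <- diag(p)[, which.min(abs(w)), drop = TRUE]
      wo_raw <- basis - drop(crossprod(w, basis)) * w
    }
    wo <- unit(wo_raw)
    to <- drop(z %*% wo)
    po <- drop(crossprod(z, to)) / sum(to^2)
    zf <- z - tcrossprod(to, po)
  } else {
    wo <- numeric(p)
    to <- numeric(n)
    po <- numeric(p)
    zf <- z
  }

  w2 <- unit(drop(crossprod(zf, yc)))
  t_pred <- drop(zf %*% w2)
  p_pred <- drop(crossprod(zf, t_pred)) / sum(t_pred^2)
  b <- sum(yc * t_pred) / sum(t_pred^2)

  orientation <- 1
  if (mean(t_pred[yb == 1L]) < mean(t_pred[yb == 0L])) {
    orientation <- -1
    w2 <- -w2; p_pred <- -p_pred; t_pred <- -t_pred; b <- -b
  }

  model <- list(
    w_pred = stats::setNames(w2, colnames(z)),
    p_pred = stats::setNames(p_pred, colnames(z)),
    w_orth = stats::setNames(wo, colnames(z)),
    p_orth = stats::setNames(po, colnames(z)),
    b = b,
    orthogonal = orthogonal && p >= 2,
    scores = data.frame(sample_id = rownames(z) %||%
                          as.character(seq_len(n)),
                        t_pred = t_pred, t_orth = to, y = yb,
                        stringsAsFactors = FALSE),
    class_means_tpred = c(control = mean(t_pred[yb == 0L]),
                          case = mean(t_pred[yb == 1L])),
    hc_mean_tpred = mean(t_pred[yb == 0L]),
    cutoff_tpred = NA_real_,
    orientation = orientation,
    variables = colnames(z),
    scaling = scaling)
  class(model) <- "opls_model"
  model
}

#' Project new samples onto a fitted O-PLS-DA model
#'
#' Removes the orthogonal component from each new row using the model's
#' orthogonal weight and loading, then scores the filtered row with the
#' predictive weight. Projecting the training matrix reproduces the training
#' scores.
#'
#' @param model an `opls_model`
#' @param znew matrix standardized with the model's scaling statistics;
#'   columns must match the training variables
#' @return data.frame (`sample_id`, `t_pred`, `t_orth`)
#' @export
project_scores <- function(model, znew) {
  znew <- as.matrix(znew)
  if (is.null(colnames(znew))) {
    if (ncol(znew) != length(model$variables)) {
      stop("variable mismatch: unnamed matrix of wrong width")
    }
    colnames(znew) <- model$variables
  }
  missing <- setdiff(model$variables, colnames(znew))
  extra <- setdiff(colnames(znew), model$variables)
  if (length(missing) > 0 || length(extra) > 0) {
    stop(sprintf("variable mismatch: missing [%s]; extra [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")))
  }
  znew <- znew[, model$variables, drop = FALSE]
  t_orth <- drop(znew %*% model$w_orth)
  zf <- znew - tcrossprod(t_orth, model$p_orth)
  t_pred <- drop(zf %*% model$w_pred)
  data.frame(sample_id = rownames(znew) %||% as.character(seq_len(nrow(znew))),
             t_pred = t_pred, t_orth = t_orth, stringsAsFactors = FALSE)
}

#' @export
#' @rdname project_scores
#' @param object,... method arguments (`predict` interface)
#' @param newdata standardized matrix to project
predict.opls_model <- function(object, newdata, ...) {
  project_scores(object, newdata)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "O-PLS-DA model: %d variables, 1 predictive + %d orthogonal component\n",
    length(x$variables), as.integer(x$orthogonal)))
  cat(sprintf("  class means t_pred: control %.3f, case %.3f; cutoff %s\n",
              x$class_means_tpred[["control"]], x$class_means_tpred[["case"]],
              if (is.na(x$cutoff_tpred)) "unset" else
                sprintf("%.3f", x$cutoff_tpred)))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin into folds.
.stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the O-PLS-DA model
#'
#' Five-fold (by default) stratified cross-validation repeated 10 times.
#' Standardization statistics and the model are computed inside each
#' training split only; held-out rows are standardized with the training
#' statistics and projected. The per-sample aggregate score is the mean
#' out-of-fold `t_pred` across repeats.
#'
#' @param x numeric matrix of log-transformed (unstandardized) values
#' @param y binary labels
#' @param folds number of folds (default 5)
#' @param repeats number of repeats (default 10)
#' @param seed RNG seed controlling fold assignment
#' @return list with `oof` (samples x repeats matrix of out-of-fold t_pred),
#'   `aggregate` (per-sample mean), `y`, `fold` (samples x repeats fold
#'   assignments), `folds`, `repeats`, `seed`
#' @export
cross_validate <- function(x, y, folds = 5, repeats = 10, seed = 1) {
  x <- as.matrix(x)
  yb <- if (is.factor(y)) as.integer(y) - 1L else as.integer(as.logical(y) | y > 0)
  if (min(table(yb)) < folds) stop("each class must have at least `folds` samples")
  n <- nrow(x)
  oof <- matrix(NA_real_, n, repeats)
  fold_mat <- matrix(NA_integer_, n, repeats)
  with_preserved_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- .stratified_folds(yb, folds)
      fold_mat[, r] <- fold
      for (k in seq_len(folds)) {
        tr <- fold != k
        mu <- colMeans(x[tr, , drop = FALSE])
        sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
        keep <- sd_ > 0
        ztr <- sweep(sweep(x[tr, keep, drop = FALSE], 2, mu[keep], "-"),
                     2, sd_[keep], "/")
        zte <- sweep(sweep(x[!tr, keep, drop = FALSE], 2, mu[keep], "-"),
                     2, sd_[keep], "/")
        m <- fit_oplsda(ztr, yb[tr])
        oof[!tr, r] <- project_scores(m, zte)$t_pred
      }
    }
  })
  list(oof = oof, aggregate = rowMeans(oof), y = yb, fold = fold_mat,
       folds = folds, repeats = repeats, seed = seed)
}
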