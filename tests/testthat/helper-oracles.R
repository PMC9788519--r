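# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately use naive algorithms (pair counting,
# enumeration, union-find) rather than the code paths they verify.

# AUC by explicit case-control pair counting with half credit for ties.
bf_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cs) * length(ct))
}

# Benjamini-Hochberg from the definition: sort p ascending, q_i = p_i * m / i,
# enforce monotonicity by a cumulative minimum from the largest rank.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Naive DBSCAN reference: core points from the O(n^2) distance matrix,
# clusters as connected components of the core-core eps-graph (union-find),
# border points attached to any reachable core cluster, rest noise.
# Returns list(noise = logical, core = logical, core_comp = integer labels
# over core points).
bf_dbscan <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts,
                 logical(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(core)) for (j in which(core)) {
    if (i < j && d[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- rep(NA_integer_, n)
  comp[core] <- vapply(which(core), find, integer(1))
  border <- !core & vapply(seq_len(n), function(i) {
    any(d[i, core] <= eps)
  }, logical(1))
  list(noise = !core & !border, core = core, core_comp = comp)
}

# Exact two-sided Mann-Whitney p by full enumeration of all subsets:
# probability of a rank sum at least as far from its mean as observed.
bf_mw_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  nn <- length(r)
  w_obs <- sum(r[seq_len(n1)])
  mean_w <- n1 * sum(r) / nn
  sets <- utils::combn(nn, n1)
  w_all <- apply(sets, 2, function(s) sum(r[s]))
  mean(abs(w_all - mean_w) >= abs(w_obs - mean_w) - 1e-9)
}

# Single-component PLS1 scores (NIPALS first component).
bf_pls1_scores <- function(x, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(x, yc))
  w <- w / sqrt(sum(w^2))
  drop(x %*% w)
}

# Mutually orthogonal, exactly mean-centered unit vectors (for building
# matrices with exact sample correlations).
bf_orthobasis <- function(n, k) {
  stopifnot(k < n)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- rnorm(n)
    v <- v - mean(v)
    if (j > 1) {
      for (i in seq_len(j - 1)) v <- v - sum(v * out[, i]) * out[, i]
      v <- v - mean(v)
    }
    out[, j] <- v / sqrt(sum(v^2))
  }
  out
}

# Compact default generator for cheap tests: few variables, small panel.
small_generator <- function(n_controls = 60, n_acute = 60, seed = 1, ...) {
  generator_config(
    n_controls = n_controls, n_acute = n_acute,
    n_metabolites = 6, n_lipoproteins = 8, n_inflammation_bins = 3,
    informative_panel = data.frame(
      variable = c("Glucose", "Glutamine", "GlycA"),
      effect = c(1.2, -1.0, 0.9)),
    block_structure = data.frame(size = 8L, rho = 0.6),
    seed = seed, ...)
}
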