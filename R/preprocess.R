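# Preprocessing: day-since-disease labeling, spectral bin extraction,
# density-based sample QC, and log-standardization.

#' Spectral bin grid
#'
#' Consecutive half-open buckets `[start + w*k, start + w*(k+1))` of fixed
#' width over the ppm axis, with an excluded residual-water region that
#' contributes neither to any bin nor to the normalizing total. Named
#' inflammation bins (GlycA, GlycB, SPC) are resolved to the bin whose
#' center is nearest the nominal ppm position; center ties go to the
#' lower-ppm bin.
#'
#' @param start,end axis range in ppm
#' @param width bin width in ppm (default 0.03)
#' @param exclude excluded `[lo, hi)` region in ppm (residual water)
#' @param named_bins named nominal ppm positions
#' @return object of class `bin_grid`
#' @export
bin_grid <- function(start = 0.5, end = 9.5, width = 0.03,
                     exclude = c(4.7, 5.00),
                     named_bins = c(GlycA = 2.06, GlycB = 2.09, SPC = 3.23)) {
  if (width <= 0) stop_config("width", "must be > 0")
  if (length(exclude) == 2 && (exclude[1] < start || exclude[2] > end)) {
    stop_config("exclude", "excluded region must lie inside [start, end]")
  }
  n_bins <- floor((end - start) / width)
  lower <- start + width * (seq_len(n_bins) - 1L)
  centers <- lower + width / 2
  excluded <- centers >= exclude[1] & centers < exclude[2]
  g <- list(start = start, end = end, width = width, exclude = exclude,
            n_bins = n_bins, lower = lower, centers = centers,
            excluded_bin = excluded, named_bins = named_bins)
  class(g) <- "bin_grid"
  g
}

#' Integrate a spectrum into normalized buckets
#'
#' Each bucket value is the summed intensity of its internal spectral points,
#' normalized by the total intensity of all non-excluded points, so the
#' values are invariant to global intensity scaling and sum to 1. Points in
#' the excluded (residual water) region contribute to neither the buckets
#' nor the total.
#'
#' @param spectrum data.frame (`ppm`, `intensity`), strictly monotone axis
#' @param grid a [bin_grid()]
#' @return named numeric vector of bucket values (names `bin_<center>`)
#' @export
bin_spectrum <- function(spectrum, grid = bin_grid()) {
  stopifnot(is.data.frame(spectrum), all(c("ppm", "intensity") %in%
                                           names(spectrum)))
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  if (any(diff(ppm) <= 0)) stop("ppm axis must be strictly increasing")
  if (any(y < 0)) stop("intensities must be non-negative")
  in_range <- ppm >= grid$start & ppm < grid$start + grid$n_bins * grid$width
  idx <- rep(NA_integer_, length(ppm))
  idx[in_range] <- floor((ppm[in_range] - grid$start) / grid$width) + 1L
  # a point contributes only if neither its ppm nor its bucket is excluded,
  # so the bucket values always sum to exactly 1 over the kept mass
  keep <- in_range &
    !(ppm >= grid$exclude[1] & ppm < grid$exclude[2]) &
    !grid$excluded_bin[ifelse(in_range, idx, 1L)]
  total <- sum(y[keep])
  if (total <= 0) stop("all-zero spectrum: normalization undefined")
  sums <- vapply(seq_len(grid$n_bins),
                 function(b) sum(y[keep & idx == b]), numeric(1))
  out <- sums / total
  names(out) <- sprintf("bin_%.4g", grid$centers)
  out
}

#' Extract the GlycA, GlycB and SPC bucket values
#'
#' Returns the buckets whose centers are nearest to the nominal inflammation
#' marker positions of the grid (2.06, 2.09 and 3.23 ppm by default). On a
#' 0.03-ppm grid anchored at 0.5 ppm these positions fall exactly between
#' two bucket centers; the tie resolves to the bucket whose interval
#' contains the nominal position, so a signal centered there lands in its
#' named bucket.
#'
#' @param bins bucket vector from [bin_spectrum()] on the same grid
#' @param grid the [bin_grid()] used to compute `bins`
#' @return named numeric vector, one value per named bin
#' @export
extract_glyc_spc <- function(bins, grid = bin_grid()) {
  if (length(bins) != grid$n_bins) {
    stop("bins were not computed on this grid")
  }
  pick <- vapply(grid$named_bins, function(target) {
    d <- abs(grid$centers - target)
    ties <- which(d <= min(d) + 1e-12)
    containing <- as.integer(floor((target - grid$start) / grid$width)) + 1L
    if (containing %in% ties) containing else ties[1L]
  }, integer(1))
  if (anyDuplicated(pick)) stop("named bins resolve to non-distinct buckets")
  stats::setNames(bins[pick], names(grid$named_bins))
}

#' Assign days since disease onset
#'
#' For non-hospitalized recovered (NHR) rows the day is the difference
#' between collection and self-reported infection dates. For hospitalized
#' rows (cohorts AC/RE), the earliest sample of a subject becomes day 0 and
#' is flagged acute if it was collected up to 7 days after hospitalization;
#' later samples are counted from it. If no sample qualifies as day 0, days
#' are counted from the hospitalization date and no row is flagged acute.
#' Healthy-control rows get `day = NA`. Rows lacking the date their cohort
#' requires are excluded and reported in the `"excluded"` attribute.
#'
#' @param samples sample table
#' @return sample table with `day` (integer) and `acute` (logical) columns;
#'   excluded rows (with reasons) in attribute `"excluded"`
#' @export
assign_days_since_covid <- function(samples) {
  n <- nrow(samples)
  day <- rep(NA_integer_, n)
  acute <- rep(FALSE, n)
  drop <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  is_nhr <- samples$cohort == "NHR"
  is_hosp <- samples$cohort %in% c("AC", "RE")

  bad <- is_nhr & (is.na(samples$covid_report_date) |
                     is.na(samples$collection_date))
  drop[bad] <- TRUE
  reason[bad] <- "missing covid report or collection date"
  ok <- is_nhr & !bad
  day[ok] <- as.integer(samples$collection_date[ok] -
                          samples$covid_report_date[ok])

  bad <- is_hosp & (is.na(samples$hospitalization_date) |
                      is.na(samples$collection_date))
  drop[bad] <- TRUE
  reason[bad] <- "missing hospitalization or collection date"

  hosp_idx <- which(is_hosp & !drop)
  for (idx in split(hosp_idx, samples$subject_id[hosp_idx])) {
    coll <- samples$collection_date[idx]
    hosp <- samples$hospitalization_date[idx][1]
    first <- idx[order(coll)][1L]
    if (as.integer(samples$collection_date[first] - hosp) <= 7L) {
      day[idx] <- as.integer(coll - samples$collection_date[first])
      acute[first] <- TRUE
    } else {
      day[idx] <- as.integer(coll - hosp)
    }
  }

  out <- samples[!drop, , drop = FALSE]
  out$day <- day[!drop]
  out$acute <- acute[!drop]
  excluded <- data.frame(sample_id = samples$sample_id[drop],
                         reason = reason[drop], stringsAsFactors = FALSE)
  if (nrow(excluded) > 0) {
    message(sprintf("assign_days_since_covid: excluded %d row(s) with missing dates",
                    nrow(excluded)))
  }
  attr(out, "excluded") <- excluded
  out
}

#' QC configuration for density-based sample filtering
#'
#' @param min_pts minimum points per dense region (default 5); the count
#'   includes the point itself
#' @param eps neighborhood radius in standardized Euclidean units (default 20)
#' @param k_for_knn_plot neighbor order for the k-NN distance summary
#' @return object of class `qc_config`
#' @export
qc_config <- function(min_pts = 5, eps = 20, k_for_knn_plot = 5) {
  if (min_pts < 2) stop_config("min_pts", "must be >= 2")
  if (eps <= 0) stop_config("eps", "must be > 0")
  structure(list(min_pts = as.integer(min_pts), eps = eps,
                 k_for_knn_plot = as.integer(k_for_knn_plot)),
            class = "qc_config")
}

#' DBSCAN clustering on a numeric matrix
#'
#' Classical density-based clustering on Euclidean distance: core points have
#' at least `min_pts` neighbors (self included) within `eps`; clusters grow
#' from core points in row order; non-core points within `eps` of a core
#' point join the first cluster that reaches them (border points); the rest
#' are noise (label 0).
#'
#' @param x numeric matrix (rows = samples)
#' @param eps neighborhood radius
#' @param min_pts minimum neighborhood size, self included
#' @return integer cluster labels, 0 for noise
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nbrs[[i]]
    while (length(frontier) > 0) {
      frontier <- frontier[labels[frontier] == 0L]
      if (length(frontier) == 0) break
      labels[frontier] <- cl
      # only core points expand the cluster; border points keep the label of
      # the first cluster that reaches them
      expand <- frontier[core[frontier]]
      frontier <- if (length(expand) > 0) {
        unique(unlist(nbrs[expand], use.names = FALSE))
      } else integer(0)
    }
  }
  labels
}

#' Density-based sample quality filtering
#'
#' Standardizes all measured variables (centering and unit variance), runs
#' DBSCAN with the configured `eps` and `min_pts` on Euclidean distance and
#' discards samples left without a cluster (noise points). All cluster
#' members, of any cluster, are kept.
#'
#' @param samples sample table
#' @param qc a [qc_config()]
#' @return list with `kept` (filtered sample table), `discarded_ids`,
#'   `cluster` (labels for all input rows) and `knn_distance` (per-sample
#'   k-NN distance, a diagnostic for choosing `eps`)
#' @export
qc_filter_dbscan <- function(samples, qc = qc_config()) {
  x <- sample_matrix(samples)
  if (nrow(x) < qc$min_pts) {
    stop(sprintf("need at least min_pts = %d samples", qc$min_pts))
  }
  z <- scale(x)
  sds <- attr(z, "scaled:scale")
  if (any(sds == 0)) z[, sds == 0] <- 0
  labels <- dbscan_cluster(z, eps = qc$eps, min_pts = qc$min_pts)
  d <- as.matrix(stats::dist(z))
  knn <- apply(d, 1, function(r) sort(r)[qc$k_for_knn_plot + 1L])
  keep <- labels != 0L
  list(kept = samples[keep, , drop = FALSE],
       discarded_ids = samples$sample_id[!keep],
       cluster = labels,
       knn_distance = unname(knn))
}

#' Log-transform and standardize measured variables
#'
#' Natural-log transform followed by autoscaling (mean centering and unit
#' variance). Zeros are replaced by half the smallest positive value of the
#' variable before the log. In training mode (no `stats` given) the scaling
#' statistics are computed from the data and returned; variables constant
#' across training samples are dropped with a warning. In projection mode
#' the supplied statistics (including the zero-replacement values) are
#' applied unchanged.
#'
#' @param samples sample table or numeric matrix
#' @param stats optional `scaling_stats` from a previous training call
#' @param variables optional variable subset
#' @return list with `matrix` (standardized values) and `stats`
#'   (`scaling_stats`: variable, mean, sd, zero_fill)
#' @export
log_standardize <- function(samples, stats = NULL, variables = NULL) {
  if (is.matrix(samples) && is.numeric(samples)) {
    x <- if (!is.null(variables)) samples[, variables, drop = FALSE] else samples
  } else {
    x <- sample_matrix(samples, variables)
  }
  if (any(x < 0)) stop("values must be non-negative")

  if (is.null(stats)) {
    zero_fill <- vapply(seq_len(ncol(x)), function(j) {
      pos <- x[, j][x[, j] > 0]
      if (length(pos) == 0) 1 else min(pos) / 2
    }, numeric(1))
    for (j in seq_len(ncol(x))) {
      if (any(x[, j] == 0)) x[x[, j] == 0, j] <- zero_fill[j]
    }
    lx <- log(x)
    mu <- colMeans(lx)
    sd_ <- apply(lx, 2, stats::sd)
    const <- sd_ == 0 | !is.finite(sd_)
    if (any(const)) {
      warning(sprintf("dropping %d constant variable(s): %s", sum(const),
                      paste(colnames(x)[const], collapse = ", ")))
      lx <- lx[, !const, drop = FALSE]
      mu <- mu[!const]; sd_ <- sd_[!const]; zero_fill <- zero_fill[!const]
    }
    z <- sweep(sweep(lx, 2, mu, "-"), 2, sd_, "/")
    st <- data.frame(variable = colnames(lx), mean = mu, sd = sd_,
                     zero_fill = zero_fill, stringsAsFactors = FALSE,
                     row.names = NULL)
    class(st) <- c("scaling_stats", "data.frame")
    list(matrix = z, stats = st)
  } else {
    missing <- setdiff(stats$variable, colnames(x))
    if (length(missing) > 0) {
      stop(paste0("variables missing from input: ",
                  paste(missing, collapse = ", ")))
    }
    x <- x[, stats$variable, drop = FALSE]
    for (j in seq_len(ncol(x))) {
      if (any(x[, j] == 0)) x[x[, j] == 0, j] <- stats$zero_fill[j]
    }
    z <- sweep(sweep(log(x), 2, stats$mean, "-"), 2, stats$sd, "/")
    list(matrix = z, stats = stats)
  }
}
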