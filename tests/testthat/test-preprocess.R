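# Day labeling, spectral binning, DBSCAN sample QC, log-standardization.

test_that("bin grid partitions the axis into 300 buckets", {
  g <- bin_grid()
  expect_equal(g$n_bins, 300L)
  expect_error(bin_grid(width = 0), class = "phenorevert_config_error")
  expect_error(bin_grid(exclude = c(0.1, 5)),
               class = "phenorevert_config_error")
})

test_that("uniform spectra give equal non-excluded buckets summing to 1", {
  # grid chosen so every bucket holds exactly 10 points, none on an edge
  sp <- data.frame(ppm = seq(0.4015, 9.5995, by = 0.003), intensity = 1)
  g <- bin_grid()
  b <- bin_spectrum(sp, g)
  expect_equal(sum(b), 1, tolerance = 1e-12)
  live <- b[!g$excluded_bin]
  expect_lt(diff(range(live)) / mean(live), 1e-6)
  expect_true(all(b[g$excluded_bin] == 0))
  # scaling invariance
  sp2 <- sp; sp2$intensity <- sp2$intensity * 137.5
  expect_equal(bin_spectrum(sp2, g), b, tolerance = 1e-12)
  expect_error(bin_spectrum(data.frame(ppm = sp$ppm, intensity = 0), g),
               "all-zero")
})

test_that("a peak at 2.06 ppm lands in the GlycA bucket", {
  g <- bin_grid()
  sp <- generate_spectrum(data.frame(center = 2.06, width = 0.008, area = 1))
  b <- bin_spectrum(sp, g)
  glyc <- extract_glyc_spc(b, g)
  expect_equal(unname(glyc["GlycA"]), max(b))   # argmax bucket is GlycA
  expect_gt(glyc["GlycA"], glyc["SPC"])
  # SPC peak dominates the SPC bucket
  sp2 <- generate_spectrum(data.frame(center = 3.23, width = 0.008, area = 1))
  g2 <- extract_glyc_spc(bin_spectrum(sp2, g), g)
  expect_gt(g2["SPC"], g2["GlycA"])
  expect_gt(g2["SPC"], g2["GlycB"])
  # two identical peaks at 2.06 and 3.23 give equal GlycA and SPC values
  sp3 <- generate_spectrum(data.frame(center = c(2.06, 3.23),
                                      width = 0.008, area = 1))
  g3 <- extract_glyc_spc(bin_spectrum(sp3, g), g)
  expect_equal(unname(g3["GlycA"]), unname(g3["SPC"]), tolerance = 1e-6)
})

test_that("GlycA/GlycB resolve to distinct adjacent buckets; flat is equal", {
  g <- bin_grid()
  pick <- vapply(g$named_bins, function(t) {
    d <- abs(g$centers - t); which(d == min(d))[1]
  }, integer(1))
  expect_equal(unname(pick["GlycB"] - pick["GlycA"]), 1L)
  expect_equal(length(unique(pick)), 3L)
  sp <- data.frame(ppm = seq(0.4015, 9.5995, by = 0.003), intensity = 1)
  flat <- extract_glyc_spc(bin_spectrum(sp, g), g)
  expect_equal(unname(flat["GlycA"]), unname(flat["GlycB"]), tolerance = 1e-9)
  expect_equal(unname(flat["GlycA"]), unname(flat["SPC"]), tolerance = 1e-9)
})

make_day_table <- function() {
  data.frame(
    sample_id = c("a1", "a2", "b1", "n1", "h1", "x1"),
    subject_id = c("A", "A", "B", "N", "H", "X"),
    cohort = c("AC", "RE", "AC", "NHR", "HC", "AC"),
    collection_date = as.Date("2020-05-01") + c(3, 36, 10, 75, 0, 4),
    hospitalization_date = c(as.Date("2020-05-01"), as.Date("2020-05-01"),
                             as.Date("2020-05-01"), NA, NA, NA),
    covid_report_date = c(NA, NA, NA, as.Date("2020-05-01"), NA, NA),
    age = 50L, sex = "F", severity = "none", vaccinated = FALSE,
    true_recovery_day = NA_real_,
    Glucose = 1, Lactate = 2,
    stringsAsFactors = FALSE)
}

test_that("day assignment follows the first-sample-within-7-days rule", {
  out <- assign_days_since_covid(make_day_table())
  expect_equal(out$day[out$sample_id == "a1"], 0L)   # 3 d post-admission
  expect_true(out$acute[out$sample_id == "a1"])
  expect_equal(out$day[out$sample_id == "a2"], 33L)  # counted from t = 0
  expect_false(out$acute[out$sample_id == "a2"])
  # first sample 10 d post-admission: days from hospitalization, not acute
  expect_equal(out$day[out$sample_id == "b1"], 10L)
  expect_false(out$acute[out$sample_id == "b1"])
  expect_equal(out$day[out$sample_id == "n1"], 75L)  # NHR date subtraction
  expect_true(is.na(out$day[out$sample_id == "h1"])) # HC has no day
  # hospitalized row without hospitalization date is excluded with a reason
  expect_false("x1" %in% out$sample_id)
  exc <- attr(out, "excluded")
  expect_equal(exc$sample_id, "x1")
  expect_match(exc$reason, "hospitalization")
})

test_that("day assignment is invariant to row order", {
  tab <- make_day_table()
  out1 <- assign_days_since_covid(tab)
  perm <- c(4, 2, 6, 1, 5, 3)
  out2 <- assign_days_since_covid(tab[perm, ])
  m <- match(out1$sample_id, out2$sample_id)
  expect_equal(out1$day, out2$day[m])
  expect_equal(out1$acute, out2$acute[m])
})

test_that("DBSCAN keeps dense clusters and discards injected outliers", {
  cfg <- small_generator(n_controls = 100, n_acute = 0, seed = 6)
  pop <- generate_population(cfg)
  res <- qc_filter_dbscan(pop, qc_config())
  expect_length(res$discarded_ids, 0)
  inj <- inject_outliers(pop, 3, 50, seed = 3)
  res2 <- qc_filter_dbscan(inj$samples, qc_config())
  expect_setequal(res2$discarded_ids, inj$outlier_ids)
  expect_equal(nrow(res2$kept), 97)
  expect_error(qc_filter_dbscan(pop[1:3, ], qc_config(min_pts = 5)),
               "min_pts")
  # defaults follow the published filtering settings
  q <- qc_config()
  expect_equal(q$min_pts, 5L)
  expect_equal(q$eps, 20)
})

test_that("DBSCAN agrees with a naive union-find reference", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(40:120, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    # a few shifted points create genuine noise/border cases
    x[seq_len(5), ] <- x[seq_len(5), ] + matrix(runif(15, 2, 6), 5, 3)
    eps <- runif(1, 0.6, 1.6)
    min_pts <- sample(3:6, 1)
    mine <- dbscan_cluster(x, eps, min_pts)
    ref <- bf_dbscan(x, eps, min_pts)
    expect_equal(mine == 0L, ref$noise)
    # core points partition identically (up to label names)
    core <- ref$core
    if (sum(core) > 1) {
      tab <- table(mine[core], ref$core_comp[core])
      expect_true(all(rowSums(tab > 0) == 1))
      expect_true(all(colSums(tab > 0) == 1))
    }
  }
})

test_that("log-standardization centers, scales, and projects consistently", {
  cfg <- small_generator(seed = 7)
  pop <- generate_population(cfg)
  ls <- log_standardize(pop)
  expect_true(all(abs(colMeans(ls$matrix)) < 1e-10))
  expect_true(all(abs(apply(ls$matrix, 2, sd) - 1) < 1e-10))
  # projecting the training table with its own stats reproduces the output
  reproj <- log_standardize(pop, stats = ls$stats)
  expect_equal(reproj$matrix, ls$matrix, tolerance = 1e-12)
  # a global multiplicative factor on one variable is absorbed by centering
  pop2 <- pop
  pop2$Glucose <- pop2$Glucose * 2
  ls2 <- log_standardize(pop2)
  expect_equal(ls2$matrix[, "Glucose"], ls$matrix[, "Glucose"],
               tolerance = 1e-10)
})

test_that("zeros are half-minimum replaced and constants dropped", {
  x <- cbind(a = c(0, 1, 2, 4), b = c(5, 5, 5, 5), c = c(1, 2, 3, 4))
  expect_warning(ls <- log_standardize(x), "constant")
  expect_false("b" %in% ls$stats$variable)
  expect_equal(ls$stats$zero_fill[ls$stats$variable == "a"], 0.5)
  # the zero cell was log(0.5)-standardized, finite
  expect_true(all(is.finite(ls$matrix)))
  expect_error(log_standardize(cbind(a = c(-1, 2, 3))), "non-negative")
})
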