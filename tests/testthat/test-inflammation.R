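# Mann-Whitney machinery, cytokine fold changes, linear marker decay and
# its coupling to metabolic recovery.

test_that("exact Mann-Whitney p agrees with full enumeration, ties included", {
  set.seed(21)
  for (rep in 1:25) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    # coarse rounding produces rich tie patterns
    x <- round(rnorm(n1), sample(0:1, 1))
    y <- round(rnorm(n2) + runif(1, -1, 1), sample(0:1, 1))
    expect_equal(mw_test(x, y)$p_value, bf_mw_p(x, y), tolerance = 1e-12)
  }
  # tie-free case matches the classical exact distribution
  set.seed(22)
  x <- rnorm(8); y <- rnorm(9)
  expect_equal(mw_test(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(23)
  x <- round(rnorm(40), 1); y <- round(rnorm(45) + 0.4, 1)
  mt <- mw_test(x, y)
  expect_equal(mt$method, "normal approximation")
  expect_equal(mt$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("fold changes read as binary logs of group mean ratios", {
  ctrl <- data.frame(sample_id = sprintf("c%d", 1:6), marker = "IL-6",
                     level = c(10, 12, 8, 11, 9, 10))
  case <- data.frame(sample_id = sprintf("a%d", 1:6), marker = "IL-6",
                     level = 2 * c(10, 12, 8, 11, 9, 10))
  panel <- rbind(ctrl, case)
  groups <- data.frame(sample_id = panel$sample_id,
                       group = factor(rep(c("control", "case"), each = 6),
                                      levels = c("control", "case")))
  fc <- fold_change_analysis(panel, groups)
  expect_equal(fc$log2_fc, 1)
  # identical groups: zero fold change, not significant
  panel0 <- panel; panel0$level <- rep(c(10, 12, 8, 11, 9, 10), 2)
  fc0 <- fold_change_analysis(panel0, groups)
  expect_equal(fc0$log2_fc, 0)
  expect_false(fc0$significant)
  # antisymmetry under swapping case and control
  groups_sw <- groups
  groups_sw$group <- factor(rep(c("case", "control"), each = 6),
                            levels = c("control", "case"))
  fc_sw <- fold_change_analysis(panel, groups_sw)
  expect_equal(fc_sw$log2_fc, -fc$log2_fc)
  expect_equal(fc_sw$p_mw, fc$p_mw, tolerance = 1e-12)
})

test_that("a 2.2-fold planted elevation is detected at the study group sizes", {
  for (seed in 1:3) {
    cfg <- small_generator(n_controls = 37, n_acute = 50, seed = seed)
    pop <- generate_population(cfg)
    pop$day <- ifelse(pop$cohort == "AC", 0L, NA_integer_)
    cyto <- generate_cytokines(cfg, pop)
    groups <- data.frame(sample_id = pop$sample_id,
                         group = factor(ifelse(pop$cohort == "AC", "case",
                                               "control"),
                                        levels = c("control", "case")))
    fc <- fold_change_analysis(cyto, groups)
    expect_true(fc$significant[fc$marker == "IL-6"])
    expect_gt(fc$log2_fc[fc$marker == "IL-6"], 0.5)
  }
})

test_that("marker decay line arithmetic and validity rules", {
  # level 100 at day 8 falling to 50 at day 58; healthy 40, acute 100:
  # midpoint 70 crossed at day 38
  series <- data.frame(day = c(8, 58), level = c(100, 50))
  est <- marker_decay(series, healthy_mean = 40, acute_mean = 100)
  expect_equal(est$half_recovery_day, 38)
  expect_true(est$valid)
  rising <- data.frame(day = c(8, 58), level = c(50, 100))
  expect_false(marker_decay(rising, 40, 100)$valid)
  single <- data.frame(day = 20, level = 50)
  expect_false(marker_decay(single, 40, 100)$valid)
})

test_that("estimated half-recovery tracks the generating decay duration", {
  set.seed(31)
  n <- 60
  L <- runif(n, 30, 120)
  base <- 50; fold <- 2
  healthy <- base; acute <- base * fold
  rows <- lapply(seq_len(n), function(i) {
    day <- seq(8, 98, by = 10)
    f <- pmax(0, 1 - (day - 8) / L[i])
    level <- base * fold^f * exp(rnorm(length(day), sd = 0.05))
    data.frame(subject_id = sprintf("p%02d", i), day = day, level = level,
               marker = "MCP-1", sample_id = sprintf("p%02d_%d", i, day))
  })
  panel <- do.call(rbind, rows)
  dec <- subject_marker_decays(panel, "MCP-1", healthy, acute)
  ok <- dec$valid
  expect_gt(mean(ok), 0.9)
  expect_gt(cor(dec$half_recovery_day[ok], L[ok]), 0.95)
})

test_that("recovery correlation resolves coupled and uncoupled designs", {
  # perfectly coupled noiseless pair
  dec <- data.frame(subject_id = sprintf("p%d", 1:20),
                    half_recovery_day = seq(20, 115, by = 5), valid = TRUE)
  est <- data.frame(subject_id = dec$subject_id,
                    recovery_days = 2 * dec$half_recovery_day + 7,
                    valid = TRUE)
  cr <- correlate_recovery(dec, est)
  expect_equal(cr$r, 1, tolerance = 1e-12)
  expect_equal(unname(cr$coefficients[2]), 2, tolerance = 1e-9)
  # coupling 0.8 at n = 60: generator decay truth vs recovery truth
  cfg <- small_generator(n_acute = 60, seed = 41)
  long <- generate_longitudinal(cfg)
  long$day <- as.integer(long$collection_date - long$hospitalization_date)
  long$day <- long$day - ave(long$day, long$subject_id, FUN = min)
  cyto <- generate_cytokines(cfg, long)
  mcp <- attr(cyto, "decay_days")
  mcp <- mcp[mcp$marker == "MCP-1", ]
  dec2 <- data.frame(subject_id = mcp$subject_id,
                     half_recovery_day = 8 + mcp$decay_days / 2,
                     valid = TRUE)
  truth <- long[!duplicated(long$subject_id),
                c("subject_id", "true_recovery_day")]
  est2 <- data.frame(subject_id = truth$subject_id,
                     recovery_days = truth$true_recovery_day, valid = TRUE)
  r_coupled <- correlate_recovery(dec2, est2)$r
  expect_gt(r_coupled, 0.6); expect_lt(r_coupled, 0.92)
  # zero coupling: use an uncoupled marker as the stand-in decay series
  ipd <- attr(cyto, "decay_days")
  ipd <- ipd[ipd$marker == "IP-10", ]
  dec3 <- data.frame(subject_id = ipd$subject_id,
                     half_recovery_day = 8 + ipd$decay_days / 2, valid = TRUE)
  expect_lt(abs(correlate_recovery(dec3, est2)$r), 0.35)
  expect_error(correlate_recovery(dec[1:3, ], est), "5 subjects")
})
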