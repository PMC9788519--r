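# Synthetic cohort generator: determinism, planted-effect fidelity,
# correlation structure, recovery-time law, cytokine coupling, fixtures.

test_that("same configuration and seed give bit-identical tables", {
  cfg <- small_generator(seed = 5)
  expect_identical(generate_population(cfg), generate_population(cfg))
  expect_identical(generate_longitudinal(cfg), generate_longitudinal(cfg))
  s <- generate_longitudinal(cfg)
  expect_identical(generate_cytokines(cfg, s), generate_cytokines(cfg, s))
})

test_that("empty informative panel leaves groups exchangeable", {
  cfg <- generator_config(
    n_controls = 400, n_acute = 400, n_metabolites = 10, n_lipoproteins = 8,
    informative_panel = data.frame(variable = character(0),
                                   effect = numeric(0)),
    block_structure = data.frame(size = 8L, rho = 0.5), seed = 3)
  pop <- generate_population(cfg)
  lx <- log(sample_matrix(pop))
  g <- pop$cohort == "AC"
  eff <- (colMeans(lx[g, ]) - colMeans(lx[!g, ])) /
    apply(lx[!g, ], 2, sd)
  expect_true(all(abs(eff) < 0.2))
})

test_that("a planted 1-SD shift is recovered by the screening estimator", {
  cfg <- generator_config(
    n_controls = 400, n_acute = 400, n_metabolites = 10, n_lipoproteins = 0,
    n_inflammation_bins = 0,
    informative_panel = data.frame(variable = "Glucose", effect = 1.0),
    block_structure = data.frame(size = integer(0), rho = numeric(0)),
    seed = 8)
  pop <- generate_population(cfg)
  res <- univariate_screen(log(sample_matrix(pop)),
                           as.integer(pop$cohort == "AC"),
                           covariates = pop[, c("age", "sex")])
  eff <- res$effect_sd[res$variable == "Glucose"]
  expect_true(abs(eff - 1.0) < 0.15)
  # non-panel variables identically distributed
  expect_true(all(abs(res$effect_sd[res$variable != "Glucose"]) < 0.25))
})

test_that("lipoprotein blocks carry the configured correlation", {
  cfg <- generator_config(n_controls = 600, n_acute = 0, n_metabolites = 4,
                          n_lipoproteins = 16,
                          informative_panel = data.frame(
                            variable = character(0), effect = numeric(0)),
                          block_structure = data.frame(size = c(8L, 8L),
                                                       rho = c(0.6, 0.6)),
                          seed = 4)
  pop <- generate_population(cfg)
  lx <- log(sample_matrix(pop))
  vars <- generator_variables(cfg)
  b1 <- vars[5:12]; b2 <- vars[13:20]
  c11 <- cor(lx[, b1]); c12 <- cor(lx[, b1], lx[, b2])
  expect_equal(mean(c11[upper.tri(c11)]), 0.6, tolerance = 0.08)
  expect_lt(max(abs(c12)), 0.25)
  # panel variables sit in distinct blocks by default: pairwise |r| < 0.8
  full <- generator_config(seed = 4)
  pp <- generate_population(full)
  cc <- cor(log(sample_matrix(pp, full$informative_panel$variable)))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.8)
})

test_that("recovery days follow the configured GEV law", {
  cfg <- generator_config(
    n_controls = 0, n_acute = 10000, n_metabolites = 2, n_lipoproteins = 0,
    n_inflammation_bins = 0,
    informative_panel = data.frame(variable = "Glucose", effect = 1),
    block_structure = data.frame(size = integer(0), rho = numeric(0)),
    age_effect_on_recovery = 0, severity_classes = c(all = 1),
    severity_probs = 1, seed = 21)
  long <- generate_longitudinal(cfg)
  t_true <- long$true_recovery_day[!duplicated(long$subject_id)]
  ks <- suppressWarnings(stats::ks.test(
    t_true, function(q) pgev(q, 62.44, 30.16, 0.34)))
  expect_gt(ks$p.value, 0.01)
})

test_that("age and severity modulate recovery times", {
  cfg <- generator_config(
    n_controls = 0, n_acute = 2000, n_metabolites = 2, n_lipoproteins = 0,
    n_inflammation_bins = 0,
    informative_panel = data.frame(variable = "Glucose", effect = 1),
    block_structure = data.frame(size = integer(0), rho = numeric(0)),
    seed = 22)
  long <- generate_longitudinal(cfg)
  subj <- long[!duplicated(long$subject_id), ]
  expect_gt(mean(subj$true_recovery_day[subj$age >= 65]),
            mean(subj$true_recovery_day[subj$age < 65]))
  expect_gt(mean(subj$true_recovery_day[subj$severity == "severe"]),
            mean(subj$true_recovery_day[subj$severity == "mild-moderate"]))
})

test_that("panel displacement decays linearly to zero at the recovery day", {
  cfg <- small_generator(n_controls = 5, n_acute = 40, seed = 9, noise_cv = 0)
  long <- generate_longitudinal(cfg)
  vm <- phenorevert:::.variable_model(cfg)
  day <- as.integer(long$collection_date - long$hospitalization_date)
  day <- day - ave(day, long$subject_id, FUN = min)
  f_expected <- pmax(0, 1 - day / long$true_recovery_day)
  lx <- log(sample_matrix(long, "Glucose"))
  i <- match("Glucose", vm$vars)
  f_observed <- (lx[, 1] - vm$meanlog[i]) / (vm$effect[["Glucose"]] * vm$sdlog[i])
  expect_equal(unname(f_observed), f_expected, tolerance = 1e-10)
})

test_that("cytokine table couples MCP-1 decay to metabolic recovery", {
  cfg <- small_generator(n_acute = 100, seed = 12)
  long <- generate_longitudinal(cfg)
  long$day <- as.integer(long$collection_date - long$hospitalization_date)
  long$day <- long$day - ave(long$day, long$subject_id, FUN = min)
  cyto <- generate_cytokines(cfg, long)
  expect_setequal(unique(cyto$marker), cfg$cytokine_markers)
  expect_true(all(cyto$level >= 0))
  dec <- attr(cyto, "decay_days")
  mcp <- dec[dec$marker == "MCP-1", ]
  truth <- long$true_recovery_day[match(mcp$subject_id, long$subject_id)]
  expect_equal(cor(mcp$decay_days, truth), 0.8, tolerance = 0.12)
})

test_that("acute cytokine elevation matches the configured fold", {
  cfg <- small_generator(n_controls = 300, n_acute = 300, seed = 13)
  pop <- generate_population(cfg)
  pop$day <- ifelse(pop$cohort == "AC", 0L, NA_integer_)
  cyto <- generate_cytokines(cfg, pop)
  il6 <- cyto[cyto$marker == "IL-6", ]
  acute <- il6$level[match(pop$sample_id[pop$cohort == "AC"], il6$sample_id)]
  hc <- il6$level[match(pop$sample_id[pop$cohort == "HC"], il6$sample_id)]
  expect_equal(log2(mean(acute) / mean(hc)), log2(2.2), tolerance = 0.15)
  # two healthy draws are exchangeable
  gm <- cyto[cyto$marker == "GM-CSF", ]
  a <- gm$level[match(pop$sample_id[pop$cohort == "AC"], gm$sample_id)]
  h <- gm$level[match(pop$sample_id[pop$cohort == "HC"], gm$sample_id)]
  expect_lt(abs(log2(mean(a) / mean(h))), 0.15)
})

test_that("spectrum generator produces Gaussian peaks on a clean baseline", {
  empty <- generate_spectrum(NULL, noise_sd = 0)
  expect_true(all(empty$intensity == 0))
  sp <- generate_spectrum(data.frame(center = 2.06, width = 0.01, area = 5))
  expect_equal(sp$ppm[which.max(sp$intensity)], 2.06, tolerance = 0.005)
  expect_error(generate_spectrum(data.frame(center = 2, width = 0, area = 1)),
               class = "phenorevert_config_error")
  expect_error(generate_spectrum(data.frame(center = 12, width = 1, area = 1)),
               class = "phenorevert_config_error")
})

test_that("outlier injection displaces exactly the chosen rows", {
  cfg <- small_generator(seed = 14)
  pop <- generate_population(cfg)
  expect_identical(inject_outliers(pop, 0, 50)$samples, pop)
  inj <- inject_outliers(pop, 3, 50, seed = 2)
  expect_identical(inj, inject_outliers(pop, 3, 50, seed = 2))
  z <- scale(sample_matrix(inj$samples))
  dist_to_centroid <- sqrt(rowSums(z^2))
  farthest <- inj$samples$sample_id[order(-dist_to_centroid)[1:3]]
  expect_setequal(farthest, inj$outlier_ids)
  expect_error(inject_outliers(pop, nrow(pop) + 1, 5),
               class = "phenorevert_config_error")
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(generator_config(n_controls = -1), "n_controls")
  expect_error(generator_config(gev_scale = 0), "gev_scale")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(block_structure = data.frame(size = 8L,
                                                             rho = 1)),
               "block_structure")
  expect_error(generator_config(informative_panel = data.frame(
    variable = "NotAVariable", effect = 1)), "informative_panel")
  expect_error(generator_config(cytokine_folds = c(Nonsense = 2)),
               "cytokine_folds")
  # a shape putting mass on negative recovery days is rejected
  expect_error(generator_config(gev_location = 5, gev_scale = 30,
                                gev_shape = 0),
               "gev")
})
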