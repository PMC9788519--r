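# Synthetic serum-metabolomics cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: log-normal positive concentrations, equicorrelated lipoprotein
# blocks on the log scale, an acute-phase shift planted on an informative
# variable panel (in units of the control group's log-scale SD), per-subject
# linear phenoreversion with recovery days drawn from a generalized extreme
# value law modulated by age and clinical severity, sparse longitudinal
# sampling in day bins, and a 13-marker cytokine panel whose MCP-1 decay
# time is coupled to the metabolic recovery time.

.metabolite_names <- function(n) {
  base <- c(
    "Glucose", "Lactate", "Pyruvate", "Citrate", "Glutamine", "Glutamate",
    "Alanine", "Glycine", "Histidine", "Phenylalanine", "Tyrosine", "Valine",
    "Leucine", "Isoleucine", "Lysine", "Methionine", "Threonine", "Proline",
    "Ornithine", "Asparagine", "Aspartate", "Serine", "Tryptophan",
    "Creatinine", "Creatine", "Choline", "Glycerol", "Dimethylglycine",
    "TMAO", "Sarcosine", "X2.Aminobutyrate", "X2.Oxoglutarate", "Succinate",
    "Acetate", "Acetoacetate", "Acetone", "X3.Hydroxybutyrate", "Formate",
    "Ethanol", "Methanol", "Dimethylsulfone")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("Met%02d", seq_len(n - length(base))))
}

.lipoprotein_names <- function(n) {
  classes <- c("VLDL", "IDL", "LDL", "HDL", "VLDL1", "VLDL2", "VLDL3",
               "VLDL4", "LDL1", "LDL2", "LDL3", "LDL6", "HDL1", "HDL4")
  measures <- c("TG", "CH", "FC", "PL", "ApoA1", "ApoA2", "ApoB", "PN")
  nm <- as.vector(t(outer(classes, measures, paste, sep = "_")))
  if (n <= length(nm)) nm[seq_len(n)] else
    c(nm, sprintf("LP%03d", seq_len(n - length(nm))))
}

.inflammation_names <- function(n) {
  base <- c("GlycA", "GlycB", "SPC")
  if (n <= 3L) base[seq_len(n)] else c(base, sprintf("Infl%02d", seq_len(n - 3L)))
}

#' Default informative variable panel
#'
#' The default acute-phase panel mirrors the biology of severe infection
#' serum profiles: elevated phenylalanine, glucose, glutamate, choline,
#' lactate, ketone bodies and glycoprotein inflammation signals (GlycA,
#' GlycB), depleted glutamine, histidine, lysine and most other amino acids,
#' a triglyceride-enriched VLDL/LDL profile with depleted HDL, and a reduced
#' SPC signal. Effect magnitudes are laid out on an even grid over
#' `effect_range` (largest first), in control-SD units on the log scale.
#'
#' @param n_variables panel size (default 38; at most 38)
#' @param effect_range range of absolute planted effects, in control-SD units
#' @return data.frame with columns `variable`, `effect` (signed, control-SD
#'   units on the log scale)
#' @export
default_informative_panel <- function(n_variables = 38,
                                      effect_range = c(0.66, 2.0)) {
  up <- c("Phenylalanine", "Glucose", "GlycA", "Glutamate", "GlycB",
          "Choline", "Lactate", "VLDL_TG", "Pyruvate", "X3.Hydroxybutyrate",
          "VLDL1_TG", "Acetoacetate", "IDL_CH", "Tyrosine", "LDL1_TG",
          "Creatinine", "LDL6_ApoB")
  down <- c("Glutamine", "Histidine", "Lysine", "SPC", "Citrate", "HDL_CH",
            "Glycine", "Leucine", "HDL4_ApoA1", "Isoleucine", "Valine",
            "Methionine", "Threonine", "Tryptophan", "Serine", "Asparagine",
            "Proline", "Ornithine", "Aspartate", "Alanine", "Acetate")
  vars <- character(0); sgn <- numeric(0)
  i <- 1L; j <- 1L
  while (length(vars) < length(up) + length(down)) {
    if (i <= length(up)) { vars <- c(vars, up[i]); sgn <- c(sgn, 1); i <- i + 1L }
    if (j <= length(down)) { vars <- c(vars, down[j]); sgn <- c(sgn, -1); j <- j + 1L }
  }
  if (n_variables > length(vars)) {
    stop_config("informative_panel",
                sprintf("at most %d default panel variables", length(vars)))
  }
  vars <- vars[seq_len(n_variables)]
  sgn <- sgn[seq_len(n_variables)]
  mags <- seq(max(effect_range), min(effect_range), length.out = n_variables)
  data.frame(variable = vars, effect = sgn * mags, stringsAsFactors = FALSE)
}

#' Synthetic cohort generator configuration
#'
#' @param n_controls,n_acute group sizes
#' @param n_metabolites,n_lipoproteins,n_inflammation_bins variable counts
#'   (defaults 41, 112 and 3, matching a quantified-serum panel)
#' @param informative_panel data.frame (`variable`, signed `effect` in
#'   control-SD units on the log scale) of acute-phase variables
#' @param block_structure data.frame (`size`, `rho`) of equicorrelated
#'   lipoprotein blocks on the log scale; sizes must sum to at most
#'   `n_lipoproteins` (remaining variables are independent)
#' @param inflammation_rho within-block correlation of the inflammation bins
#' @param gev_location,gev_scale,gev_shape recovery-time GEV parameters in
#'   days (defaults 62.44, 30.16, 0.34)
#' @param age_range cohort age range in years
#' @param age_effect_on_recovery days of extra recovery time per year of age
#'   (centered at the mid-range age)
#' @param severity_classes named recovery-time multipliers
#' @param severity_probs class probabilities, same order
#' @param sampling_bins list of `c(lo, hi]` day intervals for follow-up
#'   sampling
#' @param sampling_weights bin weights for follow-up draws
#' @param noise_cv within-subject coefficient of variation of repeated
#'   measurements (longitudinal samples)
#' @param cytokine_markers 13-name cytokine/chemokine panel
#' @param cytokine_folds named acute fold-changes for the elevated subset
#' @param mcp1_coupling correlation between the MCP-1 decay duration and the
#'   metabolic recovery day
#' @param decay_mean,decay_sd mean/SD (days) of cytokine decay durations
#' @param seed integer seed; all generator output is reproducible from it
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_controls = 400,
                             n_acute = 400,
                             n_metabolites = 41,
                             n_lipoproteins = 112,
                             n_inflammation_bins = 3,
                             informative_panel = default_informative_panel(),
                             block_structure = data.frame(
                               size = rep(8L, 14), rho = rep(0.6, 14)),
                             inflammation_rho = 0.5,
                             gev_location = 62.44,
                             gev_scale = 30.16,
                             gev_shape = 0.34,
                             age_range = c(30, 85),
                             age_effect_on_recovery = 0.5,
                             severity_classes = c("mild-moderate" = 0.95,
                                                  "severe" = 1.30),
                             severity_probs = c(0.75, 0.25),
                             sampling_bins = list(c(0, 7), c(7, 14), c(14, 30),
                                                  c(30, 60), c(60, 120)),
                             sampling_weights = c(0.30, 0.12, 0.15, 0.32, 0.11),
                             noise_cv = 0.05,
                             cytokine_markers = c(
                               "IL-1b", "IL-6", "IL-8", "IL-10", "TNF-a",
                               "IFN-g", "IP-10", "MCP-1", "IL-1RA", "IFN-a2",
                               "IFN-l1", "IL-12p70", "GM-CSF"),
                             cytokine_folds = c("IL-1RA" = 3.0, "IP-10" = 2.5,
                                                "IL-6" = 2.2, "MCP-1" = 2.0),
                             mcp1_coupling = 0.8,
                             decay_mean = 60,
                             decay_sd = 25,
                             seed = 1L) {
  cfg <- list(
    n_controls = n_controls, n_acute = n_acute,
    n_metabolites = n_metabolites, n_lipoproteins = n_lipoproteins,
    n_inflammation_bins = n_inflammation_bins,
    informative_panel = informative_panel,
    block_structure = block_structure,
    inflammation_rho = inflammation_rho,
    gev_location = gev_location, gev_scale = gev_scale, gev_shape = gev_shape,
    age_range = age_range,
    age_effect_on_recovery = age_effect_on_recovery,
    severity_classes = severity_classes, severity_probs = severity_probs,
    sampling_bins = sampling_bins, sampling_weights = sampling_weights,
    noise_cv = noise_cv,
    cytokine_markers = cytokine_markers, cytokine_folds = cytokine_folds,
    mcp1_coupling = mcp1_coupling,
    decay_mean = decay_mean, decay_sd = decay_sd,
    seed = seed)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param cfg a `generator_config`
#' @export
validate_generator_config <- function(cfg) {
  counts <- c("n_controls", "n_acute", "n_metabolites", "n_lipoproteins",
              "n_inflammation_bins")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v)) {
      stop_config(f, "must be a single non-negative integer")
    }
  }
  ip <- cfg$informative_panel
  if (!is.data.frame(ip) || !all(c("variable", "effect") %in% names(ip))) {
    stop_config("informative_panel",
                "must be a data.frame with columns variable, effect")
  }
  if (nrow(ip) > 0 && (!all(is.finite(ip$effect)))) {
    stop_config("informative_panel", "effects must be finite")
  }
  if (anyDuplicated(ip$variable)) {
    stop_config("informative_panel", "duplicated variable names")
  }
  vars <- generator_variables(cfg)
  missing <- setdiff(ip$variable, vars)
  if (length(missing) > 0) {
    stop_config("informative_panel", paste0(
      "unknown variables: ", paste(missing, collapse = ", ")))
  }
  bs <- cfg$block_structure
  if (!is.data.frame(bs) || !all(c("size", "rho") %in% names(bs))) {
    stop_config("block_structure",
                "must be a data.frame with columns size, rho")
  }
  if (any(bs$rho < 0 | bs$rho >= 1) ||
      cfg$inflammation_rho < 0 || cfg$inflammation_rho >= 1) {
    stop_config("block_structure", "within-block correlation must be in [0, 1)")
  }
  if (sum(bs$size) > cfg$n_lipoproteins) {
    stop_config("block_structure", "block sizes exceed n_lipoproteins")
  }
  if (cfg$gev_scale <= 0) stop_config("gev_scale", "must be > 0")
  if (!is.finite(cfg$gev_shape)) stop_config("gev_shape", "must be finite")
  if (pgev(0, cfg$gev_location, cfg$gev_scale, cfg$gev_shape) > 0.05) {
    stop_config("gev_shape",
                "configured GEV puts substantial mass on negative recovery days")
  }
  if (length(cfg$sampling_bins) > 0) {
    for (b in cfg$sampling_bins) {
      if (length(b) != 2L || b[2] <= b[1] || b[1] < 0) {
        stop_config("sampling_bins", "each bin must be an increasing day pair")
      }
    }
  }
  if (cfg$noise_cv < 0) stop_config("noise_cv", "must be >= 0")
  if (length(cfg$severity_classes) != length(cfg$severity_probs) ||
      abs(sum(cfg$severity_probs) - 1) > 1e-8) {
    stop_config("severity_probs", "must match severity_classes and sum to 1")
  }
  unknown <- setdiff(names(cfg$cytokine_folds), cfg$cytokine_markers)
  if (length(unknown) > 0) {
    stop_config("cytokine_folds", paste0(
      "unknown marker names: ", paste(unknown, collapse = ", ")))
  }
  invisible(cfg)
}

#' Variable names produced by a generator configuration
#' @param cfg a `generator_config`
#' @return character vector (metabolites, lipoproteins, inflammation bins)
#' @export
generator_variables <- function(cfg) {
  c(.metabolite_names(cfg$n_metabolites),
    .lipoprotein_names(cfg$n_lipoproteins),
    .inflammation_names(cfg$n_inflammation_bins))
}

# Fixed per-variable population model: log-scale means and SDs, derived
# deterministically from the variable index (not from the RNG) so that the
# population is a property of the configuration, not of the seed.
.variable_model <- function(cfg) {
  vars <- generator_variables(cfg)
  k <- seq_along(vars)
  frac <- (k * 0.6180339887) %% 1
  sdlog <- 0.2 + 0.4 * frac
  meanlog <- log(0.5) + 2 * (((k * 0.4142135624) %% 1) - 0.5)
  effect <- stats::setNames(rep(0, length(vars)), vars)
  if (nrow(cfg$informative_panel) > 0) {
    effect[cfg$informative_panel$variable] <- cfg$informative_panel$effect
  }
  # block index per variable: 0 = independent
  block <- integer(length(vars))
  rho <- numeric(length(vars))
  off <- cfg$n_metabolites
  bi <- 1L
  pos <- 1L
  if (nrow(cfg$block_structure) > 0) {
    for (b in seq_len(nrow(cfg$block_structure))) {
      sz <- cfg$block_structure$size[b]
      idx <- off + pos:(pos + sz - 1L)
      block[idx] <- bi
      rho[idx] <- cfg$block_structure$rho[b]
      pos <- pos + sz
      bi <- bi + 1L
    }
  }
  if (cfg$n_inflammation_bins > 1 && cfg$inflammation_rho > 0) {
    idx <- cfg$n_metabolites + cfg$n_lipoproteins +
      seq_len(cfg$n_inflammation_bins)
    block[idx] <- bi
    rho[idx] <- cfg$inflammation_rho
  }
  list(vars = vars, meanlog = meanlog, sdlog = sdlog, effect = effect,
       block = block, rho = rho)
}

# n x p matrix of standard normal scores with the configured equicorrelated
# block structure (z = sqrt(rho) g_block + sqrt(1 - rho) e).
.correlated_scores <- function(n, vm) {
  p <- length(vm$vars)
  z <- matrix(stats::rnorm(n * p), n, p)
  for (b in unique(vm$block[vm$block > 0])) {
    idx <- which(vm$block == b)
    rho <- vm$rho[idx[1]]
    if (rho > 0) {
      g <- stats::rnorm(n)
      z[, idx] <- sqrt(rho) * g + sqrt(1 - rho) * z[, idx]
    }
  }
  z
}

.sample_metadata_frame <- function(n) {
  data.frame(
    sample_id = character(n), subject_id = character(n), cohort = character(n),
    collection_date = as.Date(rep(NA, n)),
    hospitalization_date = as.Date(rep(NA, n)),
    covid_report_date = as.Date(rep(NA, n)),
    age = integer(n), sex = character(n), severity = character(n),
    vaccinated = logical(n), true_recovery_day = as.numeric(rep(NA, n)),
    stringsAsFactors = FALSE)
}

.GENERATOR_EPOCH <- as.Date("2020-04-01")

#' Generate a cross-sectional case/control population
#'
#' Draws `n_controls` healthy-control (HC) and `n_acute` acute (AC) samples.
#' Concentrations are log-normal; acute rows are shifted on the log scale by
#' the configured signed effect of each informative-panel variable, in units
#' of that variable's control-group log-scale SD. Non-panel variables are
#' identically distributed in both groups. Lipoprotein variables carry the
#' configured equicorrelated block structure.
#'
#' Acute samples are given a hospitalization date and a collection date 0-5
#' days later, so that downstream day assignment flags them as acute (t = 0).
#'
#' @param config a [generator_config()]
#' @return sample table `data.frame`; the planted panel is attached as
#'   attribute `"planted_panel"`
#' @export
generate_population <- function(config) {
  validate_generator_config(config)
  vm <- .variable_model(config)
  n0 <- config$n_controls
  n1 <- config$n_acute
  n <- n0 + n1
  with_preserved_seed(derive_seed(config$seed, "population"), {
    z <- .correlated_scores(n, vm)
    grp <- rep(c(0, 1), c(n0, n1))
    logx <- sweep(z, 2, vm$sdlog, "*")
    logx <- sweep(logx, 2, vm$meanlog, "+")
    logx <- logx + outer(grp, vm$effect * vm$sdlog)
    values <- exp(logx)
    colnames(values) <- vm$vars

    meta <- .sample_metadata_frame(n)
    meta$sample_id <- c(sprintf("HC%04d", seq_len(n0)),
                        sprintf("AC%04d", seq_len(n1)))
    meta$subject_id <- meta$sample_id
    meta$cohort <- rep(c("HC", "AC"), c(n0, n1))
    meta$age <- as.integer(round(stats::runif(n, config$age_range[1],
                                              config$age_range[2])))
    meta$sex <- sample(c("M", "F"), n, replace = TRUE)
    meta$severity <- c(rep("none", n0),
                       sample(names(config$severity_classes), n1,
                              replace = TRUE, prob = config$severity_probs))
    meta$vaccinated <- FALSE
    meta$collection_date[seq_len(n0)] <-
      .GENERATOR_EPOCH - sample(30:400, n0, replace = TRUE)
    if (n1 > 0) {
      hosp <- .GENERATOR_EPOCH + sample(0:200, n1, replace = TRUE)
      meta$hospitalization_date[n0 + seq_len(n1)] <- hosp
      meta$collection_date[n0 + seq_len(n1)] <-
        hosp + sample(0:5, n1, replace = TRUE)
    }
    out <- cbind(meta, as.data.frame(values, optional = TRUE))
    attr(out, "planted_panel") <- config$informative_panel
    out
  })
}

#' Generate longitudinal acute-to-recovery trajectories
#'
#' For each of `n_acute` subjects, a true recovery day `T` is drawn from the
#' configured GEV law, multiplied by the subject's severity-class factor and
#' shifted by `age_effect_on_recovery * (age - midrange age)` days (floored
#' at 5 days). Each subject contributes an acute sample at day 0 and 1-4
#' follow-up samples at integer days drawn uniformly within sampling bins
#' chosen by the configured weights. The planted panel displacement shrinks
#' linearly from its full acute value at day 0 to zero at day `T` and stays
#' at zero thereafter; repeated samples vary around this trajectory with a
#' within-subject log-scale SD of `sqrt(log(1 + noise_cv^2))`.
#'
#' @param config a [generator_config()]
#' @return sample table with one row per sample; day-0 rows have cohort
#'   `"AC"`, follow-ups `"RE"`; `true_recovery_day` carries the ground truth
#' @export
generate_longitudinal <- function(config) {
  validate_generator_config(config)
  if (length(config$sampling_bins) == 0) {
    stop_config("sampling_bins", "at least one sampling bin is required")
  }
  vm <- .variable_model(config)
  ns <- config$n_acute
  if (ns == 0) stop_config("n_acute", "need at least one subject")
  with_preserved_seed(derive_seed(config$seed, "longitudinal"), {
    age <- as.integer(round(stats::runif(ns, config$age_range[1],
                                         config$age_range[2])))
    sex <- sample(c("M", "F"), ns, replace = TRUE)
    severity <- sample(names(config$severity_classes), ns, replace = TRUE,
                       prob = config$severity_probs)
    t_base <- rgev(ns, config$gev_location, config$gev_scale, config$gev_shape)
    mid_age <- mean(config$age_range)
    t_true <- pmax(
      t_base * unname(config$severity_classes[severity]) +
        config$age_effect_on_recovery * (age - mid_age), 5)

    nb <- length(config$sampling_bins)
    subj <- integer(0); day <- integer(0)
    for (i in seq_len(ns)) {
      nf <- sample(1:4, 1, prob = c(0.30, 0.30, 0.25, 0.15))
      bins <- sample.int(nb, nf, replace = TRUE, prob = config$sampling_weights)
      d <- vapply(bins, function(b) {
        lo <- config$sampling_bins[[b]][1]
        hi <- config$sampling_bins[[b]][2]
        as.integer(sample(seq(floor(lo) + 1L, floor(hi)), 1))
      }, integer(1))
      d <- unique(d)
      subj <- c(subj, rep(i, 1L + length(d)))
      day <- c(day, 0L, sort(d))
    }
    m <- length(day)
    f <- pmax(0, 1 - day / t_true[subj])
    sdlog_noise <- sqrt(log(1 + config$noise_cv^2))
    logx <- matrix(vm$meanlog, m, length(vm$vars), byrow = TRUE) +
      outer(f, vm$effect * vm$sdlog) +
      matrix(stats::rnorm(m * length(vm$vars), sd = sdlog_noise),
             m, length(vm$vars))
    values <- exp(logx)
    colnames(values) <- vm$vars

    meta <- .sample_metadata_frame(m)
    rep_idx <- as.integer(stats::ave(subj, subj, FUN = seq_along))
    meta$sample_id <- sprintf("RE%04d_%d", subj, rep_idx)
    meta$subject_id <- sprintf("P%04d", subj)
    meta$cohort <- ifelse(day == 0L, "AC", "RE")
    meta$age <- age[subj]
    meta$sex <- sex[subj]
    meta$severity <- severity[subj]
    meta$vaccinated <- FALSE
    meta$true_recovery_day <- t_true[subj]
    hosp <- .GENERATOR_EPOCH + (subj %% 150L)
    first_offset <- sample(0:5, ns, replace = TRUE)
    meta$hospitalization_date <- hosp
    meta$collection_date <- hosp + first_offset[subj] + day
    out <- cbind(meta, as.data.frame(values, optional = TRUE))
    attr(out, "planted_panel") <- config$informative_panel
    out
  })
}

#' Generate a 13-marker cytokine/chemokine table
#'
#' Healthy rows draw every marker from its log-normal baseline. Acute
#' subjects carry the configured fold-elevation on the elevated subset
#' (default IL-1RA, IP-10, IL-6, MCP-1) for days 0-8, then decay linearly
#' (on the log scale of the fold) back to the healthy mean over a per-subject
#' decay duration. The MCP-1 decay duration is generated with correlation
#' `mcp1_coupling` to the subject's `true_recovery_day`.
#'
#' @param config a [generator_config()]
#' @param samples sample table with `day` assigned (see
#'   [assign_days_since_covid()]) or generated by [generate_longitudinal()]
#' @return long data.frame (`sample_id`, `subject_id`, `day`, `marker`,
#'   `level`); per-subject decay durations are attached as attribute
#'   `"decay_days"`
#' @export
generate_cytokines <- function(config, samples) {
  validate_generator_config(config)
  if (!"day" %in% names(samples)) {
    samples$day <- as.integer(round(
      as.numeric(samples$collection_date - samples$hospitalization_date)))
  }
  hospitalized <- samples$cohort %in% c("AC", "RE")
  if (any(hospitalized & !is.finite(samples$day))) {
    stop_config("samples", "acute/recovery rows must carry day labels")
  }
  markers <- config$cytokine_markers
  nm <- length(markers)
  base_mean <- stats::setNames(
    exp(log(50) + 2 * ((seq_len(nm) * 0.7548777) %% 1)), markers)
  sdlog <- 0.4
  folds <- config$cytokine_folds

  with_preserved_seed(derive_seed(config$seed, "cytokines"), {
    subjects <- unique(samples$subject_id[hospitalized])
    t_true <- samples$true_recovery_day[match(subjects, samples$subject_id)]
    # per-subject decay durations; MCP-1 coupled to the metabolic recovery day
    decay <- list()
    fin <- is.finite(t_true)
    for (mk in names(folds)) {
      d <- stats::rnorm(length(subjects), config$decay_mean, config$decay_sd)
      if (mk == "MCP-1" && sum(fin) > 2 && stats::sd(t_true[fin]) > 0) {
        # Gaussian coupling to the metabolic recovery day where truth exists
        rho <- config$mcp1_coupling
        t_std <- (t_true[fin] - mean(t_true[fin])) / stats::sd(t_true[fin])
        zz <- rho * t_std + sqrt(1 - rho^2) * stats::rnorm(sum(fin))
        d[fin] <- config$decay_mean + config$decay_sd * zz
      }
      decay[[mk]] <- pmax(d, 10)
    }
    decay_df <- do.call(rbind, lapply(names(folds), function(mk) {
      data.frame(subject_id = subjects, marker = mk,
                 decay_days = decay[[mk]], stringsAsFactors = FALSE)
    }))

    n <- nrow(samples)
    out <- vector("list", nm)
    for (k in seq_len(nm)) {
      mk <- markers[k]
      f <- numeric(n)
      if (mk %in% names(folds)) {
        si <- match(samples$subject_id, subjects)
        el <- hospitalized & !is.na(si)
        d <- samples$day[el]
        L <- decay[[mk]][si[el]]
        f[el] <- ifelse(d <= 8, 1, pmax(0, 1 - (d - 8) / L))
      }
      lvl <- exp(log(base_mean[[mk]]) +
                   f * log(if (mk %in% names(folds)) folds[[mk]] else 1) +
                   stats::rnorm(n, sd = sdlog))
      out[[k]] <- data.frame(
        sample_id = samples$sample_id, subject_id = samples$subject_id,
        day = if ("day" %in% names(samples)) samples$day else NA_integer_,
        marker = mk, level = lvl, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "decay_days") <- decay_df
    res
  })
}

#' Generate a synthetic 1D spectrum from Gaussian peaks
#'
#' Sum of Gaussian peaks on a uniform ppm grid, with optional additive
#' baseline noise (clipped at zero so intensities stay non-negative).
#'
#' @param peaks data.frame with columns `center` (ppm), `width` (Gaussian SD,
#'   ppm) and `area`
#' @param ppm_range axis limits
#' @param resolution grid step in ppm
#' @param noise_sd baseline noise SD (0 = none)
#' @param seed optional RNG seed for the noise
#' @return data.frame (`ppm`, `intensity`)
#' @export
generate_spectrum <- function(peaks = NULL, ppm_range = c(0.5, 9.5),
                              resolution = 0.005, noise_sd = 0, seed = NULL) {
  ppm <- seq(ppm_range[1], ppm_range[2], by = resolution)
  intensity <- numeric(length(ppm))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    if (!all(c("center", "width", "area") %in% names(peaks))) {
      stop_config("peaks", "need columns center, width, area")
    }
    if (any(peaks$width <= 0)) stop_config("peaks", "widths must be positive")
    if (any(peaks$center < ppm_range[1] | peaks$center > ppm_range[2])) {
      stop_config("peaks", "centers must lie within ppm_range")
    }
    for (i in seq_len(nrow(peaks))) {
      intensity <- intensity +
        peaks$area[i] * stats::dnorm(ppm, peaks$center[i], peaks$width[i])
    }
  }
  if (noise_sd > 0) {
    intensity <- with_preserved_seed(seed, {
      pmax(intensity + stats::rnorm(length(ppm), sd = noise_sd), 0)
    })
  }
  data.frame(ppm = ppm, intensity = intensity)
}

#' Displace rows of a sample table to create multivariate outliers
#'
#' Adds `magnitude` per-variable SDs (raw scale, upward) to every variable of
#' `n_outliers` randomly chosen rows, producing points far from the cohort
#' centroid in standardized Euclidean distance — fixtures for density-based
#' sample QC.
#'
#' @param samples sample table
#' @param n_outliers number of rows to displace
#' @param magnitude displacement per variable, in that variable's SD
#' @param seed optional RNG seed
#' @return list with `samples` (displaced copy) and `outlier_ids`
#' @export
inject_outliers <- function(samples, n_outliers, magnitude, seed = NULL) {
  if (n_outliers > nrow(samples)) {
    stop_config("n_outliers", "more outliers than rows")
  }
  if (n_outliers == 0) {
    return(list(samples = samples, outlier_ids = character(0)))
  }
  vars <- sample_variables(samples)
  with_preserved_seed(seed, {
    rows <- sample.int(nrow(samples), n_outliers)
    sds <- vapply(samples[vars], stats::sd, numeric(1))
    for (r in rows) {
      samples[r, vars] <- samples[r, vars] + magnitude * sds
    }
    list(samples = samples, outlier_ids = samples$sample_id[rows])
  })
}
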