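#' Default configuration for the synthetic microdata generator
#'
#' The generator emulates pooled NHANES-style microdata for adults aged 60+:
#' the 16 food-security items arise from a correlated three-factor latent
#' model (resource constraints, physical limitations, and a severity factor
#' carrying the two "whole day without eating" items) with probit thresholds;
#' respondents are allocated to a stratified two-PSU-per-stratum design with
#' log-normal weight variation; depression and poor self-reported health are
#' drawn from logistic models on the cross-classified category with planted
#' odds ratios; diet quality follows a category-dependent gradient.
#'
#' Threshold shifts and the resource/physical factor correlation are
#' calibrated (see \code{\link{calibrate_thresholds}}) so the cross-classified
#' category distribution matches the published 2007-2018 prevalence pattern
#' (48.3, 30.8, 13.6, 7.3 percent); the planted outcome odds ratios mirror
#' the published adjusted estimates.
#'
#' @param n number of respondents.
#' @param seed RNG seed stored in the config (generation is reproducible).
#' @param ... overrides for any default element.
#' @return list of class \code{fs_sim_config}.
#' @export
fs_sim_config <- function(n = 10000, seed = 1, ...) {
  items <- c(paste0("afssm_", 1:10), paste0("pfs_", 1:6))
  ## loading pattern: unit-strength rows scaled by the per-scale loading
  ## strengths load_afssm / load_pfs (calibrated); the two whole-day items
  ## (rows 9:10) sit on the severity factor with a resource cross-loading
  L <- matrix(0, 16, 3, dimnames = list(items, c("resource", "physical", "severity")))
  L[1:8, "resource"] <- 1
  L[9:10, "resource"] <- 0.30
  L[9:10, "severity"] <- 0.85
  L[11:16, "physical"] <- 1
  base_prev <- c(0.10, 0.09, 0.08, 0.055, 0.045, 0.035, 0.03, 0.02,
                 0.012, 0.008,
                 0.30, 0.32, 0.15, 0.18, 0.10, 0.05)
  names(base_prev) <- items
  cfg <- list(
    n = n, seed = seed,
    n_strata = 15, psus_per_stratum = 2,
    weight_cv = 0.5, weight_mean = 3000, n_cycles = 6,
    loadings = L,
    base_prev = base_prev,
    ## frozen output of calibrate_thresholds() against the published joint
    ## and marginal category targets below
    shift_afssm = -0.083011, shift_pfs = 0.086438,
    spread_afssm = 0.537018, spread_pfs = 1.313435,
    load_afssm = 0.927237, load_pfs = 0.848003,
    rho_rp = 0.305490,  # resource-physical factor correlation (calibrated)
    rho_rs = 0.55,      # resource-severity
    rho_ps = 0.30,      # physical-severity
    joint_targets = c(High = 0.483, Marginal = 0.308,
                      Low = 0.136, VeryLow = 0.073),
    ## model-implied shares of the frozen default model (reference draw of
    ## one million); the generating truth for recovery checks
    joint_model = c(High = 0.48064, Marginal = 0.30971,
                    Low = 0.14203, VeryLow = 0.06763),
    afssm_targets = c(High = 0.860, Marginal = 0.060,
                      Low = 0.047, VeryLow = 0.033),
    pfs_targets = c(High = 0.527, Marginal = 0.314,
                    Low = 0.114, VeryLow = 0.044),
    ## outcome models (log odds for Marginal/Low/VeryLow vs High)
    depression = list(base_p = 0.04, log_or = log(c(2.92, 6.36, 14.6)),
                      b_female = 0.30, b_age70 = 0.10),
    poor_srh = list(base_p = 0.13, log_or = log(c(3.44, 7.64, 12.7)),
                    b_female = 0.10, b_age70 = 0.20),
    ## dietary gradient on the plogis scale (High referent)
    dietary = list(base_mix = 0.55, cat_effect = c(0, -0.10, -0.17, -0.26),
                   mix_sd = 0.55, energy_meanlog = log(1750),
                   energy_sdlog = 0.30),
    missingness = list(enabled = FALSE, phq9 = 0.10, pir = 0.09,
                       education = 0.0016, marital = 0.0008)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "fs_sim_config")
}

factor_corr <- function(config) {
  Phi <- diag(3)
  Phi[1, 2] <- Phi[2, 1] <- config$rho_rp
  Phi[1, 3] <- Phi[3, 1] <- config$rho_rs
  Phi[2, 3] <- Phi[3, 2] <- config$rho_ps
  Phi
}

item_thresholds <- function(config) {
  tau <- stats::qnorm(1 - config$base_prev)
  ma <- mean(tau[1:10]); mp <- mean(tau[11:16])
  tau[1:10] <- ma + config$spread_afssm * (tau[1:10] - ma) + config$shift_afssm
  tau[11:16] <- mp + config$spread_pfs * (tau[11:16] - mp) + config$shift_pfs
  tau
}

## latent-threshold item draws from pre-drawn standard normals:
## Zf n x 3, Ze n x 16. Returns 0/1 matrix.
items_from_normals <- function(Zf, Ze, config) {
  Phi <- factor_corr(config)
  L <- config$loadings
  L[1:10, ] <- L[1:10, ] * config$load_afssm
  L[11:16, ] <- L[11:16, ] * config$load_pfs
  comm <- rowSums((L %*% Phi) * L)   # communality lambda' Phi lambda
  if (any(comm >= 1)) stop("infeasible loadings: communality >= 1")
  f <- Zf %*% chol(Phi)
  lat <- f %*% t(L) + Ze %*% diag(sqrt(1 - comm))
  tau <- item_thresholds(config)
  items <- sweep(lat, 2, tau, ">") * 1
  colnames(items) <- rownames(L)
  list(items = items, factors = f)
}

#' Model-implied item correlation matrix
#'
#' The latent (tetrachoric-scale) correlation matrix of the 16 items implied
#' by the configured loadings and factor correlations: Lambda Phi Lambda'
#' with unit diagonal. Useful for structural checks free of sampling noise,
#' e.g. that zeroing the secondary factors leaves exactly one eigenvalue
#' above 1.
#'
#' @param config an \code{fs_sim_config}.
#' @return 16 x 16 correlation matrix.
#' @export
model_item_correlation <- function(config) {
  Phi <- factor_corr(config)
  L <- config$loadings
  L[1:10, ] <- L[1:10, ] * config$load_afssm
  L[11:16, ] <- L[11:16, ] * config$load_pfs
  R <- L %*% Phi %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(rownames(L), rownames(L))
  R
}

category_shares <- function(items) {
  a <- categorize_afssm(raw_score(items[, paste0("afssm_", 1:10)]))
  p <- categorize_pfs(raw_score(items[, paste0("pfs_", 1:6)]))
  jt <- cross_classify(a, p)
  list(joint = as.vector(table(jt)) / length(jt),
       afssm = as.vector(table(a)) / length(a),
       pfs = as.vector(table(p)) / length(p))
}

#' Calibrate item thresholds to the category probability targets
#'
#' Adjusts seven generator parameters — a threshold shift, a threshold
#' spread, and a loading strength per scale, plus the resource-physical
#' factor correlation — so the latent model reproduces the configured
#' cross-classified joint category distribution together with the two
#' scale-marginal distributions. The least-squares objective upweights the
#' joint targets and is evaluated on one large common-random-numbers draw,
#' making the search deterministic.
#'
#' @param config an \code{fs_sim_config}.
#' @param n_calib size of the calibration draw (default 100,000).
#' @param seed seed for the calibration draw.
#' @return the config with calibrated \code{shift_afssm}, \code{shift_pfs},
#'   \code{spread_afssm}, \code{spread_pfs}, \code{load_afssm},
#'   \code{load_pfs}, \code{rho_rp}, and an \code{achieved} attribute holding
#'   the calibration shares.
#' @export
calibrate_thresholds <- function(config, n_calib = 1e5, seed = 1) {
  for (tg in c("joint_targets", "afssm_targets", "pfs_targets")) {
    s <- sum(config[[tg]])
    if (abs(s - 1) > 0.005) stop("infeasible ", tg, ": must sum to 1")
    config[[tg]] <- config[[tg]] / s  # absorb printed-value rounding
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Zf <- matrix(stats::rnorm(n_calib * 3), n_calib, 3)
  Ze <- matrix(stats::rnorm(n_calib * 16), n_calib, 16)
  apply_par <- function(cf, par) {
    cf$shift_afssm <- par[1]
    cf$shift_pfs <- par[2]
    cf$spread_afssm <- exp(par[3])
    cf$spread_pfs <- exp(par[4])
    cf$load_afssm <- 0.95 * stats::plogis(par[5])
    cf$load_pfs <- 0.95 * stats::plogis(par[6])
    cf$rho_rp <- tanh(par[7])
    cf
  }
  obj <- function(par) {
    cf <- apply_par(config, par)
    sh <- tryCatch(category_shares(items_from_normals(Zf, Ze, cf)$items),
                   error = function(e) NULL)  # infeasible corr/communality
    if (is.null(sh)) return(10)
    4 * sum((sh$joint - config$joint_targets)^2) +
      sum((sh$afssm - config$afssm_targets)^2) +
      sum((sh$pfs - config$pfs_targets)^2)
  }
  start <- c(config$shift_afssm, config$shift_pfs,
             log(config$spread_afssm), log(config$spread_pfs),
             stats::qlogis(config$load_afssm / 0.95),
             stats::qlogis(config$load_pfs / 0.95),
             atanh(config$rho_rp))
  fit <- stats::optim(start, obj, control = list(maxit = 800, reltol = 1e-10))
  config <- apply_par(config, fit$par)
  sh <- category_shares(items_from_normals(Zf, Ze, config)$items)
  if (max(abs(sh$joint - config$joint_targets)) > 0.02) {
    stop("calibration failed: achieved joint shares ",
         paste(round(sh$joint, 3), collapse = "/"), " vs targets ",
         paste(config$joint_targets, collapse = "/"))
  }
  attr(config, "achieved") <- sh
  config
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

rcat <- function(n, probs, labels) {
  labels[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

## allocate a PHQ-9 total (0..27) across 9 items capped at 3 each
phq9_items_from_total <- function(totals) {
  slots <- rep(1:9, each = 3)
  t(vapply(totals, function(tt) {
    tabulate(sample(slots, tt), nbins = 9)
  }, numeric(9)))
}

#' Generate a synthetic NHANES-like respondent population
#'
#' Draws a full respondent table (items, demographics, design variables,
#' outcomes) from the configured model together with a truth ledger
#' recording every planted parameter and the per-record latent factor
#' scores, so any planted quantity can be recomputed independently of the
#' analysis pipeline.
#'
#' @param config an \code{fs_sim_config} (use calibrated defaults).
#' @return list with \code{table} (data.frame) and \code{truth} (list).
#' @export
generate_population <- function(config = fs_sim_config()) {
  set.seed(config$seed)
  n <- config$n
  ## design: strata x PSUs, log-normal weights independent of the outcomes
  stratum <- sample(seq_len(config$n_strata), n, replace = TRUE)
  psu <- sample(seq_len(config$psus_per_stratum), n, replace = TRUE)
  cv <- config$weight_cv
  sdlog <- sqrt(log(1 + cv^2))
  w2yr <- config$weight_mean *
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  cycle <- sample(paste0("cycle_", seq_len(config$n_cycles)), n, replace = TRUE)

  ## items from the three-factor latent model
  Zf <- matrix(stats::rnorm(n * 3), n, 3)
  Ze <- matrix(stats::rnorm(n * 16), n, 16)
  drawn <- items_from_normals(Zf, Ze, config)
  items <- drawn$items

  tab <- data.frame(respondent_id = seq_len(n), cycle = cycle,
                    stratum = stratum, psu = psu,
                    wtint2yr = w2yr,
                    wtmec2yr = w2yr * stats::rlnorm(n, 0, 0.05),
                    wtdr2d = w2yr * stats::rlnorm(n, 0, 0.08))
  tab <- cbind(tab, as.data.frame(items))

  ## demographics
  tab$age_years <- ifelse(stats::runif(n) < 0.60,
                          sample(60:69, n, replace = TRUE),
                          sample(70:85, n, replace = TRUE))
  tab$sex <- rcat(n, c(0.45, 0.55), c("male", "female"))
  tab$race_ethnicity <- rcat(n, c(0.04, 0.04, 0.78, 0.09, 0.05),
                             c("mexican_american", "other_hispanic",
                               "nh_white", "nh_black", "other"))
  tab$education <- rcat(n, c(0.17, 0.25, 0.58),
                        c("less_hs", "hs", "gt_hs"))
  tab$marital <- rcat(n, c(0.63, 0.37), c("partnered", "unpartnered"))
  tab$household_size <- rcat(n, c(0.24, 0.55, 0.21), c("1", "2", "3+"))
  tab$pir <- round(pmin(5, stats::rlnorm(n, log(2.4), 0.6)), 2)

  ## classification (ground truth for outcome generation)
  cls <- classify_table(tab)
  sev <- fs_severity(as.character(cls$crossclass_cat))
  female <- as.numeric(tab$sex == "female")
  age70 <- as.numeric(tab$age_years >= 70)

  dep <- config$depression
  lp_dep <- stats::qlogis(dep$base_p) + c(0, dep$log_or)[sev] +
    dep$b_female * female + dep$b_age70 * age70
  depressed <- stats::rbinom(n, 1, stats::plogis(lp_dep))
  ## PHQ-9 items consistent with the planted flag (total >= 10 iff depressed)
  tot <- ifelse(depressed == 1,
                10 + stats::rbinom(n, 17, 0.25),
                pmin(9, stats::rbinom(n, 27, 0.10)))
  phq <- phq9_items_from_total(tot)
  colnames(phq) <- paste0("phq9_", 1:9)
  tab <- cbind(tab, as.data.frame(phq))

  srh_m <- config$poor_srh
  lp_srh <- stats::qlogis(srh_m$base_p) + c(0, srh_m$log_or)[sev] +
    srh_m$b_female * female + srh_m$b_age70 * age70
  poor <- stats::rbinom(n, 1, stats::plogis(lp_srh))
  tab$srh <- ifelse(poor == 1,
                    sample(4:5, n, replace = TRUE, prob = c(0.7, 0.3)),
                    sample(1:3, n, replace = TRUE))

  ## other self-reports with severity gradients (not planted-OR targets)
  tab$appetite <- stats::rbinom(n, 1, stats::plogis(-2.1 + 0.55 * (sev - 1))) *
    sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  tab$depression_difficulty_src <-
    stats::rbinom(n, 1, stats::plogis(-2.6 + 0.75 * (sev - 1))) *
    sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  tab$weight_1y_ago <- round(stats::rnorm(n, 80, 14), 1)
  tab$weight_1y_ago[tab$weight_1y_ago < 45] <- 45
  loss_flag <- stats::rbinom(n, 1, stats::plogis(-2.9 + 0.45 * (sev - 1)))
  loss_frac <- ifelse(loss_flag == 1, stats::runif(n, 0.10, 0.25),
                      stats::runif(n, -0.05, 0.08))
  tab$weight_now <- round(tab$weight_1y_ago * (1 - loss_frac), 1)
  for (cond in c("arthritis", "coronary", "diabetes", "stroke", "cancer")) {
    base <- c(arthritis = -0.5, coronary = -2.4, diabetes = -1.5,
              stroke = -3.4, cancer = -1.2)[[cond]]
    slope <- c(arthritis = 0.45, coronary = 0.25, diabetes = 0.30,
               stroke = 0.60, cancer = 0.02)[[cond]]
    tab[[cond]] <- stats::rbinom(n, 1, stats::plogis(base + slope * (sev - 1)))
  }

  if (isTRUE(config$missingness$enabled)) {
    mrate <- config$missingness
    drop_phq <- stats::runif(n) < mrate$phq9
    for (j in paste0("phq9_", 1:9)) tab[[j]][drop_phq & stats::runif(n) < 0.5] <- NA
    tab$pir[stats::runif(n) < mrate$pir] <- NA
    tab$education[stats::runif(n) < mrate$education] <- NA
    tab$marital[stats::runif(n) < mrate$marital] <- NA
  }

  truth <- list(
    config = config,
    thresholds = item_thresholds(config),
    factor_corr = factor_corr(config),
    factors = drawn$factors,
    crossclass_cat = as.character(cls$crossclass_cat),
    depression_lp = lp_dep, srh_lp = lp_srh,
    planted = list(depression_or = exp(config$depression$log_or),
                   srh_or = exp(config$poor_srh$log_or),
                   joint_targets = config$joint_targets)
  )
  list(table = tab, truth = truth)
}

#' Generate two-day dietary intakes with a category-dependent quality gradient
#'
#' Each respondent gets a diet-quality mixing value on the logistic scale
#' (category effect plus noise); component densities interpolate between a
#' poor-diet and an ideal-diet profile, so expected HEI-2015 decreases with
#' cross-classified severity. A zero gradient gives equal expected totals
#' across categories.
#'
#' @param config \code{fs_sim_config} (its \code{dietary} element is used).
#' @param table classified respondent table (needs \code{crossclass_cat}).
#' @return data.frame of per-day energy and constituent amounts
#'   (\code{*_d1}, \code{*_d2}) suitable for \code{\link{pool_days}}.
#' @export
generate_dietary <- function(config, table) {
  dcfg <- config$dietary
  n <- nrow(table)
  sev <- fs_severity(as.character(table$crossclass_cat))
  mix <- stats::plogis(stats::qlogis(dcfg$base_mix) + dcfg$cat_effect[sev] +
                       stats::rnorm(n, 0, dcfg$mix_sd))
  floor_prof <- c(total_fruits = 0.10, whole_fruits = 0.03,
                  total_vegetables = 0.50, greens_beans = 0.02,
                  whole_grains = 0.15, dairy = 0.30, total_protein = 1.20,
                  seafood_plant_protein = 0.10, fatty_acids = 1.00,
                  refined_grains = 5.00, sodium = 2.30,
                  added_sugars = 20, sat_fat = 14)
  ideal_prof <- c(total_fruits = 0.8, whole_fruits = 0.4,
                  total_vegetables = 1.1, greens_beans = 0.2,
                  whole_grains = 1.5, dairy = 1.3, total_protein = 2.5,
                  seafood_plant_protein = 0.8, fatty_acids = 2.5,
                  refined_grains = 1.8, sodium = 1.1,
                  added_sugars = 6.5, sat_fat = 8)
  out <- data.frame(respondent_id = table$respondent_id)
  energy <- sapply(1:2, function(d)
    stats::rlnorm(n, dcfg$energy_meanlog, dcfg$energy_sdlog))
  out$energy_d1 <- energy[, 1]
  out$energy_d2 <- energy[, 2]
  std <- hei_standards()
  for (comp in names(floor_prof)) {
    dens <- floor_prof[[comp]] + (ideal_prof[[comp]] - floor_prof[[comp]]) * mix
    dens <- dens * stats::rlnorm(n, -0.02, 0.2)
    row <- std[std$component == comp, ]
    for (d in 1:2) {
      e <- energy[, d]
      amt <- switch(row$unit,
        per1000kcal = dens * e / 1000,
        pct_energy = dens * e / (100 * row$energy_per_unit),
        ratio = dens)  # handled below for fatty acids
      if (comp == "fatty_acids") next
      out[[paste0(comp, "_d", d)]] <- amt
    }
    if (comp == "fatty_acids") ratio <- dens
  }
  ## fatty-acid ratio realized through MUFA+PUFA grams against saturated fat
  out$mufa_pufa_d1 <- ratio * out$sat_fat_d1
  out$mufa_pufa_d2 <- ratio * out$sat_fat_d2
  out
}
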