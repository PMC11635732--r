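test_that("generation is deterministic under a fixed seed", {
  cfg <- fs_sim_config(n = 500, seed = 123)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$table, p2$table)
  expect_identical(p1$truth$factors, p2$truth$factors)
  d1 <- generate_dietary(cfg, classify_table(p1$table))
  d2 <- generate_dietary(cfg, classify_table(p2$table))
  # dietary draws consume the generator stream after population generation
  set.seed(99); d1 <- generate_dietary(cfg, classify_table(p1$table))
  set.seed(99); d2 <- generate_dietary(cfg, classify_table(p2$table))
  expect_identical(d1, d2)
})

test_that("weighted joint category shares match the generating model at n = 10,000", {
  cfg <- fs_sim_config(n = 10000, seed = 2024)
  pop <- generate_population(cfg)
  tab <- classify_table(pop$table)
  d <- fs_design(tab$stratum, tab$psu, tab$wtint2yr)
  est <- weighted_prevalence(tab$crossclass_cat, d)
  truth <- cfg$joint_model
  expect_true(all(abs(est$proportion - truth) <= 3 * est$se),
              info = paste(round(est$proportion, 4), collapse = " "))
  # and the calibrated model sits close to the published targets
  expect_true(all(abs(truth - cfg$joint_targets) < 0.02))
})

test_that("planted depression odds ratios are recovered by the weighted fit", {
  cfg <- fs_sim_config(n = 10000, seed = 31415)
  pop <- generate_population(cfg)
  tab <- classify_table(pop$table)
  tab$age_group <- ifelse(tab$age_years >= 70, "70+", "60-69")
  phq <- score_phq9(tab[paste0("phq9_", 1:9)])
  tab$depressed <- phq$depressed
  d <- fs_design(tab$stratum, tab$psu, tab$wtmec2yr)
  fit <- weighted_logistic(depressed ~ crossclass_cat + sex + age_group, tab, d)
  r <- fit$results[grepl("crossclass", fit$results$term), ]
  expect_true(all(abs(r$estimate - cfg$depression$log_or) <= 3 * r$se),
              info = paste(round(exp(r$estimate), 2), collapse = " "))
})

test_that("PHQ-9 item batteries reproduce the planted depression flag exactly", {
  cfg <- fs_sim_config(n = 2000, seed = 8)
  pop <- generate_population(cfg)
  phq <- score_phq9(pop$table[paste0("phq9_", 1:9)])
  sev <- fs_severity(pop$truth$crossclass_cat)
  expect_true(all(phq$total >= 0 & phq$total <= 27))
  # planted gradient visible in the flag rate
  rate <- tapply(phq$depressed, sev, mean)
  expect_true(all(diff(rate) > 0))
})

test_that("zeroing the secondary factors collapses the item structure to one factor", {
  cfg <- fs_sim_config(n = 6000, seed = 5)
  L <- cfg$loadings
  L[, c("physical", "severity")] <- 0
  L[9:10, "resource"] <- 1          # whole-day items join the single factor
  cfg1 <- fs_sim_config(n = 6000, seed = 5, loadings = L,
                        rho_rp = 0, rho_rs = 0, rho_ps = 0)
  # model-implied (noise-free) structure: exactly one eigenvalue above 1
  ev1 <- efa_eigenvalues(model_item_correlation(cfg1))$eigenvalues
  expect_equal(sum(ev1 > 1), 1)

  # and the sampled items reproduce the three-factor structure at defaults
  pop3 <- generate_population(fs_sim_config(n = 6000, seed = 5))
  R3 <- item_correlation(pop3$table[c(paste0("afssm_", 1:10),
                                      paste0("pfs_", 1:6))])$R
  expect_gte(sum(efa_eigenvalues(R3)$eigenvalues > 1), 3)
})

test_that("the truth ledger suffices to recompute planted quantities independently", {
  cfg <- fs_sim_config(n = 3000, seed = 77)
  pop <- generate_population(cfg)
  truth <- pop$truth
  # items reproducible from thresholds? categories recorded in the ledger
  # must agree with an independent re-derivation from the table
  tab <- classify_table(pop$table)
  expect_equal(as.character(tab$crossclass_cat), truth$crossclass_cat)
  expect_equal(truth$planted$depression_or, c(2.92, 6.36, 14.6))
  expect_equal(dim(truth$factors), c(3000, 3))
  expect_equal(length(truth$thresholds), 16)
  # planted linear predictors regenerate the flag probabilities
  expect_true(all(plogis(truth$depression_lp) > 0 &
                  plogis(truth$depression_lp) < 1))
})

test_that("dietary generator plants a monotone HEI gradient; zero gradient is flat", {
  cfg <- fs_sim_config(n = 8000, seed = 12)
  pop <- generate_population(cfg)
  tab <- classify_table(pop$table)
  diet <- generate_dietary(cfg, tab)
  hei <- score_hei(pool_days(diet[-1]))
  m <- tapply(hei$hei_total, tab$crossclass_cat, mean)
  expect_true(all(diff(m) < 0))  # High > Marginal > Low > VeryLow

  cfg0 <- cfg
  cfg0$dietary$cat_effect <- c(0, 0, 0, 0)
  diet0 <- generate_dietary(cfg0, tab)
  hei0 <- score_hei(pool_days(diet0[-1]))
  m0 <- tapply(hei0$hei_total, tab$crossclass_cat, mean)
  expect_lt(max(m0) - min(m0), 1.0)  # no systematic gradient
})

test_that("missingness injection produces the exclusion structure when enabled", {
  cfg <- fs_sim_config(n = 4000, seed = 13)
  cfg$missingness$enabled <- TRUE
  pop <- generate_population(cfg)
  phq <- score_phq9(pop$table[paste0("phq9_", 1:9)])
  expect_gt(sum(is.na(phq$total)), 0)
  expect_gt(sum(is.na(pop$table$pir)), 0)
  # the default configuration stays complete
  pop0 <- generate_population(fs_sim_config(n = 1000, seed = 13))
  expect_equal(sum(is.na(pop0$table$pir)), 0)
})

test_that("infeasible calibration targets are rejected", {
  cfg <- fs_sim_config()
  cfg$joint_targets <- c(High = 0.9, Marginal = 0.3, Low = 0.1, VeryLow = 0.1)
  expect_error(calibrate_thresholds(cfg, n_calib = 1000), "sum to 1")
})
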