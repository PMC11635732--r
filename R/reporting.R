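#' Read a pipeline run configuration from YAML
#'
#' Builds an \code{fs_sim_config} from a YAML file of overrides (see
#' \code{inst/extdata/run_config_example.yaml}); fields not listed keep
#' their calibrated defaults. A \code{compare_reps} entry, if present, is
#' returned as an attribute for \code{\link{run_pipeline}}.
#'
#' @param path YAML file.
#' @return an \code{fs_sim_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  reps <- cfg$compare_reps
  cfg$compare_reps <- NULL
  ## sample size travels as n_respondents ("n" is a YAML 1.1 boolean)
  if (!is.null(cfg$n_respondents)) {
    cfg$n <- cfg$n_respondents
    cfg$n_respondents <- NULL
  }
  out <- do.call(fs_sim_config, cfg)
  attr(out, "compare_reps") <- if (is.null(reps)) 0 else reps
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates generation (or ingestion), scale scoring, cross-
#' classification, and the design-based analyses into the report surfaces of
#' the study: a three-approach prevalence table, a sociodemographic
#' cross-tabulation with Rao-Scott tests, an outcomes cross-tabulation, an
#' odds-ratio table for depression and poor self-reported health under both
#' classification methods, and the HEI-2015 coefficient table. Deterministic
#' given the config seed.
#'
#' @param config \code{fs_sim_config}; its seed drives all randomness.
#' @param table optional pre-built respondent table (bypasses generation);
#'   must carry item batteries, demographics, and two-year weights.
#' @param compare_reps bootstrap replicates for the cross-model coefficient
#'   comparison (0 skips the comparison).
#' @return list of class \code{fs_report}.
#' @export
run_pipeline <- function(config = fs_sim_config(), table = NULL,
                         compare_reps = 0) {
  if (is.null(table)) {
    pop <- generate_population(config)
    table <- pop$table
  }
  table <- apply_inclusion_filter(table)
  exclusions <- attr(table, "exclusions")
  table <- classify_table(table)
  table <- build_multiyear_weights(table, config$n_cycles)
  table <- derive_flags(table)
  phq <- score_phq9(table[paste0("phq9_", 1:9)])
  table$phq9_total <- phq$total
  table$depressed <- phq$depressed

  des <- function(kind) fs_design(table$stratum, table$psu,
                                  table[[select_weight(kind)]])
  d_int <- des("interview")
  d_mec <- des("mec")
  d_diet <- des("dietary")

  ## Prevalence under the three classification approaches
  prev <- do.call(rbind, lapply(
    c(crossclass = "crossclass_cat", afssm = "afssm_cat", pfs = "pfs_cat"),
    function(col) weighted_prevalence(table[[col]], d_int)))
  prev$approach <- rep(c("crossclass", "afssm", "pfs"), each = 4)
  prev <- prev[c("approach", setdiff(names(prev), "approach"))]

  subcats <- tabulate_subcategories(table$afssm_cat, table$pfs_cat)

  ## Sociodemographics by cross-classified status (interview weight)
  table$age_group <- ifelse(table$age_years >= 70, "70+", "60-69")
  socio_vars <- c("sex", "age_group", "race_ethnicity", "marital",
                  "household_size", "education", "pir_low")
  socio <- lapply(socio_vars, function(v)
    crosstab_with_test(table[[v]], table$crossclass_cat, d_int, v))
  socio <- do.call(rbind, socio)

  ## Health outcomes by status (MEC weight)
  out_vars <- c("arthritis", "coronary", "diabetes", "stroke", "cancer",
                "significant_weight_loss", "depression_difficulty",
                "appetite_problem", "depressed", "poor_srh")
  outcomes <- lapply(out_vars, function(v)
    crosstab_with_test(table[[v]], table$crossclass_cat, d_mec, v))
  outcomes <- do.call(rbind, outcomes)

  ## Odds ratios, both methods, both outcomes (MEC weight), adjusted
  adj <- ~ age_years + sex + race_ethnicity + marital + education
  or_rows <- list()
  fits <- list()
  methods <- c(crossclass = "crossclass_cat", afssm = "afssm_cat")
  for (outv in c("depressed", "poor_srh")) {
    for (mname in names(methods)) {
      f <- stats::as.formula(paste(outv, "~", methods[[mname]], "+",
                                   as.character(adj)[2]))
      fit <- weighted_logistic(f, table, d_mec)
      r <- fit$results
      r <- r[grepl("_cat", r$term), ]
      r$outcome <- outv
      r$method <- mname
      or_rows[[paste(outv, mname)]] <- r
      fits[[paste(outv, mname)]] <- fit
    }
  }
  or_table <- do.call(rbind, c(or_rows, make.row.names = FALSE))

  ## HEI-2015 (dietary weight)
  diet <- generate_dietary(config, table)
  pooled <- pool_days(diet[-1])
  hei <- score_hei(pooled)
  table$hei_total <- hei$hei_total
  hei_means <- design_group_means(table$hei_total, table$crossclass_cat, d_diet)
  hei_ttests <- design_ttest_bonferroni(table$hei_total, table$crossclass_cat,
                                        d_diet, m = 6)
  hei_fit_cc <- weighted_linear(
    stats::as.formula(paste("hei_total ~ crossclass_cat +",
                            as.character(adj)[2])), table, d_diet)
  hei_fit_af <- weighted_linear(
    stats::as.formula(paste("hei_total ~ afssm_cat +",
                            as.character(adj)[2])), table, d_diet)
  hei_compare <- if (compare_reps > 0) {
    compare_models(rename_exposure(hei_fit_cc), rename_exposure(hei_fit_af),
                   reps = compare_reps, seed = config$seed + 1)
  } else NULL

  ## dimensionality diagnostics on the 16 items
  it <- item_correlation(table[c(paste0("afssm_", 1:10), paste0("pfs_", 1:6))])
  efa <- efa_eigenvalues(it$R)
  diag_tab <- list(kmo = kmo(it$R)$overall,
                   bartlett = bartlett_sphericity(it$R, it$n_effective),
                   eigenvalues = efa$eigenvalues,
                   n_factors = efa$n_retained)

  structure(list(
    n = nrow(table), exclusions = exclusions,
    prevalence = prev, subcategories = subcats,
    sociodemographics = socio, outcomes = outcomes,
    odds_ratios = or_table,
    hei_means = hei_means, hei_ttests = hei_ttests,
    hei_coefficients = rbind(
      cbind(method = "crossclass",
            hei_fit_cc$results[grepl("_cat", hei_fit_cc$results$term), ]),
      cbind(method = "afssm",
            hei_fit_af$results[grepl("_cat", hei_fit_af$results$term), ])),
    hei_model_comparison = hei_compare,
    diagnostics = diag_tab,
    fits = fits, seed = config$seed
  ), class = "fs_report")
}

## rename the exposure factor so the two HEI models share severity terms
rename_exposure <- function(fit) {
  res <- fit$results
  res$term <- sub("^(crossclass|afssm)_cat", "fs", res$term)
  fit$results <- res
  v <- all.vars(fit$formula)
  expo <- grep("_cat$", v, value = TRUE)
  names(fit$data)[names(fit$data) == expo] <- "fs"
  fit$formula <- stats::as.formula(
    sub(expo, "fs", paste(deparse(fit$formula), collapse = " ")))
  fit
}

## weighted column-percent cross-tab plus a Rao-Scott test
crosstab_with_test <- function(x, status, design, varname) {
  keep <- !is.na(x) & !is.na(status)
  if (is.logical(x)) x <- ifelse(x, "yes", "no")
  x2 <- factor(x[keep])
  s2 <- droplevels(factor(status[keep], levels = fs_levels))
  d2 <- design_subset(design, keep)
  rs <- rao_scott_test(x2, s2, d2)
  props <- prop_by_col(x2, s2, d2$weights)
  rows <- expand.grid(level = rownames(props), status = colnames(props),
                      stringsAsFactors = FALSE)
  data.frame(variable = varname, level = rows$level, status = rows$status,
             pct = 100 * props[cbind(rows$level, rows$status)],
             n = sum(keep), p_value = rs$p.value)
}

prop_by_col <- function(x, status, w) {
  num <- tapply(w, list(x, status), sum, default = 0)
  sweep(num, 2, colSums(num), "/")
}

## design-weighted group means with linearized SE and t CIs
design_group_means <- function(y, group, design, conf = 0.95) {
  keep <- !is.na(y) & !is.na(group)
  y <- y[keep]
  g <- droplevels(factor(group[keep]))
  d2 <- design_subset(design, keep)
  df <- degf(d2)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  rows <- lapply(levels(g), function(lv) {
    m <- wmean_influence(y, as.numeric(g == lv), d2$weights)
    v <- psu_covariance(matrix(m$U, ncol = 1), d2)[1, 1]
    data.frame(group = lv, n = sum(g == lv), mean = m$mean, se = sqrt(v),
               ci_lower = m$mean - tcrit * sqrt(v),
               ci_upper = m$mean + tcrit * sqrt(v))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @export
print.fs_report <- function(x, ...) {
  cat("Cross-classified food security analysis (n =", x$n, ")\n\n")
  cat("Weighted prevalence (%) by approach:\n")
  p <- x$prevalence
  p$pct <- round(100 * p$proportion, 1)
  print(stats::reshape(p[c("approach", "category", "pct")],
                       direction = "wide", idvar = "approach",
                       timevar = "category"), row.names = FALSE)
  cat("\nKMO:", round(x$diagnostics$kmo, 3),
      "; Bartlett p:", format.pval(x$diagnostics$bartlett$p.value),
      "; eigenvalues > 1:", x$diagnostics$n_factors, "\n")
  invisible(x)
}

#' Write the analysis report to CSV tables plus run metadata
#'
#' @param report \code{fs_report}; @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  wr(report$prevalence, "table2_prevalence")
  wr(as.data.frame(report$subcategories), "appendix_subcategories")
  wr(report$sociodemographics, "table3_sociodemographics")
  wr(report$outcomes, "table4_outcomes")
  wr(report$odds_ratios, "figure2_odds_ratios")
  wr(report$hei_means, "table4_hei_means")
  wr(report$hei_coefficients, "hei_coefficients")
  meta <- list(n = report$n, seed = report$seed,
               exclusions = as.list(report$exclusions),
               kmo = report$diagnostics$kmo,
               bartlett_p = report$diagnostics$bartlett$p.value,
               eigenvalues = report$diagnostics$eigenvalues)
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
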