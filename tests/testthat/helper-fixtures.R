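# shared fixtures built in code

# self-representing design: one observation per PSU, single stratum, equal
# weights -- estimators must reduce to their classical SRS forms
srs_design <- function(n, w = 1) {
  fs_design(strata = rep(1, n), psu = seq_len(n), weights = rep(w, n))
}

# small clustered design for variance paths
clustered_design <- function(n, n_strata = 5, psus = 2, seed = NULL,
                             weight_cv = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  strata <- sample(seq_len(n_strata), n, replace = TRUE)
  psu <- sample(seq_len(psus), n, replace = TRUE)
  sdlog <- sqrt(log(1 + weight_cv^2))
  w <- rlnorm(n, -sdlog^2 / 2, sdlog)
  fs_design(strata, psu, w)
}

# a respondent table with complete batteries for filter/classify tests
make_item_table <- function(afssm_raw, pfs_raw, age = 70) {
  n <- length(afssm_raw)
  stopifnot(length(pfs_raw) == n)
  tab <- data.frame(respondent_id = seq_len(n), age_years = rep(age, n))
  for (j in 1:10) tab[[paste0("afssm_", j)]] <- as.numeric(j <= afssm_raw)
  for (j in 1:6) tab[[paste0("pfs_", j)]] <- as.numeric(j <= pfs_raw)
  tab
}

# the published 4x4 joint-category lookup, frozen as an independent oracle
# (rows = PFS category, columns = AFSSM category)
joint_lookup <- matrix(
  c("High",     "Marginal", "Low", "VeryLow",
    "Marginal", "Marginal", "Low", "VeryLow",
    "Low",      "Low",      "Low", "VeryLow",
    "VeryLow",  "VeryLow",  "VeryLow", "VeryLow"),
  nrow = 4, byrow = TRUE,
  dimnames = list(pfs = fs_levels, afssm = fs_levels))
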