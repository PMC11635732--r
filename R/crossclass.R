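#' Cross-classify the two food-security scales into one joint status
#'
#' The joint severity is the more severe of the two scale categories: a
#' respondent is jointly high food secure only when high on both the
#' resource-constraint (AFSSM) and physical (PFS) scales, and jointly very
#' low food secure when very low on either. This is the maximum-severity
#' rule over the 4x4 grid of category pairs.
#'
#' @param afssm_cat,pfs_cat vectors of categories in \code{fs_levels}
#'   (character or factor). Missing input yields missing output.
#' @return ordered factor of joint categories with levels \code{fs_levels}.
#'   The display labels in \code{crossclass_labels} give the conventional
#'   joint names (e.g. "LFS/L-PFS").
#' @export
cross_classify <- function(afssm_cat, pfs_cat) {
  sa <- fs_severity(as.character(afssm_cat))
  sp <- fs_severity(as.character(pfs_cat))
  joint <- pmax(sa, sp)
  fs_factor(fs_levels[joint])
}

#' Cross-classify from raw scores
#'
#' Composes the two raw-score categorizations with the maximum-severity
#' joint rule, covering all 11 x 7 = 77 raw-score pairs.
#'
#' @param afssm_raw integer 0..10; @param pfs_raw integer 0..6.
#' @return ordered factor of joint categories.
#' @export
cross_classify_raw <- function(afssm_raw, pfs_raw) {
  cross_classify(categorize_afssm(afssm_raw), categorize_pfs(pfs_raw))
}

#' Tabulate the 16 cross-classification subcategories
#'
#' Counts respondents over the 4x4 grid of (AFSSM category, PFS category)
#' cells. Row and column sums are the marginal category counts; the grand
#' total is the number of classified respondents.
#'
#' @param afssm_cat,pfs_cat category vectors (pairs with any missing value
#'   are dropped).
#' @return 4x4 integer matrix, rows = PFS category, columns = AFSSM category.
#' @export
tabulate_subcategories <- function(afssm_cat, pfs_cat) {
  a <- fs_factor(as.character(afssm_cat))
  p <- fs_factor(as.character(pfs_cat))
  keep <- !is.na(a) & !is.na(p)
  table(pfs = p[keep], afssm = a[keep])
}

#' Classify a scored respondent table
#'
#' Adds raw scores, per-scale categories, and the joint cross-classified
#' category to a respondent table carrying the item batteries.
#'
#' @param table data.frame with columns \code{afssm_1..afssm_10} (0/1) and
#'   \code{pfs_1..pfs_6} (0/1 affirmative indicators).
#' @return the table with columns \code{afssm_raw}, \code{afssm_cat},
#'   \code{pfs_raw}, \code{pfs_cat}, \code{crossclass_cat} appended.
#' @export
classify_table <- function(table) {
  a_items <- table[paste0("afssm_", 1:10)]
  p_items <- table[paste0("pfs_", 1:6)]
  table$afssm_raw <- raw_score(a_items)
  table$pfs_raw <- raw_score(p_items)
  table$afssm_cat <- categorize_afssm(table$afssm_raw)
  table$pfs_cat <- categorize_pfs(table$pfs_raw)
  table$crossclass_cat <- cross_classify(table$afssm_cat, table$pfs_cat)
  table
}
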