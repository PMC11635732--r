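#' Ordered food-security severity levels
#'
#' The four severity categories shared by the resource-constraint scale
#' (AFSSM), the physical food security scale (PFS), and the cross-classified
#' joint status, ordered from least to most severe.
#'
#' @format Character vector of length 4.
#' @export
fs_levels <- c("High", "Marginal", "Low", "VeryLow")

#' Display labels for the cross-classified categories
#'
#' @format Named character vector mapping severity level to the joint label.
#' @export
crossclass_labels <- c(
  High     = "HFS/H-PFS",
  Marginal = "MFS/M-PFS",
  Low      = "LFS/L-PFS",
  VeryLow  = "VLFS/VL-PFS"
)

#' Severity rank of a food-security category
#'
#' @param category character vector of values in \code{fs_levels}.
#' @return integer severity rank (1 = High ... 4 = VeryLow); NA propagates.
#' @export
fs_severity <- function(category) {
  out <- match(category, fs_levels)
  bad <- !is.na(category) & is.na(out)
  if (any(bad)) {
    stop("unknown food-security category: ", paste(unique(category[bad]), collapse = ", "))
  }
  out
}

fs_factor <- function(category) {
  factor(category, levels = fs_levels, ordered = TRUE)
}

#' Categorize an AFSSM raw score
#'
#' Maps the adult food security raw score (number of affirmative responses to
#' the 10 resource-constraint items) to the four-level severity category:
#' 0 affirmations is high food security, 1-2 marginal, 3-5 low, and 6-10
#' very low.
#'
#' @param raw integer vector of raw scores in 0..10; NA allowed (propagates).
#' @return ordered factor with levels \code{fs_levels}.
#' @export
categorize_afssm <- function(raw) {
  ok <- is.na(raw) | (raw >= 0 & raw <= 10 & raw == floor(raw))
  if (!all(ok)) stop("AFSSM raw score must be an integer in [0, 10]")
  cat <- ifelse(raw == 0, "High",
         ifelse(raw <= 2, "Marginal",
         ifelse(raw <= 5, "Low", "VeryLow")))
  fs_factor(cat)
}

#' Categorize a PFS raw score
#'
#' Maps the physical food security raw score (number of the 6 food-related
#' physical functioning items answered with any level of difficulty) to the
#' severity category: 0 high, 1-2 marginal, 3-4 low, 5-6 very low.
#'
#' @param raw integer vector of raw scores in 0..6; NA allowed (propagates).
#' @return ordered factor with levels \code{fs_levels}.
#' @export
categorize_pfs <- function(raw) {
  ok <- is.na(raw) | (raw >= 0 & raw <= 6 & raw == floor(raw))
  if (!all(ok)) stop("PFS raw score must be an integer in [0, 6]")
  cat <- ifelse(raw == 0, "High",
         ifelse(raw <= 2, "Marginal",
         ifelse(raw <= 4, "Low", "VeryLow")))
  fs_factor(cat)
}

#' Raw score for a battery of binary items
#'
#' Counts affirmative responses across the columns of an item matrix. The
#' raw score is defined only for respondents with every item observed;
#' any missing item yields NA.
#'
#' @param items numeric matrix or data.frame of 0/1 indicators
#'   (rows = respondents).
#' @return integer vector of raw scores with NA where any item is missing.
#' @export
raw_score <- function(items) {
  items <- as.matrix(items)
  if (!all(items %in% c(0, 1, NA))) stop("items must be coded 0/1 (or NA)")
  n_miss <- rowSums(is.na(items))
  out <- rowSums(items)
  out[n_miss > 0] <- NA
  as.integer(out)
}

#' Dichotomize PFS item responses
#'
#' PFS items are asked on a four-level difficulty scale; a response of
#' "some difficulty", "much difficulty", or "unable to do" is affirmative,
#' "no difficulty" is negative.
#'
#' @param items matrix/data.frame of responses coded 0 (no difficulty),
#'   1 (some), 2 (much), 3 (unable), or NA.
#' @return 0/1 matrix of affirmative indicators (NA preserved).
#' @export
pfs_affirmative <- function(items) {
  items <- as.matrix(items)
  if (!all(items %in% c(0, 1, 2, 3, NA))) {
    stop("PFS items must be coded 0..3 (no difficulty .. unable) or NA")
  }
  out <- (items >= 1) * 1
  out
}

#' Score the PHQ-9 depression screener
#'
#' Sums the nine item scores (0-3 each) into a 0-27 total and applies the
#' conventional cutoff of 10 for the presence of depression. Respondents
#' with any missing item are excluded (NA total, NA flag) rather than scored.
#'
#' @param items matrix/data.frame with 9 columns of item scores in 0..3.
#' @return data.frame with columns \code{total} (integer, NA if any item
#'   missing) and \code{depressed} (logical).
#' @param cutoff total score at or above which depression is flagged
#'   (default 10).
#' @export
score_phq9 <- function(items, cutoff = 10) {
  items <- as.matrix(items)
  if (ncol(items) != 9) stop("PHQ-9 requires exactly 9 items")
  if (!all(items %in% c(0, 1, 2, 3, NA))) stop("PHQ-9 items must be in 0..3 or NA")
  complete <- rowSums(is.na(items)) == 0
  total <- ifelse(complete, rowSums(items), NA)
  data.frame(total = as.integer(total), depressed = total >= cutoff)
}

#' Derive the dichotomized analysis variables
#'
#' Computes the analysis flags from their source fields:
#' \itemize{
#'   \item \code{significant_weight_loss}: lost at least 10\% of body weight
#'     relative to the weight one year ago (inclusive boundary).
#'   \item \code{poor_srh}: self-reported health of "fair" or "poor" versus
#'     "excellent"/"very good"/"good".
#'   \item \code{pir_low}: income-to-poverty ratio at or below 1.85.
#'   \item \code{appetite_problem} / \code{depression_difficulty}: any
#'     reported difficulty ("somewhat", "very", "extremely") versus none.
#' }
#' Each flag is NA when its source field is missing.
#'
#' @param record data.frame with columns (any subset used):
#'   \code{weight_now}, \code{weight_1y_ago} (positive), \code{srh}
#'   (1=excellent..5=poor), \code{pir}, \code{appetite} and
#'   \code{depression_difficulty_src} (0=not at all .. 3=extremely).
#' @return the input with flag columns appended.
#' @export
derive_flags <- function(record) {
  out <- record
  if (all(c("weight_now", "weight_1y_ago") %in% names(record))) {
    w0 <- record$weight_1y_ago
    if (any(!is.na(w0) & w0 <= 0)) stop("weight one year ago must be positive")
    loss <- (w0 - record$weight_now) / w0
    out$significant_weight_loss <- loss >= 0.10
  }
  if ("srh" %in% names(record)) {
    if (any(!is.na(record$srh) & !(record$srh %in% 1:5))) {
      stop("srh must be coded 1 (excellent) .. 5 (poor)")
    }
    out$poor_srh <- record$srh >= 4
  }
  if ("pir" %in% names(record)) {
    out$pir_low <- record$pir <= 1.85
  }
  if ("appetite" %in% names(record)) {
    out$appetite_problem <- record$appetite >= 1
  }
  if ("depression_difficulty_src" %in% names(record)) {
    out$depression_difficulty <- record$depression_difficulty_src >= 1
  }
  out
}
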