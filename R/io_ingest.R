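#' Read a variable-map configuration
#'
#' A variable map harmonizes survey-cycle-specific column names and codes
#' into the logical variables the analysis uses. YAML layout:
#' \preformatted{
#' variables:
#'   education:
#'     cycles: {default: DMDEDUC2, "2007-2008": DMDEDUC2}
#'     recode: {"1": 1, "2": 1, "3": 2, "4": 3, "5": 3,
#'              "7": refused, "9": dont_know}
#' }
#' \code{cycles} maps each survey cycle to the source column (a
#' \code{default} entry covers unlisted cycles); \code{recode}, if present,
#' must cover every declared source code and may map codes to the sentinel
#' states \code{missing}, \code{refused}, \code{dont_know}, all of which are
#' stored as NA with the reason retained.
#'
#' @param path YAML file path.
#' @return list of class \code{fs_variable_map}.
#' @export
read_variable_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_variable_map(cfg)
}

#' Construct a variable map from a list
#'
#' @param cfg list with a \code{variables} element (see
#'   \code{\link{read_variable_map}}).
#' @return validated \code{fs_variable_map}.
#' @export
as_variable_map <- function(cfg) {
  if (is.null(cfg$variables) || !length(cfg$variables)) {
    stop("variable map must declare at least one variable")
  }
  for (v in names(cfg$variables)) {
    spec <- cfg$variables[[v]]
    if (is.null(spec$cycles) || !length(spec$cycles)) {
      stop("variable '", v, "' declares no source column")
    }
  }
  structure(cfg, class = "fs_variable_map")
}

MISSING_SENTINELS <- c("missing", "refused", "dont_know")
SCREENED_SENTINEL <- "screened"

source_column <- function(map, variable, cycle) {
  cyc <- map$variables[[variable]]$cycles
  col <- cyc[[cycle]]
  if (is.null(col)) col <- cyc[["default"]]
  if (is.null(col)) {
    stop("variable '", variable, "' has no source column for cycle '", cycle, "'")
  }
  col
}

apply_recode <- function(x, recode, variable) {
  if (is.null(recode)) {
    return(list(values = x, reason = rep(NA_character_, length(x))))
  }
  key <- as.character(x)
  known <- key %in% names(recode) | is.na(x)
  if (any(!known)) {
    stop("variable '", variable, "' has undeclared source code(s): ",
         paste(unique(key[!known]), collapse = ", "))
  }
  coded <- rep(NA_character_, length(x))
  coded[!is.na(x)] <- vapply(key[!is.na(x)],
                             function(k) as.character(recode[[k]]), "")
  reason <- ifelse(coded %in% c(MISSING_SENTINELS, SCREENED_SENTINEL),
                   coded, NA_character_)
  reason[is.na(x)] <- "missing"
  vals <- coded
  vals[coded %in% MISSING_SENTINELS] <- NA
  num <- suppressWarnings(as.numeric(vals))
  if (all(is.na(num) == is.na(vals))) vals <- num
  list(values = vals, reason = reason)
}

#' Read respondent-level microdata
#'
#' Reads a CSV or SAS transport (XPT) file, harmonizes column names via the
#' variable map for the given cycle, applies code recodes (converting the
#' sentinel states missing/refused/don't-know to typed NA), and returns one
#' record per row. Unmapped source columns are ignored.
#'
#' @param path input file.
#' @param format "csv" or "xpt" (XPT is read-only, as published by NHANES).
#' @param variable_map an \code{fs_variable_map}.
#' @param cycle survey-cycle label used to resolve source columns; also
#'   stored in the output's \code{cycle} column.
#' @param screened_as how to treat item codes recoded to the sentinel
#'   \code{screened} (household screener skip patterns): "negative"
#'   (default, scored as a negative response) or "missing".
#' @return data.frame of logical variables with attribute
#'   \code{missing_reasons}: a data.frame (row, variable, reason) recording
#'   why each NA cell is missing.
#' @export
read_microdata <- function(path, format = c("csv", "xpt"), variable_map,
                           cycle = "default",
                           screened_as = c("negative", "missing")) {
  format <- match.arg(format)
  screened_as <- match.arg(screened_as)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE),
    xpt = as.data.frame(haven::read_xpt(path))
  )
  vars <- names(variable_map$variables)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  reasons <- list()
  for (v in vars) {
    col <- source_column(variable_map, v, cycle)
    if (!col %in% names(raw)) {
      stop("mapped source column '", col, "' (variable '", v,
           "') not present in ", path)
    }
    rec <- apply_recode(raw[[col]], variable_map$variables[[v]]$recode, v)
    scr <- !is.na(rec$reason) & rec$reason == SCREENED_SENTINEL
    if (any(scr)) {
      rec$values[scr] <- if (screened_as == "negative") 0 else NA
      if (screened_as == "negative") rec$reason[scr] <- NA_character_
      rec$values <- suppressWarnings(as.numeric(rec$values))
    }
    out[[v]] <- rec$values
    hit <- which(!is.na(rec$reason))
    if (length(hit)) {
      reasons[[v]] <- data.frame(row = hit, variable = v,
                                 reason = rec$reason[hit])
    }
  }
  out$cycle <- cycle
  attr(out, "missing_reasons") <-
    if (length(reasons)) do.call(rbind, c(reasons, make.row.names = FALSE))
    else data.frame(row = integer(), variable = character(),
                    reason = character())
  out
}

#' Pool cycle tables into one analysis table
#'
#' Concatenates already-recoded cycle tables; all tables must share the same
#' logical columns. The per-table \code{cycle} column is retained for
#' multiyear weight construction.
#'
#' @param ... data.frames from \code{read_microdata}, or a single list of them.
#' @return pooled data.frame.
#' @export
pool_cycles <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  cols <- lapply(tabs, function(t) sort(names(t)))
  if (length(unique(vapply(cols, paste, "", collapse = ","))) != 1) {
    stop("cycle tables have differing logical columns; check the variable map")
  }
  do.call(rbind, c(lapply(tabs, function(t) t[names(tabs[[1]])]),
                   make.row.names = FALSE))
}

#' Write a microdata table as CSV
#'
#' Doubles are written with 17 significant digits so that a write-read
#' round trip reproduces every value bit-exactly.
#'
#' @param table data.frame; @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_microdata <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- sprintf("%.17g", out[[j]])
      x[is.na(out[[j]])] <- NA
      out[[j]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a microdata table written by \code{write_microdata}
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_microdata_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, na.strings = "")
}

#' Apply the analytic inclusion filter
#'
#' Retains respondents aged 60 years or older with complete data on both
#' food-security item batteries (all 10 AFSSM items and all 6 PFS items
#' observed). Each excluded record is tallied under exactly one reason,
#' assessed in the order age, AFSSM completeness, PFS completeness.
#'
#' @param table data.frame with \code{age_years}, \code{afssm_1..10},
#'   \code{pfs_1..6}.
#' @return the filtered table, with attribute \code{exclusions}: named
#'   integer vector of counts for reasons \code{age_under_60},
#'   \code{afssm_incomplete}, \code{pfs_incomplete}.
#' @export
apply_inclusion_filter <- function(table) {
  need <- c("age_years", paste0("afssm_", 1:10), paste0("pfs_", 1:6))
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks required columns: ",
                         paste(miss, collapse = ", "))
  age_ok <- !is.na(table$age_years) & table$age_years >= 60
  afssm_ok <- rowSums(is.na(table[paste0("afssm_", 1:10)])) == 0
  pfs_ok <- rowSums(is.na(table[paste0("pfs_", 1:6)])) == 0
  reason <- rep(NA_character_, nrow(table))
  reason[!pfs_ok] <- "pfs_incomplete"
  reason[!afssm_ok] <- "afssm_incomplete"
  reason[!age_ok] <- "age_under_60"
  keep <- is.na(reason)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  tally <- c(age_under_60 = sum(reason == "age_under_60", na.rm = TRUE),
             afssm_incomplete = sum(reason == "afssm_incomplete", na.rm = TRUE),
             pfs_incomplete = sum(reason == "pfs_incomplete", na.rm = TRUE))
  attr(out, "exclusions") <- tally
  out
}
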