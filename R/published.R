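#' Published prevalence estimates (NHANES 2007-2018, adults 60+)
#'
#' The published unweighted frequencies and weighted percentages of the four
#' food-security categories under the three classification approaches
#' (cross-classified, resource-constraint AFSSM, physical PFS) for the
#' 10,237 respondents of the 2007-2018 pooled analysis. These printed
#' estimates are inputs to the arithmetic consistency and dominance checks;
#' they are not reproducible from synthetic data.
#'
#' @return data.frame with approach, category, n, weighted_pct.
#' @export
published_prevalence <- function() {
  utils::read.csv(system.file("extdata", "published_prevalence_2007_2018.csv",
                              package = "foodsecx"),
                  stringsAsFactors = FALSE)
}

#' Published dietary-recall sample flow
#'
#' The published dietary analysis retained 8,163 respondents with two
#' complete, reliable recalls; 6 lacked total energy, leaving 8,157 scored.
#'
#' @return named list with complete_recalls, missing_energy, scored.
#' @export
published_dietary_flow <- function() {
  list(complete_recalls = 8163, missing_energy = 6,
       scored = 8163 - 6)
}
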