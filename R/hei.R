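#' Load the HEI-2015 scoring standards
#'
#' The 13-component Healthy Eating Index 2015 standards are bundled as an
#' editable CSV: for each component its maximum points (totalling 100), its
#' direction (adequacy components reward intake, moderation components reward
#' restraint), the density unit (amount per 1,000 kcal, percent of energy, or
#' the unitless fatty-acid ratio), and the densities at which the score hits
#' zero and the maximum. \code{energy_per_unit} converts amounts to kcal for
#' the percent-of-energy components (16 kcal per teaspoon of added sugars,
#' 9 kcal per gram of saturated fat).
#'
#' @param path optional path to an alternative standards CSV.
#' @return data.frame of scoring standards.
#' @export
hei_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hei2015_standards.csv", package = "foodsecx")
  }
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(std$zero_standard == std$full_standard)) {
    stop("malformed standards: zero and full standards coincide for ",
         paste(std$component[std$zero_standard == std$full_standard],
               collapse = ", "))
  }
  if (sum(std$max_points) != 100) stop("component maxima must total 100")
  std
}

#' HEI component names (in standards order)
#' @return character vector of the 13 component names.
#' @export
hei_components <- function() hei_standards()$component

#' Pool two days of dietary recall into per-person totals
#'
#' The per-person simple scoring method sums the two days' energy and
#' constituent amounts before forming densities. Respondents missing either
#' day are marked unscorable ("incomplete_recall"); respondents with zero
#' pooled energy are unscorable ("zero_energy").
#'
#' @param intake data.frame with columns \code{energy_d1}, \code{energy_d2}
#'   and \code{<component>_d1}, \code{<component>_d2} for each of the 13
#'   components (fatty acids enter as \code{mufa_pufa} grams together with
#'   \code{sat_fat} grams).
#' @return data.frame with pooled \code{energy}, one column per constituent,
#'   \code{scorable} (logical) and \code{unscorable_reason}.
#' @export
pool_days <- function(intake) {
  comps <- setdiff(hei_components(), "fatty_acids")
  constituents <- c("energy", comps, "mufa_pufa")
  out <- data.frame(row.names = seq_len(nrow(intake)))
  any_missing <- rep(FALSE, nrow(intake))
  for (v in constituents) {
    d1 <- intake[[paste0(v, "_d1")]]
    d2 <- intake[[paste0(v, "_d2")]]
    if (is.null(d1) || is.null(d2)) stop("intake lacks both days of: ", v)
    if (any(c(d1, d2) < 0, na.rm = TRUE)) stop("negative amount in: ", v)
    any_missing <- any_missing | is.na(d1) | is.na(d2)
    out[[v]] <- d1 + d2
  }
  reason <- rep(NA_character_, nrow(intake))
  reason[!is.na(out$energy) & out$energy == 0] <- "zero_energy"
  reason[any_missing] <- "incomplete_recall"
  out$scorable <- is.na(reason)
  out$unscorable_reason <- reason
  out
}

#' Score one HEI component
#'
#' Forms the density of the constituent (per 1,000 kcal, percent of energy,
#' or the fatty-acid ratio passed directly) and interpolates linearly between
#' the zero-score and full-score standards, clipping to [0, max points].
#' Moderation components have their zero standard above their full standard,
#' so the same interpolation scores them inversely.
#'
#' @param amount constituent amount (for unit "ratio", the ratio itself).
#' @param energy pooled energy in kcal (> 0 for energy-based densities).
#' @param standard one row of \code{hei_standards()}.
#' @return numeric score in [0, max points].
#' @export
score_component <- function(amount, energy, standard) {
  if (standard$zero_standard == standard$full_standard) {
    stop("malformed standard for ", standard$component)
  }
  density <- switch(standard$unit,
    per1000kcal = {
      stopifnot(all(energy > 0))
      amount / (energy / 1000)
    },
    pct_energy = {
      stopifnot(all(energy > 0))
      100 * amount * standard$energy_per_unit / energy
    },
    ratio = amount,
    stop("unknown unit: ", standard$unit)
  )
  frac <- (density - standard$zero_standard) /
    (standard$full_standard - standard$zero_standard)
  standard$max_points * pmin(1, pmax(0, frac))
}

#' Score the HEI-2015 for pooled intakes
#'
#' Computes the 13 component scores and their total (0-100) for each
#' scorable record; unscorable records (missing recall day, zero energy)
#' propagate NA scores with their reason.
#'
#' @param pooled output of \code{\link{pool_days}} (or a data.frame with the
#'   same pooled columns plus \code{scorable}).
#' @param standards standards table (default the bundled HEI-2015 table).
#' @return data.frame of 13 component score columns (\code{score_<component>}),
#'   \code{hei_total}, and \code{unscorable_reason}.
#' @export
score_hei <- function(pooled, standards = hei_standards()) {
  n <- nrow(pooled)
  scorable <- if ("scorable" %in% names(pooled)) pooled$scorable else rep(TRUE, n)
  out <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(standards))) {
    std <- standards[i, ]
    sc <- rep(NA_real_, n)
    if (any(scorable)) {
      if (std$component == "fatty_acids") {
        mp <- pooled$mufa_pufa[scorable]
        sf <- pooled$sat_fat[scorable]
        ratio <- ifelse(sf > 0, mp / sf,
                        ifelse(mp > 0, std$full_standard, std$zero_standard))
        sc[scorable] <- score_component(ratio, NULL, std)
      } else {
        sc[scorable] <- score_component(pooled[[std$component]][scorable],
                                        pooled$energy[scorable], std)
      }
    }
    out[[paste0("score_", std$component)]] <- sc
  }
  out$hei_total <- rowSums(out)
  out$unscorable_reason <-
    if ("unscorable_reason" %in% names(pooled)) pooled$unscorable_reason
    else NA_character_
  out
}
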