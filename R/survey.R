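#' Construct a complex-survey design
#'
#' Describes a stratified, clustered design with per-respondent weights.
#' Variance estimation treats primary sampling units (PSUs) as sampled with
#' replacement within strata (the standard Taylor-linearization
#' approximation for NHANES-style public-use designs).
#'
#' @param strata stratum identifiers (coerced to factor).
#' @param psu PSU identifiers, nested within stratum.
#' @param weights nonnegative sampling weights.
#' @param lonely how to handle strata with a single PSU when estimating
#'   variance: "error" (default) or "center" (deviations taken about the
#'   grand mean of PSU totals).
#' @return object of class \code{fs_design}.
#' @export
fs_design <- function(strata, psu, weights, lonely = c("error", "center")) {
  lonely <- match.arg(lonely)
  if (length(strata) != length(psu) || length(psu) != length(weights)) {
    stop("strata, psu, and weights must have equal length")
  }
  if (any(is.na(weights)) || any(weights < 0)) {
    stop("weights must be nonnegative and non-missing")
  }
  strata <- factor(strata)
  psu <- factor(paste(strata, psu, sep = ":"))
  structure(list(strata = strata, psu = psu, weights = as.numeric(weights),
                 lonely = lonely),
            class = "fs_design")
}

design_subset <- function(design, keep) {
  fs_design(design$strata[keep], sub("^[^:]*:", "", design$psu[keep]),
            design$weights[keep], lonely = design$lonely)
}

#' Design degrees of freedom
#'
#' Number of PSUs minus number of strata, the usual degrees of freedom for
#' design-based Wald intervals.
#'
#' @param design an \code{fs_design}.
#' @return integer degrees of freedom.
#' @export
degf <- function(design) {
  nlevels(droplevels(design$psu)) - nlevels(droplevels(design$strata))
}

## Stratified between-PSU covariance of linearized score contributions.
## U is an n x k matrix of per-observation (already weight-multiplied)
## influence values; returns the k x k with-replacement variance estimate.
psu_covariance <- function(U, design) {
  U <- as.matrix(U)
  psu <- droplevels(design$psu)
  strata <- droplevels(design$strata)
  z <- rowsum(U, psu, reorder = FALSE)
  h_of_psu <- strata[match(rownames(z), as.character(psu))]
  V <- matrix(0, ncol(U), ncol(U))
  lonely <- character()
  grand <- colMeans(z)
  for (h in levels(h_of_psu)) {
    zh <- z[h_of_psu == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh < 2) {
      if (design$lonely == "error") { lonely <- c(lonely, h); next }
      d <- sweep(zh, 2, grand)
      V <- V + crossprod(d)
      next
    }
    d <- sweep(zh, 2, colMeans(zh))
    V <- V + nh / (nh - 1) * crossprod(d)
  }
  if (length(lonely)) {
    stop("stratum with a single PSU: ", paste(lonely, collapse = ", "),
         " (use lonely = \"center\" to proceed)")
  }
  V
}

#' Construct multiyear sampling weights
#'
#' Pools per-cycle two-year weights into multiyear weights by dividing each
#' two-year weight by the number of pooled two-year cycles.
#'
#' @param table respondent table carrying the two-year weight columns.
#' @param n_cycles number of pooled two-year cycles (6 for a 12-year pool).
#' @param weight_cols named character vector mapping new multiyear column
#'   names to existing two-year columns.
#' @return table with multiyear weight columns appended.
#' @export
build_multiyear_weights <- function(table, n_cycles,
                                    weight_cols = c(wtint12yr = "wtint2yr",
                                                    wtmec12yr = "wtmec2yr",
                                                    wtdr2d12yr = "wtdr2d")) {
  if (length(n_cycles) != 1 || is.na(n_cycles) || n_cycles < 1) {
    stop("n_cycles must be a positive integer")
  }
  for (new in names(weight_cols)) {
    src <- weight_cols[[new]]
    if (!src %in% names(table)) stop("missing two-year weight column: ", src)
    table[[new]] <- table[[src]] / n_cycles
  }
  table
}

#' Select the analysis weight for a given analysis kind
#'
#' Interview-only analyses use the interview weight, analyses involving
#' examination-center variables use the MEC weight, and dietary analyses use
#' the two-day dietary weight.
#'
#' @param analysis_kind one of "interview", "mec", "dietary".
#' @return the multiyear weight column name.
#' @export
select_weight <- function(analysis_kind = c("interview", "mec", "dietary")) {
  analysis_kind <- match.arg(analysis_kind)
  switch(analysis_kind,
         interview = "wtint12yr",
         mec = "wtmec12yr",
         dietary = "wtdr2d12yr")
}

#' Design-weighted category prevalence
#'
#' Horvitz-Thompson ratio estimates of category proportions with
#' Taylor-linearized standard errors clustered on PSU within stratum.
#' Confidence intervals use the logit-Wald construction with design degrees
#' of freedom by default; Korn-Graubard beta intervals are available.
#'
#' @param x categorical vector (factor or character); NA dropped together
#'   with its design row.
#' @param design \code{fs_design} aligned with \code{x}.
#' @param conf confidence level (default 0.95).
#' @param ci_method "logit" (default) or "korn-graubard".
#' @return data.frame with category, n (unweighted), proportion, se, ci_lower,
#'   ci_upper.
#' @export
weighted_prevalence <- function(x, design, conf = 0.95,
                                ci_method = c("logit", "korn-graubard")) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(x)
  x <- factor(x[keep])
  design <- design_subset(design, keep)
  w <- design$weights
  W <- sum(w)
  df <- degf(design)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  out <- data.frame(category = levels(x), n = as.integer(table(x)),
                    proportion = NA_real_, se = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_)
  for (i in seq_along(levels(x))) {
    ind <- as.numeric(x == levels(x)[i])
    p <- sum(w * ind) / W
    U <- w * (ind - p) / W
    v <- psu_covariance(matrix(U, ncol = 1), design)[1, 1]
    se <- sqrt(v)
    if (p %in% c(0, 1) || se == 0) {
      ci <- c(p, p)
    } else if (ci_method == "logit") {
      l <- stats::qlogis(p)
      se_l <- se / (p * (1 - p))
      ci <- stats::plogis(l + c(-1, 1) * tcrit * se_l)
    } else {
      n_eff <- min(p * (1 - p) / v, sum(keep))
      a <- (1 - conf) / 2
      lo <- if (p == 0) 0 else stats::qbeta(a, n_eff * p, n_eff * (1 - p) + 1)
      hi <- if (p == 1) 1 else stats::qbeta(1 - a, n_eff * p + 1, n_eff * (1 - p))
      ci <- c(lo, hi)
    }
    out$proportion[i] <- p
    out$se[i] <- se
    out$ci_lower[i] <- ci[1]
    out$ci_upper[i] <- ci[2]
  }
  out
}

#' Rao-Scott corrected chi-square test of association
#'
#' Pearson chi-square for a two-way table of design-weighted proportions,
#' corrected for the complex design. The default second-order (Satterthwaite)
#' correction reports an F statistic: F = X2 / tr(Delta) on
#' (d0, d0 * design df) degrees of freedom where d0 = tr(Delta)^2 / tr(Delta^2)
#' and Delta is the generalized design-effect matrix of the interaction
#' contrasts. The first-order correction (X2 / mean eigenvalue against a
#' chi-square) is available by flag.
#'
#' @param row_var,col_var categorical vectors; rows with any NA are dropped.
#' @param design \code{fs_design} aligned with the inputs.
#' @param order "second" (default) or "first".
#' @return list with statistic, df1, df2 (NA for first order), p.value, and
#'   the weighted proportion table.
#' @export
rao_scott_test <- function(row_var, col_var, design,
                           order = c("second", "first")) {
  order <- match.arg(order)
  keep <- !is.na(row_var) & !is.na(col_var)
  r <- droplevels(factor(row_var[keep]))
  c_ <- droplevels(factor(col_var[keep]))
  if (nlevels(r) < 2 || nlevels(c_) < 2) {
    stop("both variables need at least two observed categories")
  }
  design <- design_subset(design, keep)
  w <- design$weights
  n <- length(w)
  W <- sum(w)
  R <- nlevels(r); C <- nlevels(c_)
  cell <- interaction(r, c_, lex.order = TRUE)  # cells vary over c within r
  P <- matrix(0, R, C, dimnames = list(levels(r), levels(c_)))
  for (i in seq_len(R)) for (j in seq_len(C)) {
    P[i, j] <- sum(w[r == levels(r)[i] & c_ == levels(c_)[j]]) / W
  }
  prow <- rowSums(P); pcol <- colSums(P)
  E <- outer(prow, pcol)
  X2 <- n * sum((P - E)^2 / E)

  ## linearized covariance of the RC cell proportions
  p <- as.vector(t(P))  # ordered to match interaction(r, c_) lex.order
  Ind <- stats::model.matrix(~ cell - 1)
  U <- (w / W) * sweep(Ind, 2, p)
  Vhat <- psu_covariance(U, design)

  ## interaction contrast basis, projected out of the main-effects space
  ## under the metric diag(p)
  rr <- factor(rep(levels(r), each = C), levels = levels(r))
  cc <- factor(rep(levels(c_), R), levels = levels(c_))
  X1 <- stats::model.matrix(~ rr + cc)
  X12 <- stats::model.matrix(~ rr * cc)
  Xint <- X12[, setdiff(colnames(X12), colnames(X1)), drop = FALSE]
  Dp <- diag(p)
  ## generalized inverses tolerate empty cells (perfect association)
  Cmat <- Xint - X1 %*% ginv_sym(crossprod(X1, Dp %*% X1)) %*%
    crossprod(X1, Dp %*% Xint)
  V0c <- crossprod(Cmat, Dp %*% Cmat)       # = C' (Dp - pp') C since C'Dp 1=0
  Vc <- crossprod(Cmat, Vhat %*% Cmat)
  Delta <- n * ginv_sym(V0c) %*% Vc
  d <- (R - 1) * (C - 1)
  tr1 <- sum(diag(Delta))
  if (order == "first") {
    stat <- X2 / (tr1 / d)
    return(list(statistic = stat, df1 = d, df2 = NA_real_,
                p.value = stats::pchisq(stat, d, lower.tail = FALSE),
                proportions = P, order = "first"))
  }
  tr2 <- sum(Delta * t(Delta))
  d0 <- tr1^2 / tr2
  Fstat <- X2 / tr1
  df2 <- d0 * degf(design)
  list(statistic = Fstat, df1 = d0, df2 = df2,
       p.value = stats::pf(Fstat, d0, df2, lower.tail = FALSE),
       proportions = P, order = "second")
}

## Moore-Penrose inverse of a symmetric matrix
ginv_sym <- function(A, tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values), 1e-300)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

## weighted mean of y within group g, with linearized influence values
wmean_influence <- function(y, ind, w) {
  Wg <- sum(w * ind)
  m <- sum(w * ind * y) / Wg
  list(mean = m, U = w * ind * (y - m) / Wg)
}

#' Design-based pairwise t-tests with Bonferroni adjustment
#'
#' Tests differences in design-weighted means between category pairs, with
#' Taylor-linearized variance of the difference and p-values multiplied by
#' the Bonferroni factor \code{m} (capped at 1). For the four food-security
#' categories, all 6 pairwise comparisons use m = 6.
#'
#' @param y numeric outcome; @param group categorical vector.
#' @param design \code{fs_design}; rows with NA in y or group are dropped.
#' @param pairs optional list of length-2 character vectors; default all
#'   pairs of observed groups.
#' @param m Bonferroni multiplier; defaults to the number of pairs.
#' @return data.frame with group1, group2, diff, se, t, df, p_raw, p_adj.
#' @export
design_ttest_bonferroni <- function(y, group, design, pairs = NULL, m = NULL) {
  keep <- !is.na(y) & !is.na(group)
  y <- y[keep]
  g <- droplevels(factor(group[keep]))
  design <- design_subset(design, keep)
  if (is.null(pairs)) {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  for (pr in pairs) {
    if (!all(pr %in% levels(g))) stop("unknown group label: ",
                                      paste(setdiff(pr, levels(g)), collapse = ", "))
  }
  if (is.null(m)) m <- length(pairs)
  if (m < 1) stop("Bonferroni multiplier m must be >= 1")
  w <- design$weights
  df <- degf(design)
  res <- lapply(pairs, function(pr) {
    a <- wmean_influence(y, as.numeric(g == pr[1]), w)
    b <- wmean_influence(y, as.numeric(g == pr[2]), w)
    d <- a$mean - b$mean
    v <- psu_covariance(matrix(a$U - b$U, ncol = 1), design)[1, 1]
    tt <- d / sqrt(v)
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(group1 = pr[1], group2 = pr[2], diff = d, se = sqrt(v),
               t = tt, df = df, p_raw = p, p_adj = pmin(1, p * m))
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

## shared machinery for design-weighted GLMs: point estimates by
## pseudo-maximum likelihood (base glm/lm with prior weights), variance by
## clustered sandwich over PSUs within strata
svy_glm_fit <- function(formula, data, design, family, conf = 0.95) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  data <- data[keep, , drop = FALSE]
  design2 <- design_subset(design, keep)
  ## fit with weights normalized to mean 1: estimates and the sandwich are
  ## invariant to the scale, and glm's starting values degenerate under
  ## population-scale weights
  data$.w <- design2$weights / mean(design2$weights)
  ## treatment contrasts against the first level (the High-food-security
  ## referent for severity exposures), not polynomial contrasts
  for (v in names(mf)) {
    if (is.ordered(data[[v]])) data[[v]] <- factor(data[[v]], ordered = FALSE)
  }
  if (family == "binomial") {
    yv <- stats::model.response(stats::model.frame(formula, data))
    if (length(unique(yv)) < 2) stop("outcome is constant; nothing to fit")
    fit <- suppressWarnings(
      stats::glm(formula, data = data, weights = .w, family = stats::quasibinomial())
    )
    if (!fit$converged || max(abs(stats::coef(fit))) > 20) {
      stop("separation detected: weighted logistic fit did not stabilize")
    }
  } else {
    fit <- stats::lm(formula, data = data, weights = .w)
  }
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient (empty category?)")
  beta <- stats::coef(fit)
  w <- design2$weights
  if (family == "binomial") {
    mu <- stats::fitted(fit)
    resid_work <- stats::model.response(stats::model.frame(fit)) - mu
    A <- crossprod(X, (w * mu * (1 - mu)) * X)
  } else {
    resid_work <- stats::resid(fit)
    A <- crossprod(X, w * X)
  }
  U <- (w * resid_work) * X           # per-observation estimating scores
  G <- psu_covariance(U, design2)
  Ainv <- solve(A)
  V <- Ainv %*% G %*% Ainv
  se <- sqrt(diag(V))
  df <- degf(design2)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  res <- data.frame(term = names(beta), estimate = beta, se = se,
                    t = beta / se,
                    p = 2 * stats::pt(-abs(beta / se), df),
                    ci_lower = beta - tcrit * se,
                    ci_upper = beta + tcrit * se,
                    row.names = NULL)
  structure(list(results = res, family = family, formula = formula,
                 data = data, design = design2, vcov = V, df = df,
                 n = nrow(data)),
            class = "fs_svyglm")
}

#' @export
print.fs_svyglm <- function(x, ...) {
  cat("Design-weighted", if (x$family == "binomial") "logistic" else "linear",
      "regression (n =", x$n, ", design df =", x$df, ")\n")
  print(x$results, digits = 4)
  invisible(x)
}

#' Design-weighted logistic regression
#'
#' Pseudo-maximum-likelihood logistic fit with sampling weights; variance by
#' the linearized (sandwich) estimator clustered on PSU within stratum.
#' Odds ratios with design-df t confidence intervals are reported for every
#' non-intercept term.
#'
#' @param formula model formula with a 0/1 (or logical) outcome. Exposure
#'   categories enter as factors; set the referent by factor level order
#'   (high food security first).
#' @param data data.frame; rows with NA in any model variable are dropped
#'   together with their design rows.
#' @param design \code{fs_design} aligned with \code{data}.
#' @param conf confidence level.
#' @return \code{fs_svyglm} object; \code{$results} has estimate (log odds),
#'   se, p, CI, plus \code{odds_ratio}, \code{or_lower}, \code{or_upper}.
#' @export
weighted_logistic <- function(formula, data, design, conf = 0.95) {
  fit <- svy_glm_fit(formula, data, design, "binomial", conf)
  r <- fit$results
  r$odds_ratio <- exp(r$estimate)
  r$or_lower <- exp(r$ci_lower)
  r$or_upper <- exp(r$ci_upper)
  fit$results <- r
  fit
}

#' Design-weighted linear regression
#'
#' Weighted least squares point estimates with linearized variance clustered
#' on PSU within stratum; coefficients are on the outcome scale.
#'
#' @inheritParams weighted_logistic
#' @return \code{fs_svyglm} object.
#' @export
weighted_linear <- function(formula, data, design, conf = 0.95) {
  svy_glm_fit(formula, data, design, "gaussian", conf)
}

#' Compare coefficients of two design-weighted models by paired bootstrap
#'
#' Replaces a stacked-estimating-equation (seemingly-unrelated) comparison
#' with a design-respecting paired bootstrap: PSUs are resampled within
#' strata (Rao-Wu, n_h - 1 draws with weight rescaling), both models are
#' refit on each replicate, and per-term coefficient differences are
#' summarized by percentile intervals and a two-sided bootstrap p-value.
#' Both models must have been fit on the same respondents.
#'
#' @param fit_a,fit_b \code{fs_svyglm} objects sharing their data rows.
#' @param reps number of bootstrap replicates (default 200).
#' @param conf confidence level; @param seed optional RNG seed.
#' @return data.frame with term, diff (a minus b), ci_lower, ci_upper, p.
#' @export
compare_models <- function(fit_a, fit_b, reps = 200, conf = 0.95, seed = NULL) {
  if (fit_a$n != fit_b$n ||
      !identical(as.character(fit_a$design$psu), as.character(fit_b$design$psu))) {
    stop("models were not fit on the same respondents/design")
  }
  if (!is.null(seed)) set.seed(seed)
  shared <- intersect(fit_a$results$term, fit_b$results$term)
  shared <- setdiff(shared, "(Intercept)")
  if (!length(shared)) stop("models share no non-intercept terms")
  design <- fit_a$design
  strata <- droplevels(design$strata)
  psu <- droplevels(design$psu)
  psu_by_stratum <- split(levels(droplevels(psu)),
                          strata[match(levels(droplevels(psu)), as.character(psu))])
  idx_by_psu <- split(seq_len(fit_a$n), psu, drop = TRUE)

  refit <- function(fit, rows, wmult) {
    d <- fit$data[rows, , drop = FALSE]
    d$.w <- d$.w * wmult
    if (fit$family == "binomial") {
      m <- suppressWarnings(stats::glm(fit$formula, data = d, weights = .w,
                                       family = stats::quasibinomial()))
    } else {
      m <- stats::lm(fit$formula, data = d, weights = .w)
    }
    stats::coef(m)
  }
  point <- stats::setNames(
    fit_a$results$estimate[match(shared, fit_a$results$term)] -
      fit_b$results$estimate[match(shared, fit_b$results$term)], shared)
  diffs <- matrix(NA_real_, reps, length(shared),
                  dimnames = list(NULL, shared))
  for (b in seq_len(reps)) {
    rows <- integer(); wmult <- numeric()
    for (h in names(psu_by_stratum)) {
      ph <- psu_by_stratum[[h]]
      nh <- length(ph)
      take <- if (nh == 1) ph else sample(ph, nh - 1, replace = TRUE)
      scale_h <- nh / max(1, nh - 1)
      for (u in take) {
        rows <- c(rows, idx_by_psu[[u]])
        wmult <- c(wmult, rep(scale_h, length(idx_by_psu[[u]])))
      }
    }
    ca <- tryCatch(refit(fit_a, rows, wmult), error = function(e) NULL)
    cb <- tryCatch(refit(fit_b, rows, wmult), error = function(e) NULL)
    if (is.null(ca) || is.null(cb)) next
    diffs[b, ] <- ca[shared] - cb[shared]
  }
  a <- (1 - conf) / 2
  out <- lapply(shared, function(tm) {
    d <- diffs[, tm]; d <- d[!is.na(d)]
    pl <- (1 + sum(d <= 0)) / (1 + length(d))
    pu <- (1 + sum(d >= 0)) / (1 + length(d))
    data.frame(term = tm, diff = point[[tm]],
               ci_lower = stats::quantile(d, a, names = FALSE),
               ci_upper = stats::quantile(d, 1 - a, names = FALSE),
               p = min(1, 2 * min(pl, pu)), reps_used = length(d))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
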