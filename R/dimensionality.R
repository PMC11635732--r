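#' Correlation matrix for the pooled food-security items
#'
#' Pearson correlations on the 0/1 item indicators by default (tetrachoric
#' correlations, estimated pairwise by maximum likelihood on the 2x2 tables,
#' as an option). Only rows complete on all items contribute.
#'
#' @param items data.frame/matrix of 0/1 item indicators.
#' @param method "pearson" (default) or "tetrachoric".
#' @param weights optional nonnegative weights for a weighted Pearson
#'   correlation (ignored for tetrachoric).
#' @return list with \code{R} (correlation matrix), \code{n_effective},
#'   \code{method}.
#' @export
item_correlation <- function(items, method = c("pearson", "tetrachoric"),
                             weights = NULL) {
  method <- match.arg(method)
  X <- as.matrix(items)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  if (method == "pearson") {
    if (is.null(weights)) {
      R <- stats::cor(X)
    } else {
      w <- weights[keep] / sum(weights[keep])
      mu <- colSums(w * X)
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc, w * Xc)
      R <- stats::cov2cor(S)
    }
  } else {
    p <- ncol(X)
    R <- diag(p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      R[i, j] <- R[j, i] <- tetrachoric_r(X[, i], X[, j])
    }
    dimnames(R) <- list(colnames(X), colnames(X))
  }
  list(R = R, n_effective = n, method = method)
}

## ML tetrachoric correlation for a pair of binary items
tetrachoric_r <- function(x, y) {
  tab <- table(factor(x, c(0, 1)), factor(y, c(0, 1))) + 0.5  # continuity
  n <- sum(tab)
  p1 <- sum(tab[2, ]) / n   # P(x = 1)
  p2 <- sum(tab[, 2]) / n   # P(y = 1)
  a <- stats::qnorm(1 - p1)
  b <- stats::qnorm(1 - p2)
  nll <- function(r) {
    p11 <- pbivnorm_scalar(a, b, r)
    ## cell order of as.vector(tab): (0,0), (1,0), (0,1), (1,1)
    pr <- pmax(c(1 - p1 - p2 + p11, p1 - p11, p2 - p11, p11), 1e-12)
    -sum(as.vector(tab) * log(pr))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

## upper-orthant bivariate normal probability P(X > a, Y > b) with corr r,
## by Gauss-Legendre quadrature over the conditional probability
pbivnorm_scalar <- function(a, b, r) {
  gl <- gauss_legendre(48)
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((-(b) + r * x) / sqrt(1 - r^2))
  lo <- a; hi <- a + 12
  x <- (hi - lo) / 2 * gl$nodes + (hi + lo) / 2
  (hi - lo) / 2 * sum(gl$weights * f(x))
}

gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

validate_corr <- function(R, tol = 1e-8) {
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) stop("R must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("R must have a unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop("R is not positive semidefinite (min eigenvalue ",
                           signif(min(ev), 3), ")")
  R
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity (no intercorrelation,
#' factor analysis unwarranted). The statistic is
#' -(n - 1 - (2p + 5)/6) * log det(R) on p(p-1)/2 chi-square degrees of
#' freedom.
#'
#' @param R correlation matrix; @param n number of observations (> p).
#' @return list with statistic, df, p.value.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- validate_corr(R)
  p <- ncol(R)
  if (n <= p) stop("Bartlett's test requires n > p")
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    stop("R is singular (log-determinant undefined); condition number ",
         signif(kappa(R), 3))
  }
  stat <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO compares observed correlations with anti-image partial correlations:
#' overall KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2) over i != j, where
#' q_ij are the partial correlations obtained from the inverse correlation
#' matrix. Values near 1 indicate shared variance suitable for factoring;
#' the conventional floor is 0.5.
#'
#' @param R correlation matrix (invertible).
#' @return list with \code{overall} and \code{per_item} (named vector).
#' @export
kmo <- function(R) {
  R <- validate_corr(R)
  Ri <- tryCatch(solve(R), error = function(e)
    stop("R is singular; KMO undefined (condition number ",
         signif(kappa(R), 3), ")"))
  Q <- -stats::cov2cor(Ri)
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_item <- colSums(r2) / (colSums(r2) + colSums(q2))
  names(per_item) <- colnames(R)
  list(overall = overall, per_item = per_item)
}

#' Eigenvalues and principal-axis factor extraction
#'
#' Returns the descending eigenvalues of the correlation matrix (the basis
#' of the eigenvalue-greater-than-one retention rule) and, for the retained
#' factors, loadings from principal-axis iteration: communalities start at
#' the squared multiple correlations and the reduced matrix is re-factored
#' until the communalities stabilize.
#'
#' @param R correlation matrix.
#' @param n_factors number of factors to retain; default: eigenvalues > 1.
#' @param max_iter,tol iteration control for the communality updates.
#' @return list with \code{eigenvalues} (of R, descending), \code{n_retained},
#'   \code{loadings} (p x k), \code{communalities}, \code{iterations}.
#' @export
efa_eigenvalues <- function(R, n_factors = NULL, max_iter = 2000, tol = 1e-3) {
  R <- validate_corr(R)
  p <- ncol(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (is.null(n_factors)) n_factors <- sum(ev > 1)
  k <- max(1L, as.integer(n_factors))
  ## principal-axis iteration
  Ri <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(Ri)) rep(0.5, p) else 1 - 1 / diag(Ri)  # SMC start
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
    h2_new <- pmin(rowSums(L^2), 1)
    delta <- max(abs(h2_new - h2))
    trace <- c(trace, delta)
    h2 <- h2_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop("principal-axis communality iteration did not converge; ",
         "last deltas: ", paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  }
  rownames(L) <- colnames(R)
  list(eigenvalues = ev, n_retained = k, loadings = L,
       communalities = h2, iterations = it)
}
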