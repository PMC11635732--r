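# independent oracles shared across test files

cs_matrix <- function(p, rho) {
  R <- matrix(rho, p, p)
  diag(R) <- 1
  R
}

# brute-force partial correlation of i and j given all other variables,
# via explicit regression algebra on the correlation matrix
partial_cor_oracle <- function(R, i, j) {
  o <- setdiff(seq_len(ncol(R)), c(i, j))
  if (!length(o)) return(R[i, j])
  Roo <- solve(R[o, o, drop = FALSE])
  num <- R[i, j] - R[i, o, drop = FALSE] %*% Roo %*% R[o, j, drop = FALSE]
  den_i <- 1 - R[i, o, drop = FALSE] %*% Roo %*% R[o, i, drop = FALSE]
  den_j <- 1 - R[j, o, drop = FALSE] %*% Roo %*% R[o, j, drop = FALSE]
  as.numeric(num / sqrt(den_i * den_j))
}

kmo_oracle <- function(R) {
  p <- ncol(R)
  r2 <- 0; q2 <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r2 <- r2 + 2 * R[i, j]^2
    q2 <- q2 + 2 * partial_cor_oracle(R, i, j)^2
  }
  r2 / (r2 + q2)
}

# two-day intake table from pooled target amounts split evenly across days
intake_row <- function(energy, amounts) {
  comps <- c(setdiff(hei_components(), "fatty_acids"), "mufa_pufa")
  row <- list()
  for (v in c("energy", comps)) {
    val <- if (v == "energy") energy else amounts[[v]]
    if (is.null(val)) val <- 0
    row[[paste0(v, "_d1")]] <- val / 2
    row[[paste0(v, "_d2")]] <- val / 2
  }
  as.data.frame(row)
}
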