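# Independent oracles used by the acceptance suite.

# Brute-force Freeman-Halton p for a 2 x c table: enumerate every
# margin-compatible table, accumulate multivariate hypergeometric
# probabilities at most the observed one (with a relative float guard).
fisher_oracle_2xc <- function(tab) {
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  grid <- as.matrix(expand.grid(lapply(cs, function(cj) 0:cj)))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  probs <- apply(grid, 1, function(x) prod(choose(cs, x))) /
    choose(n, r1)
  p_obs <- prod(choose(cs, tab[1, ])) / choose(n, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All distinct 2 x c tables with positive margins and total n, organised
# by margin class so the enumeration is shared; calls `fun(tab, p_oracle)`
# for each table.
sweep_2xc_tables <- function(n, c, fun) {
  col_splits <- compositions_positive(n, c)
  for (ci in seq_len(nrow(col_splits))) {
    cs <- col_splits[ci, ]
    grid <- as.matrix(expand.grid(lapply(cs, function(cj) 0:cj)))
    sums <- rowSums(grid)
    for (r1 in 1:(n - 1)) {
      members <- grid[sums == r1, , drop = FALSE]
      probs <- apply(members, 1, function(x) prod(choose(cs, x))) /
        choose(n, r1)
      for (i in seq_len(nrow(members))) {
        tab <- rbind(members[i, ], cs - members[i, ])
        p_oracle <- sum(probs[probs <= probs[i] * (1 + 1e-7)])
        fun(tab, p_oracle)
      }
    }
  }
}

# Ordered compositions of n into k positive parts.
compositions_positive <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (first in 1:(n - k + 1)) {
    rest <- compositions_positive(n - first, k - 1)
    out[[first]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}

# Direct-formula Hedges' g in plain arithmetic (the oracle mirrors the
# textbook definition, not the package implementation).
hedges_g_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (1 - 3 / (4 * (nx + ny) - 9)) * (mean(x) - mean(y)) / sp
}
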