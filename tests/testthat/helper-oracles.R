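# Independent oracles kept deliberately separate from the package's
# implementation paths.

# NB log-pmf in explicit gamma-function form, mean/dispersion
# parameterisation (variance mu + kappa mu^2).
nb_logpmf_gamma <- function(y, mu, kappa) {
  a <- 1 / kappa
  lgamma(y + a) - lgamma(a) - lgamma(y + 1) +
    y * log(kappa * mu / (1 + kappa * mu)) - a * log(1 + kappa * mu)
}

# Cyclic coordinate grid refinement of the NB GLM log-likelihood:
# scans each coefficient over a shrinking grid until the grid spacing
# is below `final_step`. Slow but independent of IRLS.
grid_refine_loglik <- function(y, X, offsets, kappa, start, span = 2,
                               final_step = 1e-4) {
  beta <- start
  ll_at <- function(b) {
    mu <- pmax(exp(pmin(offsets + drop(X %*% b), 700)), 1e-8)
    sum(nb_logpmf_gamma(y, mu, rep_len(kappa, length(y))))
  }
  while (span > final_step) {
    for (k in seq_along(beta)) {
      grid <- beta[k] + seq(-span, span, length.out = 15)
      vals <- vapply(grid, function(g) {
        b <- beta
        b[k] <- g
        ll_at(b)
      }, numeric(1))
      beta[k] <- grid[which.max(vals)]
    }
    span <- span * 0.55
  }
  list(beta = beta, loglik = ll_at(beta))
}

# Brute-force median-of-ratios size factors over the stated definition
# (all-positive reference genes, one protocol at a time).
brute_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  sub <- m[keep, , drop = FALSE]
  ref <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  f <- apply(sweep(sub, 1, ref, "/"), 2, median)
  f / prod(f)^(1 / length(f))
}

# Benjamini-Hochberg step-up applied literally: padj(i) = min over
# ranks i' >= i of p(i') * m / i'.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(padj_sorted, 1)
  out
}

# AUC as the normalized Mann-Whitney U statistic (ties count 1/2).
brute_auc <- function(scores, labels) {
  s1 <- scores[labels]
  s0 <- scores[!labels]
  total <- 0
  for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
  total / (length(s1) * length(s0))
}
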