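# Independent oracles used by the estimation tests. These deliberately
# re-derive predictions and integrals from first principles (no calls into
# the package's likelihood internals).

# Marginal negative log likelihood by tensor-product Gauss-Hermite
# quadrature over the two subject-level random effects. For a N(0, w^2)
# effect, E[f(u)] = (1/sqrt(pi)) * sum_k w_k f(sqrt(2) * w * x_k).
gh_marginal_nll <- function(dataset, th, n_nodes = 40) {
  gh <- pracma::gaussHermite(n_nodes)
  bs <- sqrt(2) * th$omega_baseline * gh$x
  es <- sqrt(2) * th$omega_emax * gh$x
  lw <- log(gh$w)
  total <- 0
  for (sub in split(dataset, dataset$subject_id)) {
    ll <- matrix(0, n_nodes, n_nodes)
    for (j in seq_len(nrow(sub))) {
      d <- sub$ba_dose[j]
      g <- if (d > 0) d / (th$ed50 + d) else 0
      e_ba <- outer(rep(1, n_nodes), pmin(th$emax * exp(es) * g, 1 - 1e-9))
      f <- th$baseline * exp(bs) * (1 - e_ba)   # rows: baseline nodes
      v <- (th$prop * f)^2 + th$add^2
      ll <- ll - 0.5 * (log(2 * pi * v) + (sub$ldl[j] - f)^2 / v)
    }
    lse <- outer(lw, lw, "+") + ll - log(pi)
    m <- max(lse)
    total <- total - (m + log(sum(exp(lse - m))))
  }
  total
}

# Expected imputed baseline under a truncated log-normal response draw,
# by numerical integration (the Monte-Carlo comparator for stochastic
# imputation).
expected_imputed <- function(observed, e_typ, cv, cap = 0.95) {
  s <- sqrt(log(1 + cv^2))
  zmax <- log(cap / e_typ) / s
  norm <- stats::pnorm(zmax)
  stats::integrate(function(z) {
    observed / (1 - e_typ * exp(s * z)) * stats::dnorm(z) / norm
  }, lower = -8, upper = zmax, rel.tol = 1e-9)$value
}
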