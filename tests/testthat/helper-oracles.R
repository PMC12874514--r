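# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: the RE oracle is a zooming grid search over the
# joint likelihood surface, and the matching oracle is an exhaustive
# all-pairs distance scan.

# Joint Gaussian log-likelihood of the random-effects model.
re_joint_ll <- function(mu, tau2, yi, s2) {
  d <- s2 + tau2
  -0.5 * sum(log(2 * pi * d) + (yi - mu)^2 / d)
}

# Dense grid search over (mu, tau2), refined by zooming three times so the
# final resolution is well below 1e-4 in both coordinates.
oracle_re_grid <- function(yi, sigma, n_grid = 101, zooms = 3) {
  s2 <- sigma^2
  mu_lo <- min(yi); mu_hi <- max(yi)
  t2_lo <- 0; t2_hi <- max(4 * stats::var(yi), 0.1)
  best <- c(mu = NA, tau2 = NA, ll = -Inf)
  for (z in seq_len(zooms + 1)) {
    mus <- seq(mu_lo, mu_hi, length.out = n_grid)
    t2s <- seq(t2_lo, t2_hi, length.out = n_grid)
    ll <- outer(mus, t2s, Vectorize(function(m, t) re_joint_ll(m, t, yi, s2)))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(mu = mus[idx[1]], tau2 = t2s[idx[2]], ll = max(ll))
    dm <- diff(mus)[1]; dt <- diff(t2s)[1]
    mu_lo <- best[["mu"]] - 2 * dm; mu_hi <- best[["mu"]] + 2 * dm
    t2_lo <- max(0, best[["tau2"]] - 2 * dt); t2_hi <- best[["tau2"]] + 2 * dt
  }
  best
}

# Exhaustive nearest-node scan under an explicit quadratic form.
oracle_nn_match <- function(X, G, S) {
  Sinv <- solve(S)
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- vapply(seq_len(nrow(G)), function(j) {
      v <- X[i, ] - G[j, ]
      drop(t(v) %*% Sinv %*% v)
    }, 0)
    which.min(d2)
  }, 0L)
}

# A reproducible small meta-analysis dataset.
toy_dataset <- function(n = 5, seed = 42, mu = 0.3, tau = 0.2) {
  set.seed(seed)
  sigma <- stats::runif(n, 0.15, 0.6)
  yi <- stats::rnorm(n, mu, sqrt(sigma^2 + tau^2))
  list(yi = yi, sigma = sigma)
}
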