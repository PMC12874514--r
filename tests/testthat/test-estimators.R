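# The four estimators: frozen hand-computed oracles, exact algebraic
# identities, the grid-search and metafor cross-checks, and edge cases.

toy_y <- c(0.1, 0.2, 0.3)
toy_s <- c(0.3, 0.4, 0.5)

test_that("FE matches the hand-computed inverse-variance weighted mean", {
  fit <- meta_fit(toy_y, toy_s, "FE")
  # weights 1/0.09, 1/0.16, 1/0.25 = (11.1111, 6.25, 4); frozen by hand
  expect_equal(fit$mu_hat, 0.16671001, tolerance = 1e-7)
  expect_equal(fit$se_mu, 0.21636554, tolerance = 1e-7)
  expect_equal(fit$tau2_hat, 0)
  expect_equal(fit$gamma_hat, 1)
  expect_equal(fit$n_params, 1L)
  # maximised Gaussian likelihood evaluated directly
  expect_equal(fit$loglik,
               sum(dnorm(toy_y, fit$mu_hat, toy_s, log = TRUE)))
})

test_that("FE special cases: equal weights and a single study", {
  y <- c(0.4, 0.1, 0.7)
  expect_equal(meta_fit(y, rep(0.2, 3), "FE")$mu_hat, mean(y))
  f1 <- meta_fit(0.5, 0.3, "FE")
  expect_equal(f1$mu_hat, 0.5)
  expect_equal(f1$se_mu, 0.3)
  expect_error(meta_fit(numeric(0), numeric(0), "FE"), "empty")
})

test_that("UWLS-FE matches the hand-computed Q, H2 and rescaled SE", {
  fit <- meta_fit(toy_y, toy_s, "UWLS_FE")
  # frozen hand computation: Q = sum((y - 0.16671)^2 / s^2)
  expect_equal(fit$gamma_hat * 2, 0.127438, tolerance = 1e-4)  # Q
  expect_equal(fit$gamma_hat, 0.063719, tolerance = 1e-4)
  expect_equal(fit$se_mu, 0.054619, tolerance = 1e-4)
  expect_equal(fit$n_params, 2L)
  expect_equal(fit$tau2_hat, 0)
})

test_that("point-estimate identities hold to machine precision", {
  for (seed in 1:25) {
    d <- toy_dataset(n = sample(3:10, 1), seed = seed)
    fits <- fit_all_models(d$yi, d$sigma)
    expect_identical(fits$FE$mu_hat, fits$UWLS_FE$mu_hat)
    expect_identical(fits$RE$mu_hat, fits$UWLS_RE$mu_hat)
    # SE identity: se(UWLS-FE) = sqrt(H2) * se(FE)
    expect_equal(fits$UWLS_FE$se_mu,
                 sqrt(fits$UWLS_FE$gamma_hat) * fits$FE$se_mu,
                 tolerance = 1e-14)
    # nesting: RE likelihood dominates FE; tau2 never negative
    expect_gte(fits$RE$loglik, fits$FE$loglik - 1e-10)
    expect_gte(fits$RE$tau2_hat, 0)
  }
})

test_that("RE maximum likelihood agrees with a zooming grid-search oracle", {
  d <- toy_dataset(n = 5, seed = 42)
  fit <- meta_fit(d$yi, d$sigma, "RE")
  oracle <- oracle_re_grid(d$yi, d$sigma)
  expect_equal(fit$mu_hat, oracle[["mu"]], tolerance = 1e-4)
  expect_equal(fit$tau2_hat, oracle[["tau2"]], tolerance = 1e-4)
  expect_gte(fit$loglik, oracle[["ll"]] - 1e-6)
})

test_that("RE maximum likelihood agrees with metafor's ML fit", {
  skip_if_not_installed("metafor")
  for (seed in c(3, 8, 15)) {
    d <- toy_dataset(n = 7, seed = seed)
    fit <- meta_fit(d$yi, d$sigma, "RE")
    m <- metafor::rma(yi = d$yi, vi = d$sigma^2, method = "ML")
    expect_equal(fit$mu_hat, as.numeric(m$beta), tolerance = 1e-5)
    expect_equal(fit$tau2_hat, m$tau2, tolerance = 1e-4)
    expect_equal(fit$se_mu, m$se, tolerance = 1e-4)
  }
})

test_that("UWLS-RE reuses the RE tau2 and matches a hand-computed Q*", {
  d <- toy_dataset(n = 5, seed = 42)
  re <- meta_fit(d$yi, d$sigma, "RE")
  fit <- meta_fit(d$yi, d$sigma, "UWLS_RE")
  expect_identical(fit$tau2_hat, re$tau2_hat)
  v <- 1 / (d$sigma^2 + re$tau2_hat)
  mu <- sum(v * d$yi) / sum(v)
  Qs <- sum(v * (d$yi - mu)^2)
  expect_equal(fit$gamma_hat, Qs / 4, tolerance = 1e-12)
  expect_equal(fit$se_mu, sqrt(fit$gamma_hat / sum(v)), tolerance = 1e-12)
  expect_equal(fit$n_params, 3L)
})

test_that("UWLS-RE collapses to UWLS-FE when the RE tau2 hits zero", {
  # tightly clustered effects relative to large sigmas force tau2 = 0
  y <- c(0.20, 0.21, 0.19, 0.20, 0.205)
  s <- rep(0.5, 5)
  re <- meta_fit(y, s, "RE")
  expect_equal(re$tau2_hat, 0)
  uf <- meta_fit(y, s, "UWLS_FE")
  ur <- meta_fit(y, s, "UWLS_RE")
  expect_equal(ur$gamma_hat, uf$gamma_hat, tolerance = 1e-12)
  expect_equal(ur$se_mu, uf$se_mu, tolerance = 1e-12)
})

test_that("degenerate homogeneity: identical effects floor the scale", {
  y <- rep(0.3, 4)
  s <- c(0.2, 0.3, 0.4, 0.5)
  fit <- meta_fit(y, s, "UWLS_FE")
  expect_equal(fit$gamma_hat, 1e-12)
  expect_lt(fit$se_mu, 1e-5)
  re <- meta_fit(y, s, "RE")
  expect_equal(re$tau2_hat, 0)
  expect_equal(re$mu_hat, meta_fit(y, s, "FE")$mu_hat)
})

test_that("variance components need at least two studies", {
  expect_error(meta_fit(0.5, 0.3, "RE"), "2 studies")
  expect_error(meta_fit(0.5, 0.3, "UWLS_FE"), "2 studies")
  expect_error(meta_fit(0.5, 0.3, "UWLS_RE"), "2 studies")
  expect_error(meta_fit(c(0.1, 0.2), c(0.3, -0.1), "FE"), "positive")
})

test_that("confidence intervals use standard-normal quantiles", {
  fit <- meta_fit(toy_y, toy_s, "FE")
  # unit-SE construction via direct bounds
  ci95 <- confint(fit, level = 0.95)
  expect_equal(as.numeric(ci95),
               fit$mu_hat + c(-1, 1) * 1.959964 * fit$se_mu,
               tolerance = 1e-6)
  ci50 <- confint(fit, level = 0.5)
  expect_equal(diff(as.numeric(ci50)) / 2, 0.674490 * fit$se_mu,
               tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$mu_hat && fit$mu_hat <= fit$ci_high)
  expect_error(meta_fit(toy_y, toy_s, "FE", level = 1.2), "level")
  # zero-width interval when the SE degenerates
  fit0 <- meta_fit(rep(0.3, 4), c(0.2, 0.3, 0.4, 0.5), "UWLS_FE")
  expect_equal(fit0$ci_high - fit0$ci_low, 2 * 1.959964 * fit0$se_mu,
               tolerance = 1e-6)
})

test_that("logLik carries df and nobs so AIC and BIC are the usual formulas", {
  fits <- fit_all_models(toy_y, toy_s)
  ks <- c(FE = 1, RE = 2, UWLS_FE = 2, UWLS_RE = 3)
  for (m in names(fits)) {
    ll <- logLik(fits[[m]])
    expect_equal(attr(ll, "df"), unname(ks[m]))
    expect_equal(AIC(fits[[m]]), 2 * ks[[m]] - 2 * fits[[m]]$loglik)
    expect_equal(BIC(fits[[m]]), ks[[m]] * log(3) - 2 * fits[[m]]$loglik)
  }
})

test_that("methods behave: coef, vcov, residuals, print, summary, plot", {
  fit <- meta_fit(toy_y, toy_s, "RE")
  expect_equal(coef(fit), c(mu = fit$mu_hat))
  expect_equal(drop(vcov(fit)), fit$se_mu^2)
  expect_equal(nobs(fit), 3)
  expect_equal(residuals(fit), toy_y - fit$mu_hat)
  rs <- residuals(fit, type = "standardized")
  expect_equal(rs, (toy_y - fit$mu_hat) / sqrt(toy_s^2 + fit$tau2_hat))
  expect_output(print(fit), "RE")
  expect_output(print(summary(fit)), "AIC")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("each variance component is recovered at large N when its model
           is correctly specified", {
  # N tiled to 1000, 500 replicates, 3-MC-SE bands.  Recovery is checked in
  # the regime where the estimating model matches the DGP: the RE tau2 under
  # (gamma = 1, tau2 > 0) and the UWLS-FE scale H2 under (tau2 = 0,
  # gamma != 1).  The two-step UWLS-RE decomposition is NOT jointly
  # consistent for (gamma, tau2) when both depart -- step 1 assumes
  # gamma = 1, so its tau2 absorbs part of the scale; see the vignette.
  s <- sigma_profile(1000)
  s2 <- s^2

  set.seed(101)
  y1 <- simulate_meta(0.5, gamma = 1, tau2 = 0.10, sigmas = s, nsim = 500)
  t2_hat <- uwlsim:::fit_block(y1, s, 0.95)$tau2
  expect_lt(abs(mean(t2_hat) - 0.10), 3 * sd(t2_hat) / sqrt(500))

  set.seed(103)
  y2 <- simulate_meta(0.5, gamma = 1.5, tau2 = 0, sigmas = s, nsim = 500)
  w <- 1 / s2
  mu_fe <- colSums(w * y2) / sum(w)
  g_hat <- colSums((y2 - rep(mu_fe, each = 1000))^2 * w) / 999
  expect_lt(abs(mean(g_hat) - 1.5), 3 * sd(g_hat) / sqrt(500))
})
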