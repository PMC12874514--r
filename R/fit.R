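# The four meta-analytic estimators.  Each internal *_core() returns a plain
# named list; meta_fit() wraps one into a classed object with the usual
# modelling methods.  The experiment engine calls the cores directly on
# matrices of replicates (see experiment.R) for speed.

GAMMA_FLOOR <- 1e-12

fe_core <- function(yi, sigma) {
  n <- length(yi)
  w <- 1 / sigma^2
  sw <- sum(w)
  mu <- sum(w * yi) / sw
  ll <- -0.5 * sum(log(2 * pi * sigma^2) + (yi - mu)^2 / sigma^2)
  list(model = "FE", mu_hat = mu, se_mu = 1 / sqrt(sw),
       tau2_hat = 0, gamma_hat = 1, loglik = ll, n_params = 1L)
}

# Profile log-likelihood maximisation over tau2 >= 0: for fixed tau2 the
# optimal mu is the weighted mean with weights 1/(sigma^2 + tau2), leaving a
# one-dimensional bounded search.  The boundary tau2 = 0 is compared against
# the interior optimum explicitly because optimize() never returns an
# endpoint exactly.
re_tau2 <- function(yi, s2, upper = NULL) {
  prof <- function(t2) {
    d <- s2 + t2
    w <- 1 / d
    mu <- sum(w * yi) / sum(w)
    -0.5 * sum(log(d) + (yi - mu)^2 / d)
  }
  if (is.null(upper)) upper <- max(10 * stats::var(yi), 1)
  opt <- stats::optimize(prof, c(0, upper), maximum = TRUE, tol = 1e-10)
  if (prof(0) >= opt$objective) 0 else opt$maximum
}

re_core <- function(yi, sigma) {
  n <- length(yi)
  if (n < 2L) stop("RE requires at least 2 studies (tau2 unidentifiable)")
  s2 <- sigma^2
  t2 <- re_tau2(yi, s2)
  d <- s2 + t2
  w <- 1 / d
  sw <- sum(w)
  mu <- sum(w * yi) / sw
  ll <- -0.5 * sum(log(2 * pi * d) + (yi - mu)^2 / d)
  list(model = "RE", mu_hat = mu, se_mu = 1 / sqrt(sw),
       tau2_hat = t2, gamma_hat = 1, loglik = ll, n_params = 2L)
}

# UWLS-FE: the multiplicative scale cancels from the weighted mean, so the
# point estimate is the FE one; the scale estimate equals the heterogeneity
# ratio H^2 = Q/(N-1) (no truncation at 1 -- values below 1 are "excessive
# homogeneity" and are meaningful).  The reported SE uses the N-1 convention
# so gamma_hat == H^2 exactly; the likelihood plugs in the ML scale Q/N so
# that information criteria compare maximised likelihoods.
uwls_fe_core <- function(yi, sigma) {
  n <- length(yi)
  if (n < 2L) stop("UWLS-FE requires at least 2 studies (gamma unidentifiable)")
  fe <- fe_core(yi, sigma)
  Q <- sum((yi - fe$mu_hat)^2 / sigma^2)
  g <- max(Q / (n - 1), GAMMA_FLOOR)
  g_ml <- max(Q / n, GAMMA_FLOOR)
  ll <- -(n / 2) * log(2 * pi) - sum(log(sigma)) - (n / 2) * log(g_ml) - n / 2
  list(model = "UWLS_FE", mu_hat = fe$mu_hat, se_mu = sqrt(g) * fe$se_mu,
       tau2_hat = 0, gamma_hat = g, loglik = ll, n_params = 2L, Q = Q)
}

# UWLS-RE: two-step.  Step 1 estimates tau2 by RE maximum likelihood; step 2
# treats it as fixed, so the weighted mean reproduces the RE point estimate
# and the scale acts on the combined variances sigma_i^2 + tau2_hat.
uwls_re_core <- function(yi, sigma) {
  n <- length(yi)
  if (n < 2L) stop("UWLS-RE requires at least 2 studies")
  re <- re_core(yi, sigma)
  d <- sigma^2 + re$tau2_hat
  v <- 1 / d
  sv <- sum(v)
  mu <- sum(v * yi) / sv
  Qs <- sum(v * (yi - mu)^2)
  g <- max(Qs / (n - 1), GAMMA_FLOOR)
  g_ml <- max(Qs / n, GAMMA_FLOOR)
  ll <- -(n / 2) * log(2 * pi) - 0.5 * sum(log(d)) - (n / 2) * log(g_ml) - n / 2
  list(model = "UWLS_RE", mu_hat = mu, se_mu = sqrt(g / sv),
       tau2_hat = re$tau2_hat, gamma_hat = g, loglik = ll, n_params = 3L)
}

#' Fit a meta-analytic model
#'
#' Fits one of four Gaussian models for study effects `yi` with reported
#' sampling SDs `sei`, differing only in their variance structure
#' Var(yi) = gamma * (sigma_i^2 + tau2):
#' \describe{
#'   \item{`"FE"`}{fixed effect: gamma = 1, tau2 = 0.  Inverse-variance
#'     weighted mean, SE = (sum 1/sigma_i^2)^(-1/2).}
#'   \item{`"RE"`}{random effects: gamma = 1, tau2 >= 0 estimated jointly
#'     with mu by maximum likelihood (profile likelihood in tau2).}
#'   \item{`"UWLS_FE"`}{unrestricted weighted least squares: tau2 = 0, free
#'     multiplicative scale gamma on the sampling variances.  Same point
#'     estimate as FE; SE multiplied by sqrt(H^2) where
#'     H^2 = Q/(N-1) and Q is Cochran's heterogeneity statistic.}
#'   \item{`"UWLS_RE"`}{two-step extension: tau2 from the RE fit is held
#'     fixed, then gamma scales the combined variances.  Same point estimate
#'     as RE.}
#' }
#'
#' The maximised log-likelihood stored in the fit uses each model's own
#' Gaussian density with any free scale plugged in at its maximum-likelihood
#' value, so `AIC()` and `BIC()` comparisons across the four models are
#' likelihood-coherent; reported scale estimates use the N-1 convention so
#' that `gamma_hat` equals the familiar H-squared statistic.
#'
#' @param yi Numeric vector of study effect estimates.
#' @param sei Numeric vector of their reported sampling standard errors
#'   (strictly positive, same length as `yi`).
#' @param model Which model to fit.
#' @param level Confidence level for the normal-quantile interval on mu.
#' @param data Optional data frame in which to look up `yi` and `sei`.
#' @return An object of class `"meta_fit"`: a list with components `model`,
#'   `mu_hat`, `se_mu`, `tau2_hat`, `gamma_hat`, `loglik`, `n_params`,
#'   `ci_low`, `ci_high`, `level`, `n`, `yi`, `sei`.  Supports `print()`,
#'   `summary()`, `coef()`, `vcov()`, `confint()`, `logLik()` (hence `AIC()`
#'   and `BIC()`), `nobs()`, `residuals()` and `plot()`.
#' @examples
#' d <- data.frame(yi = c(0.1, 0.2, 0.3), sei = c(0.3, 0.4, 0.5))
#' fit <- meta_fit(yi, sei, model = "RE", data = d)
#' coef(fit)
#' AIC(fit)
#' @seealso [fit_all_models()] to fit all four at once, [dgp_grid()] for the
#'   simulation design this package evaluates them on.
#' @export
meta_fit <- function(yi, sei, model = c("FE", "RE", "UWLS_FE", "UWLS_RE"),
                     level = 0.95, data = NULL) {
  model <- match.arg(model)
  if (!is.null(data)) {
    yi <- eval(substitute(yi), data, parent.frame())
    sei <- eval(substitute(sei), data, parent.frame())
  }
  yi <- as.numeric(yi); sei <- as.numeric(sei)
  if (length(yi) == 0L) stop("empty dataset")
  if (length(yi) != length(sei)) stop("'yi' and 'sei' must have equal length")
  if (any(!is.finite(yi)) || any(!is.finite(sei)) || any(sei <= 0))
    stop("'yi' must be finite and 'sei' finite and strictly positive")
  core <- switch(model,
    FE = fe_core(yi, sei),
    RE = re_core(yi, sei),
    UWLS_FE = uwls_fe_core(yi, sei),
    UWLS_RE = uwls_re_core(yi, sei))
  ci <- ci_bounds(core$mu_hat, core$se_mu, level)
  structure(c(core, list(ci_low = ci[1L], ci_high = ci[2L], level = level,
                         n = length(yi), yi = yi, sei = sei)),
            class = "meta_fit")
}

#' Fit all four candidate models to one dataset
#'
#' @inheritParams meta_fit
#' @return Named list of `"meta_fit"` objects in canonical model order.
#' @examples
#' fits <- fit_all_models(c(0.1, 0.2, 0.3), c(0.3, 0.4, 0.5))
#' sapply(fits, AIC)
#' @export
fit_all_models <- function(yi, sei, level = 0.95) {
  fits <- lapply(meta_models(), function(m) meta_fit(yi, sei, m, level))
  names(fits) <- meta_models()
  fits
}

ci_bounds <- function(mu, se, level) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("'level' must be a single value in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  c(mu - z * se, mu + z * se)
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat("Meta-analysis model:", x$model, " (", x$n, "studies )\n")
  cat(sprintf("  mu     = %.*f  (SE %.*f)\n", digits, x$mu_hat, digits, x$se_mu))
  cat(sprintf("  %g%% CI = [%.*f, %.*f]\n", 100 * x$level,
              digits, x$ci_low, digits, x$ci_high))
  if (x$model %in% c("RE", "UWLS_RE"))
    cat(sprintf("  tau2   = %.*f\n", digits, x$tau2_hat))
  if (x$model %in% c("UWLS_FE", "UWLS_RE"))
    cat(sprintf("  gamma  = %.*f\n", digits, x$gamma_hat))
  cat(sprintf("  logLik = %.*f  (df = %d)\n", digits, x$loglik, x$n_params))
  invisible(x)
}

#' @export
summary.meta_fit <- function(object, ...) {
  out <- object
  out$aic <- stats::AIC(object)
  out$bic <- stats::BIC(object)
  out$z <- object$mu_hat / object$se_mu
  out$pval <- 2 * stats::pnorm(-abs(out$z))
  class(out) <- "summary.meta_fit"
  out
}

#' @export
print.summary.meta_fit <- function(x, digits = 4, ...) {
  class(x) <- "meta_fit"
  print(x, digits = digits)
  cat(sprintf("  z = %.*f, p = %.4g\n", digits, x$z, x$pval))
  cat(sprintf("  AIC = %.*f, BIC = %.*f\n", digits, x$aic, digits, x$bic))
  invisible(x)
}

#' @export
coef.meta_fit <- function(object, ...) c(mu = object$mu_hat)

#' @export
vcov.meta_fit <- function(object, ...) {
  matrix(object$se_mu^2, 1, 1, dimnames = list("mu", "mu"))
}

#' @export
nobs.meta_fit <- function(object, ...) object$n

#' @export
logLik.meta_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Confidence interval for the pooled effect
#'
#' Normal-quantile interval mu_hat +/- z * se_mu at the requested level.
#'
#' @param object A `"meta_fit"`.
#' @param parm Ignored (the model has a single location parameter).
#' @param level Confidence level in (0, 1).
#' @param ... Unused.
#' @return 1 x 2 matrix of lower and upper bounds.
#' @export
confint.meta_fit <- function(object, parm = "mu", level = 0.95, ...) {
  ci <- ci_bounds(object$mu_hat, object$se_mu, level)
  matrix(ci, 1, 2, dimnames = list("mu",
         sprintf("%.1f %%", 100 * c((1 - level) / 2, (1 + level) / 2))))
}

#' @export
residuals.meta_fit <- function(object, type = c("response", "standardized"),
                               ...) {
  type <- match.arg(type)
  r <- object$yi - object$mu_hat
  if (type == "standardized")
    r <- r / sqrt(object$gamma_hat * (object$sei^2 + object$tau2_hat))
  r
}

#' Forest-style plot of a fitted meta-analysis
#'
#' Draws each study effect with its ~95% sampling interval and the pooled
#' estimate with its model-based confidence interval.
#'
#' @param x A `"meta_fit"`.
#' @param ... Passed to [graphics::plot.default()].
#' @return Invisibly, `x`.
#' @export
plot.meta_fit <- function(x, ...) {
  n <- x$n
  ylim <- c(0, n + 1.5)
  lo <- x$yi - 1.96 * x$sei
  hi <- x$yi + 1.96 * x$sei
  graphics::plot(NA, xlim = range(lo, hi, x$ci_low, x$ci_high),
                 ylim = ylim, yaxt = "n", xlab = "effect size",
                 ylab = "", ...)
  graphics::axis(2, at = c(n:1, 0), las = 1,
                 labels = c(paste("study", seq_len(n)), "pooled"))
  graphics::segments(lo, n:1, hi, n:1)
  graphics::points(x$yi, n:1, pch = 15)
  graphics::segments(x$ci_low, 0, x$ci_high, 0, lwd = 2)
  graphics::points(x$mu_hat, 0, pch = 18, cex = 1.5)
  graphics::abline(v = x$mu_hat, lty = 3, col = "grey50")
  invisible(x)
}
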