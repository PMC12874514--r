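# Data-generating processes: the calibrated parameter grid, the within-study
# SD profiles, heterogeneity typing, and the simulator.

#' Model labels used throughout the package
#'
#' The four candidate variance models, in canonical order.  The order matters:
#' it is the tie-breaking order for model selection.
#'
#' @return Character vector `c("FE", "RE", "UWLS_FE", "UWLS_RE")`.
#' @export
meta_models <- function() c("FE", "RE", "UWLS_FE", "UWLS_RE")

#' Within-study standard deviation profile for a meta-analysis of N studies
#'
#' Returns the calibrated vector of within-study sampling SDs used by the
#' simulation designs.  For N = 3, 5 and 10 these are fixed profiles chosen to
#' be representative of small medical meta-analyses (roughly 0.15--0.60,
#' increasing).  For larger N (the sample-size sweep) the N = 10 profile is
#' tiled N/10 times, preserving its dispersion shape.
#'
#' @param n_studies Number of studies; one of 3, 5, 10 or a positive multiple
#'   of 10.
#' @return Numeric vector of length `n_studies` of positive SDs.
#' @examples
#' sigma_profile(3)
#' length(sigma_profile(100))
#' @export
sigma_profile <- function(n_studies) {
  if (length(n_studies) != 1L || !is.finite(n_studies) || n_studies <= 0 ||
      n_studies != round(n_studies))
    stop("'n_studies' must be a single positive integer")
  base <- switch(as.character(n_studies),
    "3"  = c(0.30, 0.40, 0.50),
    "5"  = c(0.20, 0.30, 0.40, 0.50, 0.60),
    "10" = c(0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50, 0.55, 0.60),
    NULL)
  if (!is.null(base)) return(base)
  if (n_studies %% 10 == 0)
    return(rep(sigma_profile(10), times = n_studies %/% 10))
  stop("no sigma profile for n_studies = ", n_studies,
       " (must be 3, 5, 10 or a multiple of 10)")
}

#' Classify a DGP by its heterogeneity structure
#'
#' A data-generating process is typed by which of the four candidate models
#' it actually is: `FE` when (gamma = 1, tau2 = 0), `RE` when (gamma = 1,
#' tau2 > 0), `UWLS_FE` when (gamma != 1, tau2 = 0) and `UWLS_RE` when
#' (gamma != 1, tau2 > 0).  Equality with 1 is tested exactly; grid values
#' are assigned, never computed, so this is safe.
#'
#' @param gamma Multiplicative variance scale, > 0.  Vectorised.
#' @param tau2 Between-study variance, >= 0.  Vectorised.
#' @return Character vector of type labels.
#' @examples
#' classify_dgp(1, 0)      # "FE"
#' classify_dgp(1.5, 0.1)  # "UWLS_RE"
#' @export
classify_dgp <- function(gamma, tau2) {
  stopifnot(all(gamma > 0), all(tau2 >= 0))
  ifelse(gamma == 1,
         ifelse(tau2 == 0, "FE", "RE"),
         ifelse(tau2 == 0, "UWLS_FE", "UWLS_RE"))
}

#' The 108-cell simulation design grid
#'
#' Builds the full factorial design of simulated-meta-analysis worlds:
#' mu in \{0, 0.25, 0.50, 1.00\} x gamma in \{0.5, 1, 1.5\} x
#' tau2 in \{0, 0.01, 0.10\} x N in \{3, 5, 10\}, giving
#' 4 x 3 x 3 x 3 = 108 distinct data-generating processes.  Each row carries
#' its heterogeneity type (12 FE, 24 RE, 24 UWLS-FE, 48 UWLS-RE cells).
#'
#' @param n_studies Sample sizes to cross with the parameter values.
#'   Defaults to the main design; the sample-size sweep passes a single
#'   larger value.
#' @return A data frame with columns `dgp_id`, `mu`, `gamma`, `tau2`,
#'   `n_studies`, `dgp_type`; rows in deterministic order.  The sigma vector
#'   of row `i` is `sigma_profile(grid$n_studies[i])`.
#' @examples
#' g <- dgp_grid()
#' nrow(g)            # 108
#' table(g$dgp_type)  # 12 / 24 / 24 / 48
#' @export
dgp_grid <- function(n_studies = c(3, 5, 10)) {
  g <- expand.grid(mu = c(0, 0.25, 0.50, 1.00),
                   gamma = c(0.5, 1, 1.5),
                   tau2 = c(0, 0.01, 0.10),
                   n_studies = n_studies,
                   KEEP.OUT.ATTRS = FALSE)
  g$dgp_id <- seq_len(nrow(g))
  g$dgp_type <- classify_dgp(g$gamma, g$tau2)
  g[, c("dgp_id", "mu", "gamma", "tau2", "n_studies", "dgp_type")]
}

#' Simulate meta-analysis datasets from one DGP
#'
#' Generates study effects y_i = mu + u_i + e_i with
#' u_i ~ N(0, gamma * tau2) and e_i ~ N(0, gamma * sigma_i^2) drawn
#' independently per study.  The scale factor gamma is a latent distortion of
#' the reported sampling variances: the *unscaled* sigma_i are what a
#' meta-analyst would see, so they are returned unchanged alongside the
#' simulated effects and are what the estimators must be given.
#'
#' @param mu True mean effect.
#' @param gamma Multiplicative variance scale (> 0).
#' @param tau2 Between-study variance (>= 0).
#' @param sigmas Vector of within-study SDs; defaults to
#'   `sigma_profile(n_studies)` when `n_studies` is given instead.
#' @param n_studies Convenience alternative to `sigmas`.
#' @param nsim Number of independent datasets to draw.
#' @return For `nsim = 1` a data frame with columns `yi`, `sigma`; otherwise
#'   a numeric matrix of effects with `length(sigmas)` rows and `nsim`
#'   columns (replicate r is column r) with the sigma vector attached as
#'   attribute `"sigmas"`.
#' @examples
#' set.seed(1)
#' simulate_meta(mu = 0.5, gamma = 1, tau2 = 0, n_studies = 3)
#' @export
simulate_meta <- function(mu, gamma, tau2, sigmas = NULL, n_studies = NULL,
                          nsim = 1) {
  if (is.null(sigmas)) {
    if (is.null(n_studies)) stop("give either 'sigmas' or 'n_studies'")
    sigmas <- sigma_profile(n_studies)
  }
  stopifnot(gamma > 0, tau2 >= 0, all(sigmas > 0), nsim >= 1)
  n <- length(sigmas)
  u <- matrix(stats::rnorm(n * nsim, 0, sqrt(gamma * tau2)), n, nsim)
  e <- matrix(stats::rnorm(n * nsim, 0, sqrt(gamma) * sigmas), n, nsim)
  y <- mu + u + e
  if (nsim == 1L) return(data.frame(yi = y[, 1L], sigma = sigmas))
  attr(y, "sigmas") <- sigmas
  y
}

# Deterministic per-DGP substream seed: replicates within a DGP are indexed
# columns of one block draw, so results depend only on (master seed, dgp key,
# replicate index), never on execution order.  Kept below 2^31.
dgp_seed <- function(master_seed, dgp_key) {
  (as.double(master_seed) * 48271 + as.double(dgp_key) * 16807) %% 2147483629
}
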