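# uwlsim

Meta-analyses in medicine are typically tiny — a handful of studies, weak
signals — and that is exactly the regime where AIC and BIC select models
unreliably. This package is for meta-analysis methodologists who want to
evaluate, under known truth, the four Gaussian pooling models that frame
the current debate about "unrestricted weighted least squares" (UWLS)
estimators: does a low information criterion for UWLS mean it is the better
model of medical research, or just that the criteria fail at N = 5?

## The models

All four candidates share the skeleton

    y_i = mu + u_i + e_i,   Var(y_i | mu) = gamma * (sigma_i^2 + tau^2)

for study effects `y_i` with reported sampling SDs `sigma_i`:

* **FE** (gamma = 1, tau2 = 0): inverse-variance weighted mean,
  `SE = (sum 1/sigma_i^2)^(-1/2)`.
* **RE** (gamma = 1, tau2 >= 0): maximum likelihood, profile search over
  tau2.
* **UWLS-FE** (tau2 = 0, gamma free): same point estimate as FE; the SE is
  rescaled by `sqrt(H^2)` where `H^2 = Q/(N-1)` and
  `Q = sum (y_i - mu_hat)^2 / sigma_i^2` is Cochran's heterogeneity
  statistic. The scale is not truncated at 1 — values below 1 ("excessive
  homogeneity") are meaningful.
* **UWLS-RE** (both free, two-step): tau2 from the RE fit is held fixed,
  then gamma scales the combined variances; same point estimate as RE.

Around the estimators the package provides the full Monte Carlo apparatus:
a calibrated grid of 108 data-generating processes typed by their
heterogeneity structure, the main selection/performance experiment, a
sample-size sweep from N = 3 to N = 5000, AIC/BIC preference and
correct-selection rates, two-stage bias/RMSE/coverage aggregation, and
Mahalanobis-distance matching of empirical parameter estimates to grid
nodes for reweighted summaries.

## A worked example

```r
library(uwlsim)
d <- data.frame(effect = c(0.12, 0.35, -0.08, 0.26, 0.18),
                se     = c(0.15, 0.22, 0.18, 0.30, 0.12))
fits <- fit_all_models(d$effect, d$se)
round(sapply(fits, function(f) c(mu = f$mu_hat, se = f$se_mu,
                                 AIC = AIC(f), BIC = BIC(f))), 4)
#>          FE      RE UWLS_FE UWLS_RE
#> mu   0.1444  0.1444  0.1444  0.1444
#> se   0.0753  0.0753  0.0617  0.0617
#> AIC -3.0207 -1.0207 -1.8097  0.1903
#> BIC -3.4112 -1.8018 -2.5908 -0.9814
```

The point-estimate identities are visible immediately: FE and UWLS-FE agree
on `mu` (the scale cancels from the weighted mean), as do RE and UWLS-RE.
Here the RE heterogeneity estimate hits zero, so RE collapses onto FE and
the UWLS SE is *smaller* than FE's — the observed dispersion is below what
the reported variances predict (`H^2 < 1`). FE wins on both criteria, as it
should for five homogeneous studies.

```r
summary(fits$RE)
#> Meta-analysis model: RE  ( 5 studies )
#>   mu     = 0.1444  (SE 0.0753)
#>   95% CI = [-0.0032, 0.2919]
#>   tau2   = 0.0000
#>   logLik = 2.5103  (df = 2)
#>   z = 1.9181, p = 0.0551
#>   AIC = -1.0207, BIC = -1.8018
```

The simulation side runs the same machinery at scale:

```r
res <- run_main_experiment(experiment_config(master_seed = 1))
success_rate(res$selection, "aic")
#>      FE      RE UWLS_FE UWLS_RE
#>   73.11   10.45   39.68    0.00
```

Read: across 108 000 simulated meta-analyses, AIC finds the true model 73%
of the time when the world is fixed-effect, but essentially never when it
contains both heterogeneity and variance distortion — the information
criteria, not the estimators, are the weak link at these sample sizes. The
coverage comparison (`res$performance`) tells the companion story: RE
intervals cover the truth about 93% of the time versus about 85% for
UWLS-FE.

A thin command-line wrapper for fitting CSV files and running the
experiments ships in `inst/scripts/uwlsim.R`.

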