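---
title: "Evaluating meta-analytic estimators when AIC and BIC cannot be trusted"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating meta-analytic estimators when AIC and BIC cannot be trusted}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwlsim)
```

## The model family

Every estimator in this package works on the same observables: study effect
estimates $y_i$ with reported sampling standard deviations $\sigma_i$,
$i = 1, \dots, N$.  The common skeleton is

$$ y_i = \mu + u_i + \varepsilon_i, \qquad
   \operatorname{Var}(y_i \mid \mu) = \gamma\,(\sigma_i^2 + \tau^2), $$

where $\mu$ is the population mean effect, $\tau^2$ is additive
between-study heterogeneity of true effects, and $\gamma$ is a
multiplicative scale on the whole variance — a systematic distortion of the
reported sampling variances rather than genuine effect heterogeneity.  The
four candidate models are the four corners of $(\gamma, \tau^2)$ space:

| model | $\gamma$ | $\tau^2$ | free parameters $k$ |
|---|---|---|---|
| FE      | $= 1$    | $= 0$ | $\mu$ (1) |
| RE      | $= 1$    | $\ge 0$, ML | $\mu, \tau^2$ (2) |
| UWLS-FE | free     | $= 0$ | $\mu, \gamma$ (2) |
| UWLS-RE | free     | $\ge 0$ (two-step) | $\mu, \tau^2, \gamma$ (3) |

**FE** is the inverse-variance weighted mean with weights $1/\sigma_i^2$ and
standard error $(\sum_i 1/\sigma_i^2)^{-1/2}$.

**RE** is fitted by maximum likelihood (not REML, not DerSimonian–Laird):
for fixed $\tau^2$ the optimal $\mu$ is the weighted mean with weights
$1/(\sigma_i^2 + \tau^2)$, so the problem reduces to a one-dimensional
profile-likelihood search over $\tau^2 \ge 0$.

**UWLS-FE** relaxes only the scale: since $\gamma$ cancels from the weighted
mean, its point estimate equals FE exactly; what changes is the standard
error, which is multiplied by $\sqrt{\hat\gamma}$ with

$$ \hat\gamma = H^2 = \frac{Q}{N-1}, \qquad
   Q = \sum_i \frac{(y_i - \hat\mu)^2}{\sigma_i^2}. $$

$\hat\gamma$ is *not* truncated at 1: values below 1 ("excessive
homogeneity", e.g. from selection on significance) are part of what the
model is meant to detect.  It is floored at $10^{-12}$ only to keep the
degenerate all-identical-effects dataset finite.

**UWLS-RE** is a two-step procedure: step 1 takes $\hat\tau^2$ from the RE
maximum-likelihood fit; step 2 holds it fixed and estimates $\mu$ and
$\gamma$ by weighted least squares with weights
$1/(\sigma_i^2 + \hat\tau^2)$.  Its point estimate therefore equals RE
exactly, and $\hat\gamma = Q^*/(N-1)$ with $Q^*$ the weighted residual sum
under those weights.  Whether step 1 should use ML or another
$\tau^2$ estimator is a genuinely open choice; ML was chosen for internal
consistency with the RE model it extends.

## Likelihood and information-criterion conventions

AIC $= 2k - 2\ell$ and BIC $= k\log N - 2\ell$ require a maximised
log-likelihood per model.  Two conventions interact here and we keep them
deliberately separate:

* **Reported scale estimates** use the $N-1$ divisor, so
  $\hat\gamma \equiv H^2$ — the familiar heterogeneity ratio — and standard
  errors match what meta-analysis software reports.
* **Likelihoods** plug the scale in at its maximum-likelihood value (the
  $N$ divisor), e.g. for UWLS-FE
  $\ell = -\tfrac{N}{2}\log 2\pi - \sum_i \log\sigma_i
  - \tfrac{N}{2}\log(Q/N) - \tfrac{N}{2}$,
  so that the information criteria compare *maximised* likelihoods, as
  their derivation assumes.

$k$ is 1, 2, 2 and 3 for FE, RE, UWLS-FE and UWLS-RE.  The count of 3 for
UWLS-RE takes the model at face value (three free parameters), even though
its $\tau^2$ is estimated in a separate step; this is consistent with
UWLS-RE ranking last on both criteria across the simulated designs.
Intervals use standard-normal quantiles, matching conventional
meta-analysis practice.

## The simulated worlds

`dgp_grid()` builds the full factorial design

$$ \mu \in \{0, 0.25, 0.50, 1.00\} \times
   \gamma \in \{0.5, 1, 1.5\} \times
   \tau^2 \in \{0, 0.01, 0.10\} \times
   N \in \{3, 5, 10\}, $$

108 data-generating processes calibrated to look like small medical
meta-analyses: tiny study counts, weak signals, modest heterogeneity.  Each
cell is typed by which candidate model it truly is (12 FE, 24 RE, 24
UWLS-FE, 48 UWLS-RE cells).  The within-study SDs come from fixed increasing
profiles per $N$ (`sigma_profile()`), 0.30/0.40/0.50 at $N = 3$ up to
0.15–0.60 at $N = 10$; for the sample-size sweep beyond $N = 10$ the
10-study profile is tiled, which preserves its dispersion shape without
inventing new values.

`simulate_meta()` draws
$u_i \sim N(0, \gamma\tau^2)$ and
$\varepsilon_i \sim N(0, \gamma\sigma_i^2)$ independently per study.  Two
details matter:

* The estimators are handed the **unscaled** $\sigma_i$.  $\gamma$ is a
  latent distortion — that the reported variances may be wrong is the entire
  premise of the UWLS models.
* The generator emulates exactly this Gaussian, independent-study world.
  Real meta-analyses violate it in ways the simulation cannot speak to:
  correlated estimates from shared control arms, non-normal small-study
  effects, publication bias that selects on significance rather than merely
  rescaling variances.  Passing results here show how the estimators behave
  when their distributional assumptions hold and only the variance structure
  is at stake — not that they are robust to everything real data does.

Randomness is organised so experiments are reproducible and order
independent: each DGP receives a seed derived from the master seed and its
grid id, all replicates of a DGP are drawn as one block, and replicate $r$
is column $r$ of that block.  Sweep sizes are offset into separate seed
streams.

## The experiments

`run_main_experiment()` simulates 1000 datasets per DGP by default
(108 000 total), fits all four models to each, and records per-dataset AIC
and BIC with the argmin winner under each criterion (ties, which have
probability zero, would break toward FE, RE, UWLS-FE, UWLS-RE in that
order).  `run_samplesize_sweep()` repeats the 36 parameter combinations at
each requested $N$ from 3 to 5000.

Performance uses **two-stage aggregation**: bias, RMSE and coverage are
computed per DGP over its replicates, then averaged across DGPs with equal
weight per DGP.  With equal replicate counts the staging is inert for bias
and coverage, but averaging RMSEs is not the same as pooling squared
errors, so the stage order is part of the estimand.  RMSE is averaged on
the RMSE scale.

A fit failure (possible only in the shared $\tau^2$ search) would drop the
replicate from all four models' records, with the count reported in
`exclusions`; in practice none occur.

## Reweighting by Mahalanobis matching

Equal weight per DGP is a choice.  If an empirical corpus of meta-analyses
is available, each can be fitted with UWLS-RE — the one model that
estimates $\mu$, $\gamma$ and $\tau^2$ jointly — giving a cloud of
$(\hat\mu, \hat\gamma, \hat\tau^2, N)$ points.  `mahalanobis_match()`
assigns each point to its nearest grid node under the Mahalanobis distance
with covariance estimated from the full cloud (raw coordinates; a
log-$\gamma$ transform would be defensible but is not used), and the match
counts become DGP weights for `reweighted_performance()`.  The Mahalanobis
form makes the assignment invariant to affine rescaling of any coordinate,
which matters because $\tau^2$ and $N$ live on wildly different scales.
Distance ties break toward the lowest grid id; a singular cloud covariance
falls back to per-coordinate variance scaling.  Weight vectors can also be
supplied externally as CSV (`read_dgp_weights()`), since the corpus that
would generate them is not shipped with the package.

## Numerical choices

* The $\tau^2$ profile search runs on $[0, \max(10\,\mathrm{var}(y), 1)]$
  with `stats::optimize` at absolute tolerance $10^{-10}$; because a
  golden-section search never returns an endpoint, the boundary value
  $\ell(0)$ is compared explicitly, so $\hat\tau^2 = 0$ is exact when the
  likelihood is maximised there.
* $\gamma = 1$ classification in the grid uses exact equality — grid values
  are assigned, never computed.
* All closed-form fits in the experiment engine are vectorised across
  replicates; only the $\tau^2$ search loops, which keeps the full
  108 000-dataset experiment under half a minute on one core.

## What the two-step estimator does and does not recover

When $\gamma = 1$, the RE $\hat\tau^2$ is consistent for $\tau^2$, and when
$\tau^2 = 0$, the UWLS-FE $\hat\gamma = H^2$ is consistent for $\gamma$
(both verified by simulation in the test suite at $N = 1000$).  But the
two-step UWLS-RE decomposition is **not** jointly consistent when both
depart from their null values: step 1 assumes $\gamma = 1$, so its
$\hat\tau^2$ absorbs part of the scale.  Under
$(\gamma = 1.5, \tau^2 = 0.1)$ at $N = 1000$ the procedure converges to
roughly $\hat\tau^2 \approx 0.20$, $\hat\gamma \approx 1.04$.  This is a
property of the two-step construction itself, not of the implementation;
it is harmless for the selection and coverage experiments (which evaluate
each model on its own terms) but means UWLS-RE parameter estimates should
not be read as a clean $(\gamma, \tau^2)$ decomposition.

## Problem sizes in the shipped tests

The test suite runs the full design at 1000 replicates per DGP once
(shared across the end-to-end checks), the $N \in \{3, 5\}$ sweep cells at
1000 replicates, and the $N = 5000$ cell at 200 replicates with
correspondingly wider tolerance; unit tests use 10–250 replicates.  Those
sizes make the whole suite complete in about a minute while keeping the
Monte-Carlo error of every checked quantity well inside its assertion band.

## A worked example

```{r}
d <- data.frame(effect = c(0.12, 0.35, -0.08, 0.26, 0.18),
                se = c(0.15, 0.22, 0.18, 0.30, 0.12))
fits <- fit_all_models(d$effect, d$se)
sapply(fits, function(f) c(mu = f$mu_hat, se = f$se_mu,
                           AIC = AIC(f), BIC = BIC(f)))
```

```{r, fig.width = 5, fig.height = 3.5}
plot(fits$RE)
```

And a reduced-size run of the main experiment:

```{r}
res <- run_main_experiment(experiment_config(master_seed = 1,
                                             replicates_per_dgp = 50))
res
```

## Known limitations

* The grid, SD profiles and tiling rule are fixed calibration choices;
  results for very large $N$ depend on the tiling assumption.
* Only Gaussian likelihood-based fitting is provided — no REML,
  DerSimonian–Laird, Paule–Mandel or Knapp–Hartung variants, no
  meta-regression, no publication-bias corrections.
* Reweighted summaries are only as representative as the parameter cloud
  fed to the matcher; the package ships no empirical corpus.
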