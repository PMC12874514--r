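# Monte Carlo experiment runners.  Within a DGP all replicates are simulated
# as one block and every closed-form quantity is computed column-wise; only
# the one-dimensional RE likelihood search runs per replicate.  Replicate r
# is always column r of the block, so results depend only on (master seed,
# DGP key, replicate index), never on execution order.

#' Experiment configuration
#'
#' Bundles the knobs of the simulation study.  The defaults are the study
#' conditions: 1000 replicates for each DGP of the 108-cell design, 95%
#' intervals, and the sample-size sweep 3, 5, 10, 100, 500, 1000, 5000.
#'
#' @param master_seed Integer master seed; every random draw in an
#'   experiment derives from it.
#' @param replicates_per_dgp Simulated datasets per DGP (>= 1).
#' @param sweep_sizes Sample sizes for [run_samplesize_sweep()].
#' @param ci_level Confidence level for coverage.
#' @param output_dir Optional directory: when set, runners write their CSV
#'   tables there.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(master_seed = 1, replicates_per_dgp = 1000,
                              sweep_sizes = c(3, 5, 10, 100, 500, 1000, 5000),
                              ci_level = 0.95, output_dir = NULL) {
  stopifnot(replicates_per_dgp >= 1, length(master_seed) == 1,
            ci_level > 0, ci_level < 1)
  for (s in sweep_sizes) sigma_profile(s)  # validate early
  structure(list(master_seed = as.integer(master_seed),
                 replicates_per_dgp = as.integer(replicates_per_dgp),
                 sweep_sizes = sweep_sizes, ci_level = ci_level,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Recognised keys: `master_seed`, `replicates_per_dgp`, `sweep_sizes`,
#' `ci_level`, `output_dir`; missing keys take the defaults of
#' [experiment_config()].
#'
#' @param path Path to a YAML file.
#' @return An `"experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(experiment_config)))
  do.call(experiment_config, vals[keep])
}

# All four estimators on an n x reps block of simulated effects.
# Returns per-replicate vectors for each model plus the RE tau2 estimates.
fit_block <- function(y, sigmas, level) {
  n <- length(sigmas)
  reps <- ncol(y)
  s2 <- sigmas^2
  z <- stats::qnorm((1 + level) / 2)

  w <- 1 / s2
  sw <- sum(w)
  mu_fe <- colSums(w * y) / sw
  se_fe <- 1 / sqrt(sw)
  resid <- y - rep(mu_fe, each = n)
  Q <- colSums(resid^2 * w)
  ll_fe <- -0.5 * (sum(log(2 * pi * s2)) + Q)

  g_uf <- pmax(Q / (n - 1), GAMMA_FLOOR)
  se_uf <- sqrt(g_uf) * se_fe
  ll_uf <- -(n / 2) * log(2 * pi) - sum(log(sigmas)) -
    (n / 2) * log(pmax(Q / n, GAMMA_FLOOR)) - n / 2

  cm <- colMeans(y)
  vy <- colSums((y - rep(cm, each = n))^2) / (n - 1)
  ub <- pmax(10 * vy, 1)
  t2 <- vapply(seq_len(reps), function(r)
    tryCatch(re_tau2(y[, r], s2, upper = ub[r]), error = function(e) NA_real_),
    0)
  D <- matrix(s2, n, reps) + matrix(t2, n, reps, byrow = TRUE)
  V <- 1 / D
  sv <- colSums(V)
  mu_re <- colSums(V * y) / sv
  se_re <- 1 / sqrt(sv)
  resid_re <- y - rep(mu_re, each = n)
  wrss <- colSums(resid_re^2 * V)
  ll_re <- -0.5 * (colSums(log(2 * pi * D)) + wrss)

  g_ur <- pmax(wrss / (n - 1), GAMMA_FLOOR)
  se_ur <- sqrt(g_ur / sv)
  ll_ur <- -(n / 2) * log(2 * pi) - 0.5 * colSums(log(D)) -
    (n / 2) * log(pmax(wrss / n, GAMMA_FLOOR)) - n / 2

  list(mu = cbind(FE = mu_fe, RE = mu_re, UWLS_FE = mu_fe, UWLS_RE = mu_re),
       se = cbind(FE = rep(se_fe, reps), RE = se_re,
                  UWLS_FE = se_uf, UWLS_RE = se_ur),
       ll = cbind(FE = ll_fe, RE = ll_re, UWLS_FE = ll_uf, UWLS_RE = ll_ur),
       tau2 = t2, z = z, k = c(FE = 1, RE = 2, UWLS_FE = 2, UWLS_RE = 3),
       failed = which(is.na(t2)))
}

# Selection records + per-DGP performance for one DGP.
run_dgp <- function(spec, sigmas, reps, seed, level) {
  set.seed(seed)
  y <- simulate_meta(spec$mu, spec$gamma, spec$tau2, sigmas, nsim = max(reps, 2))
  if (reps == 1L) y <- y[, 1L, drop = FALSE]
  fb <- fit_block(y, sigmas, level)
  ok <- setdiff(seq_len(reps), fb$failed)
  n <- length(sigmas)

  aic <- sweep(-2 * fb$ll, 2, 2 * fb$k, "+")
  bic <- sweep(-2 * fb$ll, 2, fb$k * log(n), "+")
  models <- meta_models()
  sel <- data.frame(
    dgp_id = spec$dgp_id, replicate = ok, true_type = spec$dgp_type,
    aic[ok, , drop = FALSE], bic[ok, , drop = FALSE])
  names(sel)[4:11] <- c(paste0("aic_", models), paste0("bic_", models))
  sel$winner_aic <- models[max.col(-aic[ok, , drop = FALSE],
                                   ties.method = "first")]
  sel$winner_bic <- models[max.col(-bic[ok, , drop = FALSE],
                                   ties.method = "first")]

  perf <- do.call(rbind, lapply(models, function(m) {
    mu_h <- fb$mu[ok, m]
    se_h <- fb$se[ok, m]
    met <- per_dgp_metrics(mu_h, mu_h - fb$z * se_h, mu_h + fb$z * se_h,
                           spec$mu)
    data.frame(dgp_id = spec$dgp_id, dgp_type = spec$dgp_type, estimator = m,
               bias = met[["bias"]], rmse = met[["rmse"]],
               coverage = met[["coverage"]])
  }))
  list(selection = sel, per_dgp = perf, n_failed = length(fb$failed))
}

#' Run the main 108-DGP selection and performance experiment
#'
#' For every DGP in the grid, simulates `replicates_per_dgp` meta-analysis
#' datasets, fits all four models to each, records AIC/BIC and the argmin
#' winners, and computes per-DGP bias, RMSE and coverage for each estimator.
#' Deterministic given the master seed.
#'
#' @param config An [experiment_config()]; individual arguments below
#'   override its fields.
#' @param master_seed,replicates_per_dgp,ci_level See [experiment_config()].
#' @param grid The DGP design; defaults to the full 108-cell [dgp_grid()].
#' @param seed_offset Internal key offset separating seed streams of
#'   different experiments run under one master seed.
#' @return A list of class `"meta_experiment"`: `selection` (one row per
#'   simulated dataset), `per_dgp` (one row per DGP x estimator),
#'   `performance` (the two-stage aggregate, equal weight per DGP),
#'   `exclusions` (count of failed fits, normally 0), `config`.  If
#'   `config$output_dir` is set the summary CSVs are written there.
#' @examples
#' \donttest{
#' res <- run_main_experiment(experiment_config(master_seed = 1,
#'                                              replicates_per_dgp = 20))
#' success_rate(res$selection, "aic")
#' }
#' @export
run_main_experiment <- function(config = experiment_config(),
                                master_seed = config$master_seed,
                                replicates_per_dgp = config$replicates_per_dgp,
                                ci_level = config$ci_level,
                                grid = dgp_grid(), seed_offset = 0) {
  reps <- replicates_per_dgp
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- grid[i, ]
    out[[i]] <- run_dgp(spec, sigma_profile(spec$n_studies), reps,
                        dgp_seed(master_seed, spec$dgp_id + seed_offset),
                        ci_level)
  }
  selection <- do.call(rbind, lapply(out, `[[`, "selection"))
  per_dgp <- do.call(rbind, lapply(out, `[[`, "per_dgp"))
  rownames(selection) <- rownames(per_dgp) <- NULL
  res <- structure(list(selection = selection, per_dgp = per_dgp,
                        performance = aggregate_metrics(per_dgp),
                        exclusions = sum(vapply(out, `[[`, 0, "n_failed")),
                        config = config, grid = grid),
                   class = "meta_experiment")
  if (!is.null(config$output_dir)) write_experiment_tables(res,
                                                           config$output_dir)
  res
}

#' @export
print.meta_experiment <- function(x, ...) {
  cat("Meta-analysis simulation experiment\n")
  cat("  DGPs:", nrow(x$grid), "  datasets:", nrow(x$selection),
      "  excluded fits:", x$exclusions, "\n")
  cat("  AIC correct-selection rates by true type:\n")
  print(round(success_rate(x$selection, "aic"), 1))
  cat("  Full-sample coverage (%):\n")
  cov <- subset(x$performance, x$performance$group == "ALL")
  print(stats::setNames(round(cov$coverage, 1), cov$estimator))
  invisible(x)
}

#' Run the sample-size sweep
#'
#' Instantiates the 36 (mu, gamma, tau2) parameter combinations at each
#' requested sample size, simulates `replicates_per_dgp` datasets per DGP,
#' and tabulates how often AIC and BIC select the true model, by
#' heterogeneity type.  Sample sizes beyond the base profiles tile the
#' 10-study SD profile (see [sigma_profile()]).
#'
#' @inheritParams run_main_experiment
#' @param sizes Sample sizes to sweep over.
#' @return Data frame with columns `n_studies`, `dgp_type`, `criterion`,
#'   `success` (percent correct selections), plus attribute `"selection"`
#'   holding the per-size record list.  Written as `table6.csv` when
#'   `config$output_dir` is set.
#' @export
run_samplesize_sweep <- function(config = experiment_config(),
                                 sizes = config$sweep_sizes,
                                 master_seed = config$master_seed,
                                 replicates_per_dgp = config$replicates_per_dgp,
                                 ci_level = config$ci_level) {
  rows <- list()
  for (s in sizes) {
    grid_s <- dgp_grid(n_studies = s)
    res <- run_main_experiment(config = experiment_config(
                                 master_seed = master_seed,
                                 replicates_per_dgp = replicates_per_dgp,
                                 ci_level = ci_level),
                               grid = grid_s, seed_offset = s * 1000L)
    for (crit in c("aic", "bic")) {
      sr <- success_rate(res$selection, crit)
      rows[[length(rows) + 1L]] <- data.frame(
        n_studies = s, dgp_type = names(sr), criterion = crit,
        success = unname(sr))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(config$output_dir, "table6.csv"),
                     row.names = FALSE)
  }
  out
}

#' Reweighted performance summary
#'
#' Applies a DGP weight vector (e.g. from [mahalanobis_match()] on an
#' empirical parameter cloud, or read from CSV) to the per-DGP metrics of a
#' finished experiment.
#'
#' @param experiment A `"meta_experiment"`.
#' @param weights Named non-negative weights over `dgp_id`.
#' @return As [aggregate_metrics()].
#' @export
reweighted_performance <- function(experiment, weights) {
  aggregate_metrics(experiment$per_dgp, weights)
}

#' Write the summary tables of an experiment as CSV
#'
#' Emits long-format CSV analogues of the study's summary tables:
#' `table4.csv` (full-sample mean IC values and pairwise preference rates),
#' `table5.csv` (per-type mean IC values and correct-selection rates) and
#' `table7a.csv` (two-stage bias/RMSE/coverage).
#'
#' @param experiment A `"meta_experiment"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_experiment_tables <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- experiment$selection
  t4 <- list()
  for (crit in c("aic", "bic")) {
    avg <- average_ic_table(rec, crit)
    t4[[length(t4) + 1L]] <- data.frame(criterion = crit, panel = "average_ic",
                                        model = avg$model, value = avg$mean_ic)
    t4[[length(t4) + 1L]] <- data.frame(
      criterion = crit, panel = "pref_uwls_fe_vs_re", model = "UWLS_FE",
      value = preference_rate(rec, "UWLS_FE", "RE", crit))
    t4[[length(t4) + 1L]] <- data.frame(
      criterion = crit, panel = "pref_uwls_fe_vs_fe", model = "UWLS_FE",
      value = preference_rate(rec, "UWLS_FE", "FE", crit))
  }
  t4 <- do.call(rbind, t4)
  t5 <- list()
  for (crit in c("aic", "bic")) {
    for (ty in unique(rec$true_type)) {
      avg <- average_ic_table(rec, crit, group = ty)
      t5[[length(t5) + 1L]] <- data.frame(criterion = crit, true_type = ty,
                                          panel = "average_ic",
                                          model = avg$model,
                                          value = avg$mean_ic)
    }
    sr <- success_rate(rec, crit)
    t5[[length(t5) + 1L]] <- data.frame(criterion = crit, true_type = names(sr),
                                        panel = "success_rate",
                                        model = names(sr), value = unname(sr))
  }
  t5 <- do.call(rbind, t5)
  files <- c(table4 = file.path(dir, "table4.csv"),
             table5 = file.path(dir, "table5.csv"),
             table7a = file.path(dir, "table7a.csv"))
  utils::write.csv(t4, files["table4"], row.names = FALSE)
  utils::write.csv(t5, files["table5"], row.names = FALSE)
  utils::write.csv(experiment$performance, files["table7a"], row.names = FALSE)
  invisible(files)
}
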