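# Estimator performance: bias, RMSE and coverage, aggregated in two stages
# (within each DGP over its replicates, then equally -- or by supplied
# weights -- across DGPs).  The staging matters: RMSE is averaged on the
# RMSE scale across DGPs, which is not the same as pooling squared errors
# over all datasets.

#' Bias, RMSE and coverage for one DGP/estimator cell
#'
#' @param mu_hat Numeric vector of point estimates across replicates.
#' @param ci_low,ci_high Matching confidence-interval bounds.
#' @param true_mu The DGP's true mean effect.
#' @return Named vector `c(bias, rmse, coverage)`; coverage in percent.
#' @examples
#' per_dgp_metrics(c(0.9, 1.1), c(0.85, 1.05), c(0.95, 1.15), true_mu = 1)
#' @export
per_dgp_metrics <- function(mu_hat, ci_low, ci_high, true_mu) {
  if (length(mu_hat) == 0L) stop("no fits supplied")
  stopifnot(length(ci_low) == length(mu_hat),
            length(ci_high) == length(mu_hat))
  err <- mu_hat - true_mu
  c(bias = mean(err),
    rmse = sqrt(mean(err^2)),
    coverage = 100 * mean(ci_low <= true_mu & true_mu <= ci_high))
}

#' Aggregate per-DGP metrics across the design
#'
#' Second aggregation stage: per-DGP bias, RMSE and coverage are averaged
#' across DGPs with equal weight per DGP, for the full design (`ALL`) and
#' within each heterogeneity type.  Supplying `weights` (e.g. from
#' [mahalanobis_match()]) replaces the equal weighting with a weighted
#' average; weights are renormalised within each group.
#'
#' @param per_dgp Data frame with one row per (dgp, estimator): columns
#'   `dgp_id`, `dgp_type`, `estimator`, `bias`, `rmse`, `coverage` (as
#'   produced by [run_main_experiment()]).
#' @param weights Optional named numeric vector of non-negative weights,
#'   names = `dgp_id`; DGPs absent from `weights` get weight 0.
#' @return Data frame with columns `group` (ALL plus the types present),
#'   `estimator`, `bias`, `rmse`, `coverage`.
#' @export
aggregate_metrics <- function(per_dgp, weights = NULL) {
  need <- c("dgp_id", "dgp_type", "estimator", "bias", "rmse", "coverage")
  if (!all(need %in% names(per_dgp))) stop("missing columns in 'per_dgp'")
  if (anyNA(per_dgp[need])) stop("missing cells in 'per_dgp'")
  cells <- table(per_dgp$dgp_id, per_dgp$estimator)
  if (any(cells != 1)) stop("missing cells in 'per_dgp': every DGP needs ",
                            "exactly one row per estimator")
  w_of <- function(ids) {
    if (is.null(weights)) return(rep(1, length(ids)))
    w <- weights[as.character(ids)]
    w[is.na(w)] <- 0
    if (any(w < 0)) stop("negative weights")
    unname(w)
  }
  groups <- c("ALL", meta_models()[meta_models() %in% per_dgp$dgp_type])
  rows <- lapply(groups, function(g) {
    sub <- if (g == "ALL") per_dgp else per_dgp[per_dgp$dgp_type == g, ]
    if (sum(w_of(unique(sub$dgp_id))) <= 0) {
      # a subgroup can legitimately receive no empirical weight; the full
      # design must not
      if (g == "ALL") stop("zero total weight over the design")
      warning("no weight on group ", g, "; group omitted", call. = FALSE)
      return(NULL)
    }
    do.call(rbind, lapply(split(sub, sub$estimator), function(s) {
      w <- w_of(s$dgp_id)
      w <- w / sum(w)
      data.frame(group = g, estimator = s$estimator[1L],
                 bias = sum(w * s$bias), rmse = sum(w * s$rmse),
                 coverage = sum(w * s$coverage))
    }))
  })
  out <- do.call(rbind, rows)
  out$estimator <- factor(out$estimator, levels = meta_models())
  out <- out[order(match(out$group, groups), out$estimator), ]
  out$estimator <- as.character(out$estimator)
  rownames(out) <- NULL
  out
}
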