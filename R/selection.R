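# Information-criterion model selection and its aggregation into preference
# and correct-selection rates.
#
# Selection records are data frames with one row per simulated dataset and
# columns dgp_id, replicate, true_type, aic_<MODEL> and bic_<MODEL> for each
# of the four models, plus winner_aic / winner_bic.

#' AIC and BIC for all four models on one dataset
#'
#' Convenience wrapper: fits all four candidate models and tabulates their
#' maximised log-likelihood, parameter count, AIC (2k - 2 logLik) and BIC
#' (k log N - 2 logLik, N = number of studies).
#'
#' @inheritParams meta_fit
#' @return Data frame with one row per model, columns `model`, `logLik`,
#'   `df`, `AIC`, `BIC`, in canonical model order.
#' @examples
#' ic_table(c(0.1, 0.2, 0.3), c(0.3, 0.4, 0.5))
#' @export
ic_table <- function(yi, sei, level = 0.95) {
  fits <- fit_all_models(yi, sei, level)
  data.frame(model = meta_models(),
             logLik = vapply(fits, function(f) f$loglik, 0),
             df = vapply(fits, function(f) as.double(f$n_params), 0),
             AIC = vapply(fits, stats::AIC, 0),
             BIC = vapply(fits, stats::BIC, 0),
             row.names = NULL)
}

#' Pick the winning model from a named criterion map
#'
#' Argmin over criterion values; exact ties are broken in the canonical order
#' FE, RE, UWLS_FE, UWLS_RE.  Ties have probability zero with continuous
#' data, but the rule keeps selection deterministic.
#'
#' @param values Named numeric vector of criterion values (names are model
#'   labels).
#' @return The winning model label.
#' @examples
#' select_best(c(FE = 5, RE = 5, UWLS_FE = 7, UWLS_RE = 8))  # "FE" by tie order
#' @export
select_best <- function(values) {
  if (length(values) == 0L) stop("empty criterion map")
  ord <- meta_models()[meta_models() %in% names(values)]
  if (length(ord) == 0L) ord <- names(values)
  values <- values[ord]
  ord[which.min(values)]
}

ic_cols <- function(criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  stats::setNames(paste0(criterion, "_", meta_models()), meta_models())
}

#' Rate at which one model is preferred to another
#'
#' Percentage of datasets in which model `a` attains a *strictly* lower
#' criterion value than model `b`; ties count against `a`.
#'
#' @param records Selection-record data frame (see [run_main_experiment()]).
#' @param a,b Model labels.
#' @param criterion `"aic"` or `"bic"`.
#' @return Percentage in \[0, 100\].
#' @export
preference_rate <- function(records, a, b, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(records) > 0)
  cols <- ic_cols(criterion)
  100 * mean(records[[cols[[a]]]] < records[[cols[[b]]]])
}

#' Correct-model selection rate by DGP type
#'
#' For each heterogeneity type, the percentage of datasets generated under
#' that type for which the criterion's argmin model equals the type.
#'
#' @inheritParams preference_rate
#' @return Named numeric vector of percentages, one per type present.
#' @export
success_rate <- function(records, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(records) > 0)
  winner <- records[[paste0("winner_", criterion)]]
  rates <- tapply(winner == records$true_type, records$true_type,
                  function(ok) 100 * mean(ok))
  types <- meta_models()[meta_models() %in% names(rates)]
  stats::setNames(as.numeric(rates[types]), types)
}

#' Mean information-criterion values, ranked best to worst
#'
#' Averages a criterion across datasets (optionally within a subgroup) for
#' each model and returns the models sorted ascending, smallest (best) first.
#' Note that averaging across datasets of different N mixes likelihood
#' scales; that is deliberate -- it mirrors how the criterion values are
#' summarised in the study design this package reproduces.
#'
#' @inheritParams preference_rate
#' @param group Optional subset: a `true_type` label, or a logical/integer
#'   row index.
#' @return Data frame with columns `model`, `mean_ic`, sorted ascending.
#' @export
average_ic_table <- function(records, criterion = c("aic", "bic"),
                             group = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(group)) {
    if (is.character(group)) records <- records[records$true_type %in% group, ]
    else records <- records[group, ]
  }
  stopifnot(nrow(records) > 0)
  cols <- ic_cols(criterion)
  means <- vapply(cols, function(cn) mean(records[[cn]]), 0)
  out <- data.frame(model = names(means), mean_ic = unname(means))
  out[order(out$mean_ic), , drop = FALSE]
}

#' Winner frequencies per criterion
#'
#' Percentage of datasets won by each model under a criterion; sums to 100.
#'
#' @inheritParams preference_rate
#' @return Named numeric vector over the four models.
#' @export
selection_frequencies <- function(records, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  winner <- factor(records[[paste0("winner_", criterion)]],
                   levels = meta_models())
  out <- 100 * as.vector(prop.table(table(winner)))
  stats::setNames(out, meta_models())
}
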