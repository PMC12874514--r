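# Mahalanobis-distance matching of empirical parameter estimates to grid
# DGPs.  Each fitted meta-analysis contributes a point (mu_hat, gamma_hat,
# tau2_hat, N); matching the cloud to the design grid yields per-DGP weights
# for reweighted performance summaries.

#' Match a parameter cloud to the DGP grid by Mahalanobis distance
#'
#' Estimates a 4 x 4 covariance from the pooled point cloud over the raw
#' coordinates (mu, gamma, tau2, N), assigns each point to the grid node
#' minimising the Mahalanobis distance under that covariance, and returns
#' per-node weights proportional to match counts.  Mahalanobis distance makes
#' the assignment invariant to affine rescaling of any coordinate, so the
#' very different scales of the four coordinates do not bias the matching.
#' If the cloud covariance is singular (e.g. a coordinate is constant), the
#' matcher falls back to a diagonal covariance of per-coordinate variances
#' (zero variances replaced by 1), with a message.
#'
#' Ties in distance are broken toward the lowest `dgp_id`.
#'
#' @param points Data frame with columns `mu`, `gamma`, `tau2`, `n_studies`
#'   (one row per fitted meta-analysis; at least 2 rows).
#' @param grid DGP grid as from [dgp_grid()].
#' @return Named numeric vector of weights over `grid$dgp_id` (all nodes,
#'   zero where unmatched), summing to 1, with the integer vector of
#'   per-point assignments attached as attribute `"assignment"`.
#' @examples
#' g <- dgp_grid()
#' pts <- data.frame(mu = c(0, 1), gamma = c(1, 1.5),
#'                   tau2 = c(0, 0.1), n_studies = c(3, 10))
#' w <- mahalanobis_match(pts, g)
#' sum(w)  # 1
#' @export
mahalanobis_match <- function(points, grid) {
  need <- c("mu", "gamma", "tau2", "n_studies")
  if (!all(need %in% names(points))) stop("'points' needs columns ",
                                          paste(need, collapse = ", "))
  if (nrow(points) < 2L) stop("need at least 2 points to estimate covariance")
  if (nrow(grid) == 0L) stop("empty grid")
  X <- as.matrix(points[, need])
  if (any(!is.finite(X))) stop("non-finite parameter values")
  G <- as.matrix(grid[, need])
  S <- stats::cov(X)
  use_diag <- !is.finite(rcond_sym(S)) || rcond_sym(S) < 1e-12
  if (use_diag) {
    message("singular point-cloud covariance; falling back to diagonal scaling")
    v <- diag(S)
    v[v <= 0] <- 1
    S <- diag(v, nrow = 4L)
  }
  Sinv <- solve(S)
  # squared Mahalanobis distance from every point to every grid node
  assign_idx <- integer(nrow(X))
  d2 <- matrix(0, nrow(X), nrow(G))
  for (j in seq_len(nrow(G)))
    d2[, j] <- stats::mahalanobis(X, center = G[j, ], cov = Sinv,
                                  inverted = TRUE)
  ord <- order(grid$dgp_id)
  for (i in seq_len(nrow(X))) {
    di <- d2[i, ord]
    assign_idx[i] <- ord[which.min(di)]  # which.min: first min => lowest dgp_id
  }
  counts <- tabulate(assign_idx, nbins = nrow(grid))
  w <- counts / sum(counts)
  names(w) <- as.character(grid$dgp_id)
  attr(w, "assignment") <- grid$dgp_id[assign_idx]
  w
}

# reciprocal condition number of a symmetric matrix via its eigenvalues
rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev)) return(NA_real_)
  if (max(abs(ev)) == 0) return(0)
  min(ev) / max(abs(ev))
}

#' Read / write parameter clouds and weight vectors
#'
#' Plain-CSV interchange for the matching pipeline: point clouds have
#' columns `mu`, `gamma`, `tau2`, `n_studies`; weight vectors have columns
#' `dgp_id`, `weight`.  Externally supplied weight files (for users with the
#' empirical corpus the grid was calibrated to) plug directly into
#' [aggregate_metrics()].
#'
#' @param path File path.
#' @param points,weights Objects to write.
#' @return Readers return a data frame (`read_parameter_cloud`) or a named
#'   numeric vector (`read_dgp_weights`); writers return `path` invisibly.
#' @name weights_io
NULL

#' @rdname weights_io
#' @export
read_parameter_cloud <- function(path) {
  pts <- utils::read.csv(path)
  need <- c("mu", "gamma", "tau2", "n_studies")
  if (!all(need %in% names(pts))) stop("point-cloud CSV needs columns ",
                                       paste(need, collapse = ", "))
  pts[, need]
}

#' @rdname weights_io
#' @export
write_parameter_cloud <- function(points, path) {
  utils::write.csv(points[, c("mu", "gamma", "tau2", "n_studies")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname weights_io
#' @export
read_dgp_weights <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("dgp_id", "weight") %in% names(d)))
    stop("weight CSV needs columns dgp_id, weight")
  stats::setNames(d$weight, as.character(d$dgp_id))
}

#' @rdname weights_io
#' @export
write_dgp_weights <- function(weights, path) {
  utils::write.csv(data.frame(dgp_id = names(weights),
                              weight = as.numeric(weights)),
                   path, row.names = FALSE)
  invisible(path)
}
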