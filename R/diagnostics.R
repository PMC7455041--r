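#' @title Convergence diagnostics from ensemble-weight distributions
#' @description Whether the protocol converged onto a subset of
#'   better-performing base learners can be read off the ensemble weights:
#'   across all M subsamples the mean weights are flat (most subsamples
#'   carry no signal), while across the top M* models informative learners
#'   should dominate — unless the data are pure noise, in which case the
#'   two distributions stay indistinguishable. Bray-Curtis dissimilarity
#'   against a matched Null-generator run and the variance of the weights
#'   over M* quantify that contrast.
#' @name diagnostics
NULL

#' Mean ensemble weights over the top M* models
#'
#' @param records List of `performance_record`s.
#' @param m_star How many top-ranked records to average over (default all).
#' @param metric Ranking metric.
#' @return Named numeric vector of length L on the simplex.
#' @export
mean_learner_weights <- function(records, m_star = length(records),
                                 metric = c("accuracy", "mse")) {
  metric <- match.arg(metric)
  if (m_star > length(records)) {
    stop("m_star exceeds the number of records", call. = FALSE)
  }
  W <- weights_matrix(top_records(records, metric, m_star))
  colMeans(W)
}

#' Learner-selection cutoff from the all-M weight distribution
#'
#' Uses the largest mean weight at M* = M as a cutoff: learners whose mean
#' weight at the optimal M* strictly exceeds it are flagged as the
#' "true positive" algorithms the protocol converged to. On pure-noise data
#' no learner should clear the bar.
#'
#' @param records List of `performance_record`s (all M).
#' @param optimal_m_star The optimal M* (e.g. from [run_slicer()]).
#' @param metric Ranking metric.
#' @return List with `cutoff`, `mean_at_m` (weights at M),
#'   `mean_at_optimal` (weights at the optimal M*), and `selected`
#'   (character vector of flagged learners).
#' @export
learner_weight_cutoff <- function(records, optimal_m_star = length(records),
                                  metric = c("accuracy", "mse")) {
  metric <- match.arg(metric)
  mean_at_m <- mean_learner_weights(records, length(records), metric)
  mean_at_opt <- mean_learner_weights(records, optimal_m_star, metric)
  cutoff <- max(mean_at_m)
  list(cutoff = cutoff, mean_at_m = mean_at_m,
       mean_at_optimal = mean_at_opt,
       selected = names(mean_at_opt)[mean_at_opt > cutoff])
}

#' Bray-Curtis dissimilarity
#'
#' `BC(u, v) = sum(|u - v|) / sum(u + v)` for non-negative vectors; 0 for
#' identical vectors, 1 for disjoint supports.
#'
#' @param u,v Non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(0.5, 0.5), c(1, 0))  # 0.5
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length",
                                   call. = FALSE)
  if (any(u < 0) || any(v < 0)) stop("inputs must be non-negative",
                                     call. = FALSE)
  tot <- sum(u + v)
  if (tot == 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(u - v)) / tot
}

#' Weight trajectories over M*
#'
#' For each M* in the grid, computes (1) the Bray-Curtis dissimilarity
#' between the analysis run's mean weights over its top M* models and a
#' reference Null run's mean weights over its own top M*, and (2) the
#' variance of all (record x learner) weight entries among the analysis
#' run's top M* (with a per-learner breakdown). On signal-bearing data the
#' variance falls as M* shrinks toward the informative models; on Null data
#' both trajectories stay flat. The argmin of the variance is reported as
#' an alternative optimal-M* estimate.
#'
#' @param records_analysis Records of the analysis run.
#' @param records_reference_null Records of a Null-generator run under the
#'   same plan and learner registry.
#' @param m_star_grid M* values to scan (default: 6 log-spaced values up to
#'   M).
#' @param metric Ranking metric.
#' @return An object of class `trajectory_set`: `m_star_grid`, `bc_values`,
#'   `variance_values`, `per_learner_variance` (matrix M* x L),
#'   `optimal_m_star_variance`.
#' @export
weight_trajectories <- function(records_analysis, records_reference_null,
                                m_star_grid = NULL,
                                metric = c("accuracy", "mse")) {
  metric <- match.arg(metric)
  nms <- names(records_analysis[[1]]$weights)
  if (!identical(nms, names(records_reference_null[[1]]$weights))) {
    stop("analysis and reference runs used different learner registries",
         call. = FALSE)
  }
  M <- length(records_analysis)
  if (is.null(m_star_grid)) {
    m_star_grid <- unique(round(exp(seq(log(max(10, M / 50)), log(M),
                                        length.out = 6))))
  }
  m_star_grid <- sort(unique(pmin(m_star_grid, M)))
  ranked_a <- top_records(records_analysis, metric, M)
  ranked_0 <- top_records(records_reference_null, metric,
                          length(records_reference_null))
  bc <- var_all <- numeric(length(m_star_grid))
  per_learner <- matrix(NA_real_, length(m_star_grid), length(nms),
                        dimnames = list(m_star_grid, nms))
  for (i in seq_along(m_star_grid)) {
    m_star <- m_star_grid[i]
    Wa <- weights_matrix(ranked_a[seq_len(m_star)])
    m0 <- min(m_star, length(ranked_0))
    W0 <- weights_matrix(ranked_0[seq_len(m0)])
    bc[i] <- bray_curtis(colMeans(Wa), colMeans(W0))
    var_all[i] <- stats::var(as.vector(Wa))
    per_learner[i, ] <- apply(Wa, 2, stats::var)
  }
  structure(
    list(m_star_grid = m_star_grid, bc_values = bc,
         variance_values = var_all, per_learner_variance = per_learner,
         optimal_m_star_variance = m_star_grid[which.min(var_all)]),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set>\n")
  cat("  M*:      ", paste(x$m_star_grid, collapse = " "), "\n")
  cat("  BC:      ", paste(sprintf("%.3f", x$bc_values), collapse = " "), "\n")
  cat("  var:     ", paste(signif(x$variance_values, 3), collapse = " "), "\n")
  cat(sprintf("  variance-argmin M* = %d\n", x$optimal_m_star_variance))
  invisible(x)
}
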