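#' @title Feature mining from top-ranked subsample models
#' @description The training-stage read-out: rank the M subsample models by
#'   validation performance, tabulate how often each feature appears among
#'   the top M* models, apply a normal-approximation false-discovery cutoff
#'   `mu + z_(1-alpha) * sigma` to the frequency distribution, and select the
#'   optimal M* by the precision-recall AUC trajectory.
#' @name feature_mining
NULL

#' Rank subsample models
#'
#' Orders performance records by the primary metric (accuracy descending or
#' MSE ascending), breaking ties by the secondary metric and then by
#' subsample id ascending, and returns the ids of the first `m_star`.
#'
#' @param records List of `performance_record`s.
#' @param metric Primary metric, `"accuracy"` or `"mse"`.
#' @param m_star Number of top models to return (default all).
#' @return Integer vector of subsample ids, best first.
#' @export
rank_models <- function(records, metric = c("accuracy", "mse"),
                        m_star = length(records)) {
  metric <- match.arg(metric)
  if (!length(records)) stop("no records to rank", call. = FALSE)
  if (m_star < 1 || m_star > length(records)) {
    stop("m_star must be between 1 and the number of records", call. = FALSE)
  }
  acc <- vapply(records, `[[`, numeric(1), "accuracy")
  mse <- vapply(records, `[[`, numeric(1), "mse")
  ids <- vapply(records, `[[`, integer(1), "subsample_id")
  ord <- if (metric == "accuracy") {
    order(-acc, mse, ids)
  } else {
    order(mse, -acc, ids)
  }
  ids[ord][seq_len(m_star)]
}

#' Top-ranked performance records
#'
#' Convenience companion to [rank_models()]: returns the records
#' themselves, sorted best-first under the metric and truncated to the top
#' `m_star`.
#'
#' @inheritParams rank_models
#' @return List of `performance_record`s, best first.
#' @export
top_records <- function(records, metric = c("accuracy", "mse"),
                        m_star = length(records)) {
  metric <- match.arg(metric)
  ids <- vapply(records, `[[`, integer(1), "subsample_id")
  top_ids <- rank_models(records, metric, m_star)
  records[match(top_ids, ids)]
}

#' Feature appearance frequencies
#'
#' Counts, for every feature of the full dataset, in how many of the given
#' (top-ranked) records its name appears. Informative features accumulate
#' counts because subsamples containing them produce better-ranked models.
#'
#' @param records List of `performance_record`s (typically the top M*).
#' @param feature_names Character vector of all p feature names.
#' @param m_total Total number of subsamples M the records were drawn from
#'   (defaults to `length(records)`).
#' @return An object of class `frequency_table`: list with `counts` (named
#'   integer vector of length p), `m_star`, `m_total`, `p`.
#' @export
feature_frequencies <- function(records, feature_names,
                                m_total = length(records)) {
  counts <- integer(length(feature_names))
  names(counts) <- feature_names
  tab <- table(unlist(lapply(records, `[[`, "feature_names")))
  unknown <- setdiff(names(tab), feature_names)
  if (length(unknown)) {
    stop("records mention features absent from feature_names: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, m_star = length(records),
                 m_total = as.integer(m_total),
                 p = length(feature_names)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> p=%d features over top %d of %d models; count range [%d, %d]\n",
              x$p, x$m_star, x$m_total, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Normal-approximation false-discovery cutoff
#'
#' For M* = M each feature's count is Binomial(M, k/p), so the frequency
#' distribution over the p features is approximately normal; its sample
#' mean and standard deviation give the cutoff
#' `mu + qnorm(1 - alpha) * sigma`. Decreasing `alpha` makes the rule more
#' conservative (at `alpha = 1e-6` the multiplier is 4.75; at 0.5 it is 0).
#'
#' `alpha` is read on the decimal scale by default; set
#' `scale = "natural_e"` to interpret it as a power of e.
#'
#' @param table A [feature_frequencies()] table supplying the frequency
#'   distribution (use the table at M* or at M, per `stats_source` in
#'   [run_slicer()]).
#' @param alpha One-sided tail level in (0, 1).
#' @param scale `"decimal"` (default) or `"natural_e"` (then the quantile is
#'   taken at `exp(log(alpha))`, i.e. alpha given as e^x).
#' @return An object of class `frequency_stats`: list with `mu`, `sigma`,
#'   `alpha`, `z`, `cutoff`.
#' @export
#' @examples
#' tab <- structure(list(counts = c(a = 10, b = 12, c = 9, d = 30),
#'                       m_star = 50, m_total = 50, p = 4),
#'                  class = "frequency_table")
#' fdr_cutoff(tab, 1e-6)$z  # 4.75
fdr_cutoff <- function(table, alpha, scale = c("decimal", "natural_e")) {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "frequency_table"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  mu <- mean(table$counts)
  sigma <- stats::sd(table$counts)
  if (is.na(sigma)) sigma <- 0
  z <- stats::qnorm(1 - alpha)
  if (scale == "natural_e") z <- stats::qnorm(1 - exp(log(alpha)))
  if (sigma == 0) {
    warning("degenerate frequency distribution (sigma = 0); cutoff = mu")
    cutoff <- mu
  } else {
    cutoff <- mu + z * sigma
  }
  structure(list(mu = mu, sigma = sigma, alpha = alpha, z = z,
                 cutoff = cutoff),
            class = "frequency_stats")
}

#' @export
print.frequency_stats <- function(x, ...) {
  cat(sprintf("<frequency_stats> mu=%.3f sigma=%.3f alpha=%g -> cutoff = mu + %.2f sigma = %.3f\n",
              x$mu, x$sigma, x$alpha, x$z, x$cutoff))
  invisible(x)
}

#' Confusion counts at a frequency cutoff
#'
#' Declares every feature whose count strictly exceeds the cutoff a
#' Positive and scores the declaration against the known true feature set.
#' The empirical FDR is `fp / (tp + fp)`, defined as 0 when there are no
#' positives.
#'
#' @param table A [feature_frequencies()] table.
#' @param stats A [fdr_cutoff()] result (or any list with `$cutoff`).
#' @param truth Character vector of true feature names (or integer indices
#'   into the table).
#' @return An object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `fdr`, `positives` (character vector of flagged features).
#' @export
confusion_at_cutoff <- function(table, stats, truth) {
  stopifnot(inherits(table, "frequency_table"))
  nms <- names(table$counts)
  if (is.numeric(truth)) truth <- nms[truth]
  if (!all(truth %in% nms)) {
    stop("truth contains unknown features", call. = FALSE)
  }
  positive <- table$counts > stats$cutoff  # strict: boundary is negative
  is_true <- nms %in% truth
  tp <- sum(positive & is_true)
  fp <- sum(positive & !is_true)
  fn <- sum(!positive & is_true)
  tn <- sum(!positive & !is_true)
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, fdr = fdr,
                 positives = nms[positive]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d (FDR=%.3f)\n",
              x$tp, x$fp, x$tn, x$fn, x$fdr))
  invisible(x)
}

#' Precision and recall of a confusion table
#'
#' Standard definitions: precision = TP/(TP+FP), recall = TP/(TP+FN).
#' An undefined ratio (zero denominator) is taken as 1 by convention: no
#' mistakes of that kind were possible.
#'
#' @param c A `confusion_counts` object (or list with `tp`, `fp`, `fn`).
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(c) {
  precision <- if (c$tp + c$fp == 0) 1 else c$tp / (c$tp + c$fp)
  recall <- if (c$tp + c$fn == 0) 1 else c$tp / (c$tp + c$fn)
  c(precision = precision, recall = recall)
}

#' Area under a precision-recall curve
#'
#' Sorts the points by recall, anchors the curve at recall 0 with the
#' precision of the lowest-recall point, and integrates by the trapezoidal
#' rule up to the largest observed recall (no extrapolation to recall 1).
#'
#' @param points Two-column matrix or data frame with columns
#'   `recall`, `precision` (one row per alpha).
#' @return PR AUC in \[0, 1\].
#' @export
#' @examples
#' pr_auc(data.frame(recall = c(0, 1), precision = c(1, 1)))  # 1
#' pr_auc(data.frame(recall = c(0, 1), precision = c(1, 0)))  # 0.5
pr_auc <- function(points) {
  points <- as.data.frame(points)
  stopifnot(nrow(points) >= 1,
            all(c("recall", "precision") %in% names(points)))
  pts <- points[order(points$recall, points$precision), , drop = FALSE]
  r <- pts$recall; p <- pts$precision
  if (r[1] > 0) {  # anchor at recall zero with the lowest-recall precision
    r <- c(0, r); p <- c(p[1], p)
  }
  if (length(r) == 1) return(0)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Slice the training-stage results over (M*, alpha) grids
#'
#' For every M* in the grid: take the top-M* models, tabulate feature
#' frequencies, and for every alpha compute the cutoff and the resulting
#' confusion counts (truth known) or positive feature sets (truth unknown).
#' With known truth the per-alpha (recall, precision) points are integrated
#' into one PR AUC per M*, and the optimal M* is the argmax of that
#' trajectory (ties broken toward the smaller, cheaper M*). Too small an M*
#' starves the counts; too large an M* dilutes informative models with
#' uninformative ones — the AUC trajectory exposes the compromise.
#'
#' @param records List of `performance_record`s from the training stage.
#' @param feature_names All p feature names of the mined dataset.
#' @param truth Optional character vector (or indices) of true features;
#'   required for AUC mode.
#' @param m_star_grid M* values to scan (default the benchmark grid
#'   `c(100, 500, 1000, 2000, 3000, 5000)` clipped to M).
#' @param alpha_grid Alpha values per M* (default
#'   `c(0.9, 1e-2, 1e-5, 1e-10, 1e-16, 1e-20)`).
#' @param metric Ranking metric (default `"accuracy"`).
#' @param stats_source Which frequency distribution supplies mu and sigma:
#'   `"at_m_star"` (default) uses the top-M* table itself,
#'   `"at_m_total"` uses the all-M table.
#' @return An object of class `slicer_result`: `m_star_grid`, `alpha_grid`,
#'   `cells` (per-M* list of per-alpha confusion/positive sets),
#'   `auc_per_m_star` (NA without truth), `optimal_m_star`,
#'   `frequency_tables`, `mode` ("auc" or "fdr_proxy").
#' @export
run_slicer <- function(records, feature_names, truth = NULL,
                       m_star_grid = NULL, alpha_grid = NULL,
                       metric = c("accuracy", "mse"),
                       stats_source = c("at_m_star", "at_m_total")) {
  metric <- match.arg(metric)
  stats_source <- match.arg(stats_source)
  M <- length(records)
  if (is.null(m_star_grid)) {
    m_star_grid <- unique(pmin(c(100, 500, 1000, 2000, 3000, 5000), M))
  }
  if (is.null(alpha_grid)) {
    alpha_grid <- c(0.9, 1e-2, 1e-5, 1e-10, 1e-16, 1e-20)
  }
  if (!length(m_star_grid) || !length(alpha_grid)) {
    stop("grids must be nonempty", call. = FALSE)
  }
  if (any(m_star_grid < 1 | m_star_grid > M)) {
    stop("m_star_grid values must lie in [1, M]", call. = FALSE)
  }
  mode <- if (is.null(truth)) "fdr_proxy" else "auc"

  ranked <- top_records(records, metric, M)
  full_table <- feature_frequencies(ranked, feature_names, m_total = M)

  tables <- list(); cells <- list()
  auc <- rep(NA_real_, length(m_star_grid))
  for (i in seq_along(m_star_grid)) {
    m_star <- m_star_grid[i]
    tab <- feature_frequencies(ranked[seq_len(m_star)], feature_names,
                               m_total = M)
    stats_tab <- if (stats_source == "at_m_star") tab else full_table
    per_alpha <- list()
    pr_points <- data.frame(recall = numeric(0), precision = numeric(0))
    for (a in alpha_grid) {
      stats <- suppressWarnings(fdr_cutoff(stats_tab, a))
      if (mode == "auc") {
        conf <- confusion_at_cutoff(tab, stats, truth)
        pr <- precision_recall(conf)
        pr_points <- rbind(pr_points,
                           data.frame(recall = pr[["recall"]],
                                      precision = pr[["precision"]]))
        per_alpha[[as.character(a)]] <- list(alpha = a, stats = stats,
                                             confusion = conf)
      } else {
        positive <- names(tab$counts)[tab$counts > stats$cutoff]
        per_alpha[[as.character(a)]] <- list(alpha = a, stats = stats,
                                             positives = positive,
                                             n_positive = length(positive))
      }
    }
    if (mode == "auc") auc[i] <- pr_auc(pr_points)
    tables[[as.character(m_star)]] <- tab
    cells[[as.character(m_star)]] <- per_alpha
  }
  optimal <- if (mode == "auc") {
    m_star_grid[which(auc == max(auc))[1]]  # grid scanned smallest-first
  } else NA_integer_
  structure(
    list(m_star_grid = m_star_grid, alpha_grid = alpha_grid, cells = cells,
         auc_per_m_star = auc, optimal_m_star = optimal,
         frequency_tables = tables, metric = metric,
         stats_source = stats_source, mode = mode),
    class = "slicer_result")
}

#' @export
print.slicer_result <- function(x, ...) {
  cat(sprintf("<slicer_result> %s mode, %d M* values x %d alpha values\n",
              x$mode, length(x$m_star_grid), length(x$alpha_grid)))
  if (x$mode == "auc") {
    cat("  PR AUC:",
        paste(sprintf("M*=%d: %.3f", x$m_star_grid, x$auc_per_m_star),
              collapse = ", "), "\n")
    cat(sprintf("  optimal M* = %d\n", x$optimal_m_star))
  }
  invisible(x)
}

#' Ranked feature list from a slicer result
#'
#' Features ordered by their frequency among the top-M* models (at the
#' optimal M* unless another is given), ties broken by feature order.
#'
#' @param slicer A `slicer_result`.
#' @param m_star M* whose frequency table to use (default the optimal, or
#'   the largest grid value in FDR-proxy mode).
#' @return Data frame with columns `feature`, `count`, best first.
#' @export
ranked_features <- function(slicer, m_star = NULL) {
  stopifnot(inherits(slicer, "slicer_result"))
  if (is.null(m_star)) {
    m_star <- if (!is.na(slicer$optimal_m_star)) slicer$optimal_m_star
              else max(slicer$m_star_grid)
  }
  tab <- slicer$frequency_tables[[as.character(m_star)]]
  if (is.null(tab)) stop("m_star not in the slicer grid", call. = FALSE)
  ord <- order(-tab$counts)
  data.frame(feature = names(tab$counts)[ord],
             count = as.integer(tab$counts[ord]), row.names = NULL)
}
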