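#' @title Overfitting test stage
#' @description After the training stage ranks the features, nested models
#'   on the top-k features (k = 1..K) expose how performance grows with
#'   model size and where it plateaus: the accuracy/MSE-versus-k curve
#'   locates the number of features worth keeping and flags overfitting if
#'   performance degrades as k grows.
#' @name overfitting
NULL

#' Build the nested-model performance curve
#'
#' Draws one fixed training/validation split (disjoint, without
#' replacement) and, for each k in 1..K, fits the ensemble on the top-k
#' ranked features and records validation accuracy and MSE. The split is
#' shared across all k, so differences along the curve reflect the feature
#' sets only.
#'
#' @param data A [cbda_dataset()].
#' @param ranked_features Character vector of feature names, best first
#'   (e.g. from [ranked_features()]).
#' @param K Largest model size (default `min(50, length(ranked_features))`).
#' @param learners Learner registry (default [lean_registry()]).
#' @param train_size Training cases (default `min(3000, 60% of cases)`).
#' @param val_size Validation cases (default `min(1000, remaining cases)`).
#' @param v_folds CV folds inside each ensemble fit (default 3).
#' @param seed Seed for the split and the fits.
#' @return An object of class `overfitting_curve`: `k_values`,
#'   `accuracy_at_k`, `mse_at_k`, `optimal_k_accuracy`, `optimal_k_mse`,
#'   `split_spec`.
#' @export
build_nested_curve <- function(data, ranked_features,
                               K = min(50, length(ranked_features)),
                               learners = lean_registry(),
                               train_size = NULL, val_size = NULL,
                               v_folds = 3, seed = 1) {
  stopifnot(inherits(data, "cbda_dataset"))
  if (K > length(ranked_features)) {
    stop("K exceeds the number of ranked features", call. = FALSE)
  }
  if (!all(ranked_features[seq_len(K)] %in% data$feature_names)) {
    stop("ranked_features contains unknown feature names", call. = FALSE)
  }
  n <- nrow(data$X)
  if (is.null(train_size)) train_size <- min(3000, floor(0.6 * n))
  if (is.null(val_size)) val_size <- min(1000, n - train_size)
  if (train_size < 2 || val_size < 1 || train_size + val_size > n) {
    stop("infeasible split sizes", call. = FALSE)
  }

  draw_split <- function(s) {
    set.seed(s)
    tr <- sample.int(n, train_size)
    va <- sample(setdiff(seq_len(n), tr), val_size)
    list(train = tr, validation = va)
  }
  split <- draw_split(seed)
  if (data$outcome_type == "binary" &&
      length(unique(data$y[split$train])) < 2) {
    split <- draw_split(seed + 1)  # resample a degenerate split once
    if (length(unique(data$y[split$train])) < 2) {
      stop("training split has a single outcome class", call. = FALSE)
    }
  }

  acc <- mse <- numeric(K)
  for (k in seq_len(K)) {
    feats <- ranked_features[seq_len(k)]
    Xtr <- data$X[split$train, feats, drop = FALSE]
    Xva <- data$X[split$validation, feats, drop = FALSE]
    if (anyNA(Xtr) || anyNA(Xva)) {
      imp <- impute_subsample(Xtr, Xva, full_data = data$X[, feats, drop = FALSE])
      Xtr <- imp$train; Xva <- imp$validation
    }
    model <- fit_superlearner(Xtr, data$y[split$train], learners,
                              outcome_type = data$outcome_type,
                              v_folds = v_folds, seed = seed + k)
    rec <- evaluate_model(model, Xva, data$y[split$validation],
                          subsample_id = k)
    acc[k] <- rec$accuracy
    mse[k] <- rec$mse
  }
  curve <- structure(
    list(k_values = seq_len(K), accuracy_at_k = acc, mse_at_k = mse,
         split_spec = list(train_size = train_size, val_size = val_size,
                           seed = seed)),
    class = "overfitting_curve")
  curve$optimal_k_accuracy <- select_optimal_k(curve, metric = "accuracy")
  curve$optimal_k_mse <- select_optimal_k(curve, metric = "mse")
  curve
}

#' Select the optimal model size from a nested curve
#'
#' Operationalizes "maximal performance without overfitting" as the
#' smallest k whose accuracy is within `tolerance` of the curve's maximum
#' (or, for MSE, within `tolerance` of the minimum).
#'
#' @param curve An `overfitting_curve`.
#' @param tolerance Performance slack in accuracy (or MSE) units
#'   (default 0.005).
#' @param metric `"accuracy"` or `"mse"`.
#' @return The selected k.
#' @export
select_optimal_k <- function(curve, tolerance = 0.005,
                             metric = c("accuracy", "mse")) {
  metric <- match.arg(metric)
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  if (metric == "accuracy") {
    ok <- curve$accuracy_at_k >= max(curve$accuracy_at_k) - tolerance
  } else {
    ok <- curve$mse_at_k <= min(curve$mse_at_k) + tolerance
  }
  curve$k_values[which(ok)[1]]
}

#' @export
print.overfitting_curve <- function(x, ...) {
  cat(sprintf("<overfitting_curve> k = 1..%d (train %d / validation %d)\n",
              max(x$k_values), x$split_spec$train_size,
              x$split_spec$val_size))
  cat(sprintf("  max accuracy %.3f at k=%d; optimal k (accuracy) = %d, (mse) = %d\n",
              max(x$accuracy_at_k), which.max(x$accuracy_at_k),
              x$optimal_k_accuracy, x$optimal_k_mse))
  invisible(x)
}
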