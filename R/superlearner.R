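#' Fit a cross-validated stacking ensemble
#'
#' The ensemble predictor at the heart of the protocol. For each base
#' learner an out-of-fold prediction vector is produced by V-fold
#' cross-validation; the meta-learning step then solves for non-negative
#' weights minimizing the chosen loss of the convex combination against the
#' observed outcome, renormalizes them onto the simplex, and refits every
#' learner on the full training data.
#'
#' Learner failures are tolerated: a learner whose fit or prediction errors
#' out gets weight 0 and a warning. A single-class binary outcome is a
#' degenerate subsample and raises an error (callers skip and log it).
#'
#' @param X Numeric training matrix (no missing values).
#' @param y Outcome vector.
#' @param learners A registry: list of [learner()] specs.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param v_folds Number of cross-validation folds (default 10; use 3 for
#'   fast scaled-down runs).
#' @param loss `"squared_error"` (non-negative least squares meta-step, the
#'   canonical default) or `"log_loss"` (simplex-constrained likelihood
#'   optimization, binary only).
#' @param seed Integer seed controlling fold assignment and any learner
#'   internal randomness.
#' @return An object of class `cbda_ensemble` with elements `learners`,
#'   `fits`, `weights` (simplex), `cv_risk` (per-learner CV loss),
#'   `cv_risk_ensemble`, `v_folds`, `loss`, `feature_names`, `outcome_type`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("f", 1:5)))
#' y <- rbinom(200, 1, plogis(2 * X[, 1]))
#' fit <- fit_superlearner(X, y, lean_registry(), v_folds = 3)
#' round(fit$weights, 3)
fit_superlearner <- function(X, y, learners = default_registry(),
                             outcome_type = c("binary", "continuous"),
                             v_folds = 10,
                             loss = c("squared_error", "log_loss"),
                             seed = 1) {
  outcome_type <- match.arg(outcome_type)
  loss <- match.arg(loss)
  nms <- check_registry(learners)
  X <- as.matrix(X)
  n <- nrow(X)
  L <- length(learners)
  if (anyNA(X)) stop("training matrix contains missing values; impute first",
                     call. = FALSE)
  if (outcome_type == "binary" && length(unique(y)) < 2) {
    stop("degenerate subsample: single-class training outcome",
         call. = FALSE)
  }
  if (n < v_folds) stop("fewer cases than folds", call. = FALSE)

  set.seed(seed)
  fold <- sample(rep(seq_len(v_folds), length.out = n))

  # out-of-fold level-one predictions, one column per learner
  Z <- matrix(NA_real_, n, L, dimnames = list(NULL, nms))
  failed <- logical(L)
  for (l in seq_len(L)) {
    ok <- TRUE
    for (v in seq_len(v_folds)) {
      tr <- fold != v
      if (outcome_type == "binary" && length(unique(y[tr])) < 2) {
        ok <- FALSE; break
      }
      pred <- tryCatch({
        f <- fit_learner(learners[[l]], X[tr, , drop = FALSE], y[tr],
                         outcome_type, seed = seed + v)
        predict_learner(f, X[!tr, , drop = FALSE])
      }, error = function(e) NULL)
      if (is.null(pred) || anyNA(pred)) { ok <- FALSE; break }
      Z[!tr, l] <- pred
    }
    failed[l] <- !ok
  }
  if (all(failed)) stop("every learner failed during cross-validation",
                        call. = FALSE)
  if (any(failed)) {
    warning(sprintf("learner(s) %s failed; assigned weight 0",
                    paste(nms[failed], collapse = ", ")))
  }

  risk_fun <- if (loss == "log_loss") {
    function(p) { p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p)) }
  } else {
    function(p) mean((p - y)^2)
  }
  cv_risk <- rep(NA_real_, L); names(cv_risk) <- nms
  cv_risk[!failed] <- apply(Z[, !failed, drop = FALSE], 2, risk_fun)

  w <- solve_meta_weights(Z[, !failed, drop = FALSE], y, loss)
  weights <- numeric(L); names(weights) <- nms
  weights[!failed] <- w

  cv_risk_ensemble <- risk_fun(drop(Z[, !failed, drop = FALSE] %*% w))

  # refit every surviving learner on the full training subsample
  fits <- vector("list", L); names(fits) <- nms
  for (l in which(!failed)) {
    fits[[l]] <- tryCatch(
      fit_learner(learners[[l]], X, y, outcome_type, seed = seed),
      error = function(e) NULL)
    if (is.null(fits[[l]])) {
      failed[l] <- TRUE
      weights[l] <- 0
    }
  }
  if (sum(weights) <= 0) {
    # all weight fell on learners that later failed: spread over survivors
    weights[!failed] <- 1 / sum(!failed)
  }
  weights <- weights / sum(weights)

  structure(
    list(learners = learners, fits = fits, weights = weights,
         cv_risk = cv_risk, cv_risk_ensemble = cv_risk_ensemble,
         v_folds = v_folds, loss = loss, feature_names = colnames(X),
         outcome_type = outcome_type, seed = seed),
    class = "cbda_ensemble")
}

# Non-negative meta-weights on the simplex. Squared error: NNLS (Lawson-
# Hanson via pracma) then renormalize. Log loss: likelihood maximization
# over softmax-parameterized simplex weights, initialized at the NNLS
# solution.
solve_meta_weights <- function(Z, y, loss = "squared_error") {
  L <- ncol(Z)
  if (L == 1) return(1)
  w <- tryCatch(pracma::lsqnonneg(Z, y)$x, error = function(e) rep(1, L))
  if (sum(w) <= 0) w <- rep(1, L)
  w <- w / sum(w)
  if (loss == "log_loss") {
    obj <- function(theta) {
      v <- exp(theta - max(theta)); v <- v / sum(v)
      p <- pmin(pmax(drop(Z %*% v), 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    theta0 <- log(pmax(w, 1e-6))
    opt <- stats::optim(theta0, obj, method = "BFGS",
                        control = list(maxit = 200))
    v <- exp(opt$par - max(opt$par))
    w <- v / sum(v)
  }
  w
}

#' @export
print.cbda_ensemble <- function(x, ...) {
  cat(sprintf("<cbda_ensemble> %d learners, %d-fold CV, %s loss\n",
              length(x$learners), x$v_folds, x$loss))
  w <- sort(x$weights[x$weights > 0], decreasing = TRUE)
  cat("  weights:", paste(sprintf("%s=%.3f", names(w), w), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict from a fitted ensemble
#'
#' @param object A `cbda_ensemble` from [fit_superlearner()].
#' @param newdata Numeric matrix whose columns match the fitted feature set
#'   (same names, same order).
#' @param ... Unused.
#' @return Ensemble predictions `sum_l w_l pred_l`; probabilities in
#'   \[0, 1\] for binary outcomes.
#' @export
predict.cbda_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$feature_names)) {
    stop("newdata columns do not match the fitted feature set",
         call. = FALSE)
  }
  active <- which(object$weights > 0)
  pred <- numeric(nrow(newdata))
  for (l in active) {
    pred <- pred + object$weights[l] *
      predict_learner(object$fits[[l]], newdata)
  }
  if (object$outcome_type == "binary") clamp01(pred) else pred
}

#' Score an ensemble on a validation set
#'
#' Computes the mean squared error of the predictions and, for binary
#' outcomes, the accuracy under the binarization rule
#' `prediction >= 0.5 -> class 1`. Both metrics and the ensemble's weight
#' vector are bundled into a performance record, the unit of the
#' training-stage results file.
#'
#' @param model A `cbda_ensemble`.
#' @param X Validation matrix on the model's feature set (no missing
#'   values).
#' @param y Validation outcomes.
#' @param subsample_id Integer id of the subsample the model came from.
#' @param metric_used Primary ranking metric recorded with the result.
#' @return An object of class `performance_record`: list with
#'   `subsample_id`, `feature_names`, `accuracy` (NA for continuous
#'   outcomes), `mse`, `weights`, `metric_used`.
#' @export
evaluate_model <- function(model, X, y, subsample_id = NA_integer_,
                           metric_used = c("accuracy", "mse")) {
  metric_used <- match.arg(metric_used)
  if (!length(y)) stop("empty validation set", call. = FALSE)
  pred <- stats::predict(model, X)
  mse <- mean((pred - y)^2)
  accuracy <- if (model$outcome_type == "binary") {
    mean(as.numeric(pred >= 0.5) == y)
  } else NA_real_
  structure(
    list(subsample_id = as.integer(subsample_id),
         feature_names = model$feature_names,
         accuracy = accuracy, mse = mse, weights = model$weights,
         metric_used = metric_used),
    class = "performance_record")
}

#' @export
print.performance_record <- function(x, ...) {
  cat(sprintf("<performance_record> subsample %d: accuracy=%.3f mse=%.4f (%d features)\n",
              x$subsample_id, x$accuracy, x$mse, length(x$feature_names)))
  invisible(x)
}

#' Collect performance records into a data frame
#'
#' @param records List of `performance_record`s.
#' @return A data frame with one row per record (`subsample_id`,
#'   `accuracy`, `mse`, `metric_used`).
#' @export
records_summary <- function(records) {
  data.frame(
    subsample_id = vapply(records, `[[`, integer(1), "subsample_id"),
    accuracy = vapply(records, `[[`, numeric(1), "accuracy"),
    mse = vapply(records, `[[`, numeric(1), "mse"),
    metric_used = vapply(records, `[[`, character(1), "metric_used"))
}

# M x L matrix of ensemble weights across records (registries must agree)
weights_matrix <- function(records) {
  nms <- names(records[[1]]$weights)
  for (r in records) {
    if (!identical(names(r$weights), nms)) {
      stop("records were produced with different learner registries",
           call. = FALSE)
    }
  }
  do.call(rbind, lapply(records, `[[`, "weights"))
}
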