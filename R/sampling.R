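#' Subsampling plan
#'
#' Fixes the compressive subsampling geometry: every training subsample has
#' `n_cases` cases (drawn with replacement) by `n_features * vif` distinct
#' features, paired with a disjoint validation set of
#' `validation_factor * n_cases` cases on the same features. The defaults
#' (300 cases x 30 features, 600-case validation, M = 5000 subsamples) make
#' the per-subsample work independent of the size of the full dataset.
#'
#' @param n_cases Training cases per subsample (default 300).
#' @param n_features Features per subsample before VIF scaling (default 30).
#' @param validation_factor Validation size as a multiple of `n_cases`
#'   (default 2).
#' @param M Total number of subsamples (default 5000).
#' @param vif Variance inflation factor, a multiplier >= 1 enlarging the
#'   feature draw to cope with blocks of collinear features (default 1).
#' @param master_seed Integer seed from which every per-subsample seed is
#'   derived (default 1).
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(n_cases = 300, n_features = 30,
                          validation_factor = 2, M = 5000, vif = 1,
                          master_seed = 1) {
  if (n_cases < 2) stop("n_cases must be at least 2", call. = FALSE)
  if (n_features < 1) stop("n_features must be positive", call. = FALSE)
  if (validation_factor < 1) {
    stop("validation_factor must be at least 1", call. = FALSE)
  }
  if (M < 1) stop("M must be at least 1", call. = FALSE)
  if (vif < 1) stop("vif must be at least 1", call. = FALSE)
  structure(
    list(n_cases = as.integer(n_cases), n_features = as.integer(n_features),
         validation_factor = as.integer(validation_factor), M = as.integer(M),
         vif = vif, master_seed = as.integer(master_seed)),
    class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf(
    "<sampling_plan> M=%d subsamples of %d cases x %d features (vif=%g), validation x%d, master_seed=%d\n",
    x$M, x$n_cases, effective_n_features(x, Inf), x$vif,
    x$validation_factor, x$master_seed))
  invisible(x)
}

effective_n_features <- function(plan, p) {
  min(as.integer(round(plan$n_features * plan$vif)), p)
}

#' Case and feature sampling rates
#'
#' Recasts the fixed subsample size into the case sampling rate
#' `CSR = 100 * n_cases / n` and feature sampling rate
#' `FSR = 100 * n_features * vif / p`, the percentages of the full dataset
#' touched by one subsample.
#'
#' @param n Number of cases in the full dataset.
#' @param p Number of features in the full dataset.
#' @param plan A [sampling_plan()].
#' @return A list with percentage components `csr` and `fsr`.
#' @export
#' @examples
#' compute_sampling_rates(10000, 1000, sampling_plan())  # 3% and 3%
compute_sampling_rates <- function(n, p, plan = sampling_plan()) {
  csr <- 100 * plan$n_cases / n
  fsr <- 100 * (plan$n_features * plan$vif) / p
  if (csr > 100 || fsr > 100) {
    stop("subsample larger than the dataset: sampling rate exceeds 100%",
         call. = FALSE)
  }
  list(csr = csr, fsr = fsr)
}

#' Apply the variance inflation factor to the feature draw
#'
#' Scales the per-subsample feature count by `vif`, capping at the total
#' feature count `p`. Larger draws help when informative features hide in
#' blocks of collinear ones, at a computational cost.
#'
#' @param n_features Base feature count per subsample.
#' @param vif Multiplier >= 1.
#' @param p Total feature count available (cap; default unbounded).
#' @return The effective per-subsample feature count.
#' @export
#' @examples
#' apply_vif(30, 6)  # 180
apply_vif <- function(n_features, vif, p = Inf) {
  if (vif < 1) stop("vif must be at least 1", call. = FALSE)
  min(as.integer(round(n_features * vif)), p)
}

# Deterministic per-subsample seed stream: an affine hash of
# (master_seed, key) over a prime modulus below 2^31, so parallel workers
# need no shared RNG state and any subsample can be redrawn in isolation.
subsample_seed <- function(master_seed, key) {
  m <- 2147483629  # prime < 2^31
  as.integer((((master_seed %% m) * 1000003 + key) %% m) + 1)
}

#' Draw one training subsample
#'
#' Cases are drawn uniformly *with* replacement (size `n_cases`); features
#' uniformly *without* replacement (size `n_features * vif`, capped at `p`).
#' The draw is a pure function of `(plan$master_seed, id)`.
#'
#' @param data A [cbda_dataset()].
#' @param plan A [sampling_plan()].
#' @param id Subsample id in `1..plan$M`.
#' @return An object of class `cbda_subsample` with `id`, `case_index`
#'   (multiset), `feature_index` (distinct), `seed`, and `role = "training"`.
#' @export
draw_training_subsample <- function(data, plan, id) {
  stopifnot(inherits(data, "cbda_dataset"), inherits(plan, "sampling_plan"))
  n <- nrow(data$X); p <- ncol(data$X)
  k <- as.integer(round(plan$n_features * plan$vif))
  if (k > p) {
    stop("n_features * vif exceeds the number of features", call. = FALSE)
  }
  seed <- subsample_seed(plan$master_seed, 2 * id)
  set.seed(seed)
  case_index <- sample.int(n, plan$n_cases, replace = TRUE)
  feature_index <- sort(sample.int(p, k, replace = FALSE))
  structure(list(id = as.integer(id), case_index = case_index,
                 feature_index = feature_index, seed = seed,
                 role = "training"),
            class = "cbda_subsample")
}

#' Draw the validation set paired with a training subsample
#'
#' Samples `validation_factor * n_cases` cases with replacement from the
#' cases *not* present in the training subsample, on the identical feature
#' set. Training and validation therefore never share a case.
#'
#' @param data A [cbda_dataset()].
#' @param train A training `cbda_subsample`.
#' @param plan The [sampling_plan()] used to draw `train`.
#' @return A `cbda_subsample` with `role = "validation"`.
#' @export
draw_validation_set <- function(data, train, plan) {
  stopifnot(inherits(train, "cbda_subsample"))
  n <- nrow(data$X)
  eligible <- setdiff(seq_len(n), unique(train$case_index))
  if (!length(eligible)) {
    stop("no cases left outside the training subsample", call. = FALSE)
  }
  seed <- subsample_seed(plan$master_seed, 2 * train$id + 1)
  set.seed(seed)
  case_index <- eligible[sample.int(length(eligible),
                                    plan$validation_factor * plan$n_cases,
                                    replace = TRUE)]
  structure(list(id = train$id, case_index = case_index,
                 feature_index = train$feature_index, seed = seed,
                 role = "validation"),
            class = "cbda_subsample")
}

#' @export
print.cbda_subsample <- function(x, ...) {
  cat(sprintf("<cbda_subsample> id=%d (%s): %d cases x %d features\n",
              x$id, x$role, length(x$case_index), length(x$feature_index)))
  invisible(x)
}

#' Materialize a subsample view of a dataset
#'
#' @param data A [cbda_dataset()].
#' @param subsample A `cbda_subsample`.
#' @return A list with the subsampled `X` (rows in draw order), `y`, and
#'   `feature_names`.
#' @export
subsample_view <- function(data, subsample) {
  list(X = data$X[subsample$case_index, subsample$feature_index,
                  drop = FALSE],
       y = data$y[subsample$case_index],
       feature_names = data$feature_names[subsample$feature_index])
}
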