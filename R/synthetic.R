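#' Configuration for the synthetic benchmark generators
#'
#' Describes one of the two synthetic benchmarks used to exercise the
#' protocol: the Null dataset (a Bernoulli(0.5) outcome completely
#' independent of i.i.d. standard-normal features) and the Binomial dataset,
#' in which exactly `k_true` features drive the outcome through a linear
#' score passed through an inverse logit,
#' \deqn{Z = \sum_j b_j X_{(j)} + e, \quad e \sim N(0, \sigma^2), \quad
#'       \Pr(Y=1 \mid Z) = e^Z / (1 + e^Z).}
#'
#' The generative coefficients default to 2.0 each with unit noise, which
#' places the generator's Bayes accuracy near the ~90% plateau characteristic
#' of this benchmark family (check it with [bayes_accuracy_oracle()]).
#'
#' @param n Number of cases.
#' @param p Number of features.
#' @param outcome_kind `"null"` or `"binomial"`.
#' @param k_true Number of generative ("true") features (binomial only).
#' @param true_indices Distinct feature indices (1-based) carrying signal;
#'   defaults to the first `k_true` columns.
#' @param coefficients Effect sizes `b_j`, one per true feature.
#' @param noise_sd Standard deviation of the additive Gaussian score noise.
#' @param seed Integer RNG seed; the dataset is a pure function of the config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n, p, outcome_kind = c("binomial", "null"),
                             k_true = 10, true_indices = seq_len(k_true),
                             coefficients = rep(2, k_true), noise_sd = 1,
                             seed = 1) {
  outcome_kind <- match.arg(outcome_kind)
  n <- as.integer(n); p <- as.integer(p); k_true <- as.integer(k_true)
  if (n < 1 || p < 1) stop("n and p must be positive", call. = FALSE)
  if (outcome_kind == "binomial") {
    if (k_true > p) stop("k_true must not exceed p", call. = FALSE)
    true_indices <- as.integer(true_indices)
    if (length(true_indices) != k_true || anyDuplicated(true_indices) ||
        any(true_indices < 1L) || any(true_indices > p)) {
      stop("true_indices must be k_true distinct indices in [1, p]",
           call. = FALSE)
    }
    if (length(coefficients) != k_true) {
      stop("coefficients must have length k_true", call. = FALSE)
    }
  } else {
    k_true <- 0L
    true_indices <- integer(0)
    coefficients <- numeric(0)
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be positive", call. = FALSE)
  }
  structure(
    list(n = n, p = p, outcome_kind = outcome_kind, k_true = k_true,
         true_indices = true_indices, coefficients = as.numeric(coefficients),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %s, n=%d p=%d", x$outcome_kind, x$n, x$p))
  if (x$outcome_kind == "binomial") {
    cat(sprintf(", k_true=%d, noise_sd=%g", x$k_true, x$noise_sd))
  }
  cat(sprintf(", seed=%d\n", x$seed))
  invisible(x)
}

gen_feature_matrix <- function(n, p) {
  X <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  colnames(X) <- sprintf("f%04d", seq_len(p))
  X
}

#' Generate a Null benchmark dataset
#'
#' Each feature column is i.i.d. N(0, 1) and the binary outcome is i.i.d.
#' Bernoulli(0.5), independent of every feature. Useful as a negative
#' control: any feature the mining stage flags on Null data is a false
#' discovery.
#'
#' @param config A [generator_config()] with `outcome_kind = "null"`.
#' @return A [cbda_dataset()] with binary outcome and the config attached as
#'   provenance.
#' @export
generate_null <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$outcome_kind != "null") {
    stop("config$outcome_kind must be 'null'", call. = FALSE)
  }
  set.seed(config$seed)
  X <- gen_feature_matrix(config$n, config$p)
  y <- stats::rbinom(config$n, 1L, 0.5)
  cbda_dataset(X, y, outcome_type = "binary", provenance = config)
}

#' Generate a Binomial benchmark dataset
#'
#' Draws i.i.d. N(0,1) features, forms the linear score
#' `Z = sum(b_j * X_true_j) + e` with `e ~ N(0, noise_sd^2)`, converts it to
#' a probability by the inverse logit, and draws `y ~ Bernoulli(Pr)`. The
#' generation order (features, then noise, then outcome) is fixed so a seed
#' identifies the dataset exactly.
#'
#' @param config A [generator_config()] with `outcome_kind = "binomial"`.
#' @return A [cbda_dataset()] with binary outcome; `provenance` records the
#'   true feature indices.
#' @export
generate_binomial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$outcome_kind != "binomial") {
    stop("config$outcome_kind must be 'binomial'", call. = FALSE)
  }
  set.seed(config$seed)
  X <- gen_feature_matrix(config$n, config$p)
  e <- stats::rnorm(config$n, 0, config$noise_sd)
  Z <- drop(X[, config$true_indices, drop = FALSE] %*% config$coefficients) + e
  pr <- stats::plogis(Z)
  y <- stats::rbinom(config$n, 1L, pr)
  cbda_dataset(X, y, outcome_type = "binary", provenance = config)
}

#' Monte-Carlo Bayes-accuracy oracle for the Binomial generator
#'
#' Estimates the accuracy ceiling of any classifier on data from the
#' Binomial generator. A classifier observes the features but not the score
#' noise `e`, so the best attainable rule is the sign of the observable
#' signal `S = sum(b_j X_true_j)` (by symmetry of `e`, the conditional
#' success probability given the features crosses 1/2 exactly where `S`
#' does). The oracle simulates the generator and returns the expected
#' frequency with which that rule matches the Bernoulli outcome,
#' `E[ Pr(Y = 1 | Z) 1(S > 0) + Pr(Y = 0 | Z) 1(S <= 0) ]` with
#' `Pr(Y = 1 | Z) = plogis(S + e)`. With all-zero coefficients this is
#' exactly 0.5; it serves as the quantitative reference for the
#' overfitting-stage accuracy plateau.
#'
#' @param config A [generator_config()] with `outcome_kind = "binomial"`.
#' @param n_mc Number of Monte-Carlo draws (at least 1e5).
#' @param seed RNG seed for the Monte-Carlo draw (independent of the
#'   dataset seed).
#' @return Estimated maximal achievable accuracy, a number in \[0.5, 1\].
#' @export
#' @examples
#' cfg <- generator_config(n = 100, p = 20, k_true = 2,
#'                         coefficients = c(2, 2))
#' bayes_accuracy_oracle(cfg, n_mc = 1e5)
bayes_accuracy_oracle <- function(config, n_mc = 1e6, seed = 20260101) {
  stopifnot(inherits(config, "generator_config"))
  if (config$outcome_kind != "binomial") {
    stop("oracle is defined for the binomial generator", call. = FALSE)
  }
  n_mc <- as.integer(n_mc)
  if (n_mc < 1e5) stop("n_mc must be at least 1e5", call. = FALSE)
  set.seed(seed)
  # drawing each component explicitly keeps the oracle a literal
  # simulation of the generator
  Xs <- matrix(stats::rnorm(n_mc * config$k_true), nrow = n_mc)
  S <- drop(Xs %*% config$coefficients)
  pr <- stats::plogis(S + stats::rnorm(n_mc, 0, config$noise_sd))
  mean(ifelse(S > 0, pr, 1 - pr))
}
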