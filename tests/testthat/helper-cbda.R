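# Shared fixtures and a cache for expensive simulation runs so several
# test files can reuse the same training-stage records.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# A fabricated performance record (for mining/diagnostics unit tests).
make_record <- function(id, accuracy, features, mse = 0.25,
                        weights = c(a = 0.5, b = 0.5)) {
  structure(
    list(subsample_id = as.integer(id), feature_names = features,
         accuracy = accuracy, mse = mse, weights = weights,
         metric_used = "accuracy"),
    class = "performance_record")
}

# Small binomial dataset with a strong 2-feature signal.
toy_binomial <- function(n = 400, p = 12, seed = 42) {
  generate_binomial(generator_config(n, p, k_true = 2,
                                     coefficients = c(3, 3), seed = seed))
}

# Scaled-down benchmark run: Binomial 10000 x 1000, 10 true features with
# coefficients 2, M = 500 subsamples of 300 x 30 with 600-case validation,
# lean registry, 3-fold CV, accuracy ranking.
bench_plan <- function(seed) sampling_plan(M = 500, master_seed = seed)

bench_binomial_records <- function(seed) {
  cached(paste0("bench_binomial_", seed), {
    d <- generate_binomial(generator_config(10000, 1000, seed = seed))
    run_training_stage(d, bench_plan(seed), lean_registry(), v_folds = 3)
  })
}

bench_true_features <- sprintf("f%04d", 1:10)
bench_feature_names <- sprintf("f%04d", 1:1000)

# Bayes-accuracy ceiling of the benchmark generator (10 coefficients of
# 2.0, unit score noise), frozen from a 2e6-draw Monte-Carlo run.
BENCH_ORACLE_ACCURACY <- 0.9020
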