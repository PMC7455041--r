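small_setup <- function(seed = 1) {
  list(data = toy_binomial(n = 500, p = 15, seed = seed),
       plan = sampling_plan(n_cases = 60, n_features = 5, M = 10,
                            master_seed = seed),
       reg = list(learner("glm", "glm"), learner("mean", "mean")))
}

test_that("the training stage produces one record per subsample id", {
  s <- small_setup()
  recs <- run_training_stage(s$data, s$plan, s$reg, v_folds = 3)
  expect_length(recs, 10)
  expect_equal(vapply(recs, `[[`, integer(1), "subsample_id"), 1:10)
  expect_true(all(vapply(recs, function(r) length(r$feature_names),
                         integer(1)) == 5))
  df <- records_summary(recs)
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 1))
})

test_that("an interrupted run resumes from its checkpoint file", {
  s <- small_setup(seed = 3)
  full_file <- withr::local_tempfile(fileext = ".jsonl")
  part_file <- withr::local_tempfile(fileext = ".jsonl")
  full <- run_training_stage(s$data, s$plan, s$reg, v_folds = 3,
                             results_file = full_file)
  # simulate an interrupt after 4 records, then resume
  writeLines(head(readLines(full_file), 4), part_file)
  resumed <- run_training_stage(s$data, s$plan, s$reg, v_folds = 3,
                                results_file = part_file)
  expect_length(resumed, 10)
  expect_equal(length(readLines(part_file)), 10)
  expect_equal(records_summary(resumed), records_summary(full))
  # records round-trip through the JSON-lines file
  expect_equal(records_summary(read_records(part_file)),
               records_summary(full))
  expect_equal(read_records(part_file)[[5]]$weights, full[[5]]$weights)
})

test_that("results do not depend on the worker count", {
  s <- small_setup(seed = 5)
  r1 <- run_training_stage(s$data, s$plan, s$reg, v_folds = 3, workers = 1)
  r2 <- run_training_stage(s$data, s$plan, s$reg, v_folds = 3, workers = 2)
  expect_equal(records_summary(r1), records_summary(r2))
  expect_equal(lapply(r1, `[[`, "weights"), lapply(r2, `[[`, "weights"))
})

test_that("the full protocol runs end-to-end on a small benchmark", {
  d <- generate_binomial(generator_config(500, 50, k_true = 3,
                                          coefficients = c(3, 3, 3),
                                          seed = 9))
  plan <- sampling_plan(n_cases = 80, n_features = 8, M = 20,
                        master_seed = 9)
  out_dir <- withr::local_tempdir()
  bundle <- run_protocol(d, plan, learners = list(learner("glm", "glm"),
                                                  learner("mean", "mean")),
                         v_folds = 3, m_star_grid = c(5, 10, 20),
                         alpha_grid = c(0.9, 1e-2, 1e-6), K = 5,
                         output_dir = out_dir)
  expect_length(bundle$records, 20)
  expect_s3_class(bundle$slicer, "slicer_result")
  expect_true(bundle$slicer$optimal_m_star %in% c(5, 10, 20))
  expect_s3_class(bundle$curve, "overfitting_curve")
  expect_false(is.null(bundle$trajectories))
  expect_true(all(file.exists(file.path(out_dir,
    c("records.jsonl", "null_records.jsonl", "ranked_features.csv",
      "auc_trajectory.csv", "trajectories.csv", "overfitting_curve.csv",
      "manifest.json")))))
  manifest <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"))
  expect_equal(manifest$n, 500)
  expect_equal(manifest$plan$M, 20)
  # determinism: the ranked feature list reproduces byte-for-byte
  bundle2 <- run_protocol(d, plan,
                          learners = list(learner("glm", "glm"),
                                          learner("mean", "mean")),
                          v_folds = 3, m_star_grid = c(5, 10, 20),
                          alpha_grid = c(0.9, 1e-2, 1e-6), K = 5,
                          null_reference = "none")
  expect_identical(bundle$ranked, bundle2$ranked)
})

test_that("datasets round-trip through CSV with a generator sidecar", {
  d <- generate_binomial(generator_config(30, 6, k_true = 2,
                                          coefficients = c(1, 2), seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cbda_dataset(d, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$true_features, d$feature_names[1:2])
  back <- read_cbda_dataset(path, outcome = "y")
  expect_equal(back$X, d$X, tolerance = 1e-12)
  expect_equal(back$y, d$y)
  expect_equal(back$case_ids, d$case_ids)
})
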