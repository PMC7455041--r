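#' @title End-to-end protocol runner
#' @description Chains the stages — subsampled ensemble training, feature
#'   mining (slicer), weight diagnostics, and the overfitting test — with
#'   per-subsample seeding, optional parallel workers, and append-only
#'   JSON-lines checkpointing so an interrupted training stage resumes
#'   where it stopped.
#' @name orchestration
NULL

record_to_json <- function(rec) {
  jsonlite::toJSON(
    list(subsample_id = rec$subsample_id,
         feature_names = rec$feature_names,
         accuracy = rec$accuracy, mse = rec$mse,
         weights = as.list(rec$weights),
         metric_used = rec$metric_used),
    auto_unbox = TRUE, digits = NA, null = "null")
}

json_to_record <- function(line) {
  x <- jsonlite::fromJSON(line)
  w <- unlist(x$weights)
  structure(
    list(subsample_id = as.integer(x$subsample_id),
         feature_names = as.character(x$feature_names),
         accuracy = as.numeric(x$accuracy), mse = as.numeric(x$mse),
         weights = w, metric_used = x$metric_used),
    class = "performance_record")
}

#' Read a training-stage results file
#'
#' @param path JSON-lines results file written by [run_training_stage()].
#' @return List of `performance_record`s sorted by subsample id.
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, json_to_record)
  ids <- vapply(records, `[[`, integer(1), "subsample_id")
  records[!duplicated(ids)][order(unique(ids))]
}

fit_one_subsample <- function(data, plan, id, learners, v_folds, metric) {
  train <- draw_training_subsample(data, plan, id)
  validation <- draw_validation_set(data, train, plan)
  tv <- subsample_view(data, train)
  vv <- subsample_view(data, validation)
  if (anyNA(tv$X) || anyNA(vv$X)) {
    imp <- impute_subsample(tv$X, vv$X,
                            full_data = data$X[, train$feature_index,
                                               drop = FALSE])
    tv$X <- imp$train
    vv$X <- imp$validation
  }
  model <- fit_superlearner(tv$X, tv$y, learners,
                            outcome_type = data$outcome_type,
                            v_folds = v_folds, seed = train$seed)
  evaluate_model(model, vv$X, vv$y, subsample_id = id, metric_used = metric)
}

#' Run the subsampled ensemble training stage
#'
#' Fits one stacking ensemble per subsample id (1..M), each on its own
#' 300x30-style training draw, scored on its paired disjoint validation
#' set. Every subsample's seed derives from `(plan$master_seed, id)`, so
#' the full record set is a pure function of the plan and the data —
#' independent of the worker count and of any earlier partial run.
#'
#' Degenerate subsamples (single-class training outcome) are skipped with
#' a message; their ids simply have no record.
#'
#' @param data A [cbda_dataset()] with no missing values in the outcome.
#' @param plan A [sampling_plan()].
#' @param learners Learner registry (default [lean_registry()]).
#' @param v_folds Internal CV folds per ensemble (default 10; 3 for fast
#'   scaled runs).
#' @param metric Primary ranking metric recorded with each result.
#' @param results_file Optional JSON-lines checkpoint path. If it exists,
#'   completed subsample ids are skipped and new records appended.
#' @param workers Parallel workers via forked processes (default 1;
#'   results are identical for any worker count).
#' @param progress_every Print a progress message every this many
#'   subsamples (0 = silent).
#' @return List of `performance_record`s sorted by subsample id.
#' @export
run_training_stage <- function(data, plan, learners = lean_registry(),
                               v_folds = 10,
                               metric = c("accuracy", "mse"),
                               results_file = NULL, workers = 1,
                               progress_every = 0) {
  metric <- match.arg(metric)
  stopifnot(inherits(data, "cbda_dataset"), inherits(plan, "sampling_plan"))
  check_registry(learners)

  done <- list()
  if (!is.null(results_file) && file.exists(results_file)) {
    done <- read_records(results_file)
  }
  done_ids <- vapply(done, `[[`, integer(1), "subsample_id")
  pending <- setdiff(seq_len(plan$M), done_ids)

  one <- function(id) {
    rec <- tryCatch(
      fit_one_subsample(data, plan, id, learners, v_folds, metric),
      error = function(e) {
        message(sprintf("subsample %d skipped: %s", id, conditionMessage(e)))
        NULL
      })
    rec
  }

  new_records <- list()
  if (length(pending)) {
    if (workers > 1) {
      chunks <- split(pending, ceiling(seq_along(pending) / 50))
      for (chunk in chunks) {
        recs <- parallel::mclapply(chunk, one, mc.cores = workers,
                                   mc.preschedule = FALSE)
        recs <- Filter(Negate(is.null), recs)
        if (!is.null(results_file)) {
          for (r in recs) cat(record_to_json(r), "\n", sep = "",
                              file = results_file, append = TRUE)
        }
        new_records <- c(new_records, recs)
      }
    } else {
      for (i in seq_along(pending)) {
        r <- one(pending[i])
        if (!is.null(r)) {
          if (!is.null(results_file)) {
            cat(record_to_json(r), "\n", sep = "", file = results_file,
                append = TRUE)
          }
          new_records <- c(new_records, list(r))
        }
        if (progress_every > 0 && i %% progress_every == 0) {
          message(sprintf("  training stage: %d / %d subsamples",
                          i, length(pending)))
        }
      }
    }
  }
  records <- c(done, new_records)
  ids <- vapply(records, `[[`, integer(1), "subsample_id")
  records[order(ids)]
}

#' Run the full protocol
#'
#' Training stage, slicer-based feature mining, weight diagnostics
#' (against a matched Null-generator reference run when the dataset is
#' synthetic or `null_reference = "generate"`), and the overfitting test
#' stage on the mined feature ranking. Artifacts can be written under an
#' output directory as CSV/JSON with a manifest.
#'
#' @param data A [cbda_dataset()].
#' @param plan A [sampling_plan()].
#' @param learners Learner registry.
#' @param v_folds Internal CV folds (default 10).
#' @param metric Ranking metric.
#' @param truth Optional true feature names; defaults to the generator
#'   provenance when present.
#' @param m_star_grid,alpha_grid Grids for [run_slicer()] (defaults as
#'   there).
#' @param K Overfitting-curve depth (default 50, capped at p).
#' @param tolerance Plateau tolerance for [select_optimal_k()].
#' @param null_reference `"generate"` (default for synthetic data: run the
#'   training stage on a Null dataset of the same dimensions and plan) or
#'   `"none"` (skip the Bray-Curtis/variance trajectories).
#' @param output_dir Optional directory for artifacts
#'   (`records.jsonl`, `null_records.jsonl`, `ranked_features.csv`,
#'   `auc_trajectory.csv`, `trajectories.csv`, `overfitting_curve.csv`,
#'   `manifest.json`).
#' @param workers Parallel workers for the training stages.
#' @return A list bundle with `records`, `slicer`, `ranked`,
#'   `weight_summary`, `trajectories` (or NULL), `curve`, `plan`.
#' @export
run_protocol <- function(data, plan = sampling_plan(),
                         learners = lean_registry(), v_folds = 10,
                         metric = c("accuracy", "mse"), truth = NULL,
                         m_star_grid = NULL, alpha_grid = NULL,
                         K = 50, tolerance = 0.005,
                         null_reference = c("generate", "none"),
                         output_dir = NULL, workers = 1) {
  metric <- match.arg(metric)
  null_reference <- match.arg(null_reference)
  if (is.null(truth) && !is.null(data$provenance) &&
      data$provenance$outcome_kind == "binomial") {
    truth <- data$feature_names[data$provenance$true_indices]
  }
  rf <- nf <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    rf <- file.path(output_dir, "records.jsonl")
    nf <- file.path(output_dir, "null_records.jsonl")
  }

  records <- run_training_stage(data, plan, learners, v_folds, metric,
                                results_file = rf, workers = workers)
  slicer <- run_slicer(records, data$feature_names, truth = truth,
                       m_star_grid = m_star_grid, alpha_grid = alpha_grid,
                       metric = metric)
  ranked <- ranked_features(slicer)

  trajectories <- NULL
  if (null_reference == "generate") {
    null_cfg <- generator_config(nrow(data$X), ncol(data$X),
                                 outcome_kind = "null",
                                 seed = plan$master_seed + 1)
    null_data <- generate_null(null_cfg)
    null_plan <- plan
    null_plan$master_seed <- plan$master_seed + 1
    null_records <- run_training_stage(null_data, null_plan, learners,
                                       v_folds, metric, results_file = nf,
                                       workers = workers)
    trajectories <- weight_trajectories(records, null_records,
                                        metric = metric)
  }
  opt_m <- if (!is.na(slicer$optimal_m_star)) slicer$optimal_m_star
           else length(records)
  weight_summary <- learner_weight_cutoff(records, opt_m, metric)

  curve <- build_nested_curve(data, ranked$feature,
                              K = min(K, nrow(ranked)),
                              learners = learners,
                              v_folds = min(v_folds, 3),
                              seed = plan$master_seed)

  bundle <- list(records = records, slicer = slicer, ranked = ranked,
                 weight_summary = weight_summary,
                 trajectories = trajectories, curve = curve, plan = plan)
  if (!is.null(output_dir)) write_bundle(bundle, output_dir, data)
  bundle
}

write_bundle <- function(bundle, output_dir, data) {
  utils::write.csv(bundle$ranked,
                   file.path(output_dir, "ranked_features.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(m_star = bundle$slicer$m_star_grid,
               pr_auc = bundle$slicer$auc_per_m_star),
    file.path(output_dir, "auc_trajectory.csv"), row.names = FALSE)
  if (!is.null(bundle$trajectories)) {
    tr <- bundle$trajectories
    utils::write.csv(
      data.frame(m_star = tr$m_star_grid, bray_curtis = tr$bc_values,
                 weight_variance = tr$variance_values),
      file.path(output_dir, "trajectories.csv"), row.names = FALSE)
  }
  cv <- bundle$curve
  utils::write.csv(
    data.frame(k = cv$k_values, accuracy = cv$accuracy_at_k,
               mse = cv$mse_at_k),
    file.path(output_dir, "overfitting_curve.csv"), row.names = FALSE)
  manifest <- list(
    n = nrow(data$X), p = ncol(data$X), outcome_type = data$outcome_type,
    plan = unclass(bundle$plan),
    optimal_m_star = bundle$slicer$optimal_m_star,
    optimal_k_accuracy = cv$optimal_k_accuracy,
    optimal_k_mse = cv$optimal_k_mse,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("cbda2")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(output_dir)
}
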