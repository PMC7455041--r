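#' @title Data-wrangling filters
#' @description Generic pre-processing filters for messy tabular biomedical
#'   data: constant-feature removal, missingness thresholding, a census of
#'   categorical levels, and binary recoding of pseudo-binary features coded
#'   with sentinel levels. Each filter returns the filtered dataset together
#'   with a `wrangle_report` and never reorders surviving cases or features.
#' @name wrangling
NULL

new_wrangle_report <- function(n_dropped_constant = 0L, n_dropped_missing = 0L,
                               missingness_threshold = NA_real_,
                               level_counts = integer(0),
                               recoded_features = list()) {
  structure(
    list(n_dropped_constant = as.integer(n_dropped_constant),
         n_dropped_missing = as.integer(n_dropped_missing),
         missingness_threshold = missingness_threshold,
         level_counts = level_counts,
         recoded_features = recoded_features),
    class = "wrangle_report")
}

#' @export
print.wrangle_report <- function(x, ...) {
  cat("<wrangle_report>\n")
  cat(sprintf("  dropped constant: %d, dropped by missingness: %d",
              x$n_dropped_constant, x$n_dropped_missing))
  if (!is.na(x$missingness_threshold)) {
    cat(sprintf(" (threshold %.2f)", x$missingness_threshold))
  }
  cat("\n")
  if (length(x$level_counts)) {
    cat(sprintf("  level census over %d features\n", length(x$level_counts)))
  }
  for (rc in x$recoded_features) {
    cat(sprintf("  recoded '%s' dropping levels {%s}\n", rc$feature,
                paste(rc$dropped_levels, collapse = ", ")))
  }
  invisible(x)
}

n_distinct_nonmissing <- function(col) length(unique(col[!is.na(col)]))

#' Drop constant features
#'
#' Removes every feature with fewer than two distinct non-missing values;
#' all-missing columns count as constant. Such columns carry no information
#' and break many learners.
#'
#' @param data A [cbda_dataset()].
#' @return A list with elements `data` (filtered dataset) and `report`
#'   (a `wrangle_report` with `n_dropped_constant`).
#' @export
drop_constant_features <- function(data) {
  stopifnot(inherits(data, "cbda_dataset"))
  levels_per_feature <- apply(data$X, 2, n_distinct_nonmissing)
  keep <- levels_per_feature >= 2
  if (!any(keep)) stop("all features are constant", call. = FALSE)
  out <- data
  out$X <- data$X[, keep, drop = FALSE]
  out$feature_names <- data$feature_names[keep]
  list(data = out,
       report = new_wrangle_report(n_dropped_constant = sum(!keep)))
}

#' Filter features by missingness
#'
#' Keeps exactly the features whose missing fraction (missing entries over
#' the total case count) is at most `threshold`. The threshold is inclusive,
#' matching an "at most X% missingness" rule.
#'
#' @param data A [cbda_dataset()].
#' @param threshold Maximal tolerated missing fraction in \[0, 1\]
#'   (default 0.2).
#' @return A list with elements `data` and `report`
#'   (with `n_dropped_missing`).
#' @export
filter_by_missingness <- function(data, threshold = 0.2) {
  stopifnot(inherits(data, "cbda_dataset"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  miss_frac <- colMeans(is.na(data$X))
  keep <- miss_frac <= threshold
  out <- data
  out$X <- data$X[, keep, drop = FALSE]
  out$feature_names <- data$feature_names[keep]
  list(data = out,
       report = new_wrangle_report(n_dropped_missing = sum(!keep),
                                   missingness_threshold = threshold))
}

#' Census of categorical levels
#'
#' Counts the distinct non-missing values of every feature and reports the
#' features with at most `max_levels` levels. Missing values are never
#' counted as a level. A spike at 4 levels typically marks binary features
#' contaminated by sentinel codes (e.g. 0, 1, -1, -3).
#'
#' @param data A [cbda_dataset()].
#' @param max_levels Largest level count reported (default 30).
#' @return A `wrangle_report` whose `level_counts` is a named integer vector
#'   (feature -> level count), restricted to features with
#'   `count <= max_levels`.
#' @export
level_census <- function(data, max_levels = 30) {
  stopifnot(inherits(data, "cbda_dataset"))
  if (max_levels < 2) stop("max_levels must be at least 2", call. = FALSE)
  counts <- apply(data$X, 2, n_distinct_nonmissing)
  names(counts) <- data$feature_names
  new_wrangle_report(level_counts = counts[counts <= max_levels])
}

#' Recode a multi-level feature to binary
#'
#' Drops sentinel levels from a pseudo-binary feature so that exactly two
#' levels remain, then maps them to \{0, 1\} preserving numeric order. Cases
#' carrying a dropped level become missing for that feature — unless the
#' feature is the outcome, in which case those cases are removed entirely.
#'
#' @param data A [cbda_dataset()].
#' @param feature Feature name to recode, or `"y"` for the outcome column.
#' @param drop_levels Values to eliminate (possibly empty).
#' @return A list with elements `data` and `report` (with
#'   `recoded_features`).
#' @export
recode_multilevel_binary <- function(data, feature, drop_levels = numeric(0)) {
  stopifnot(inherits(data, "cbda_dataset"))
  is_outcome <- identical(feature, "y")
  if (!is_outcome && !feature %in% data$feature_names) {
    stop(sprintf("feature '%s' not found", feature), call. = FALSE)
  }
  col <- if (is_outcome) data$y else data$X[, feature]
  col[col %in% drop_levels] <- NA
  lev <- sort(unique(col[!is.na(col)]))
  if (length(lev) != 2) {
    stop(sprintf("recoding '%s' leaves %d levels, need exactly 2",
                 feature, length(lev)), call. = FALSE)
  }
  recoded <- as.numeric(col == lev[2])
  out <- data
  if (is_outcome) {
    keep <- !is.na(recoded)
    out$X <- data$X[keep, , drop = FALSE]
    out$y <- recoded[keep]
    out$case_ids <- data$case_ids[keep]
    out$outcome_type <- "binary"
  } else {
    out$X[, feature] <- recoded
  }
  list(data = out,
       report = new_wrangle_report(
         recoded_features = list(list(feature = feature,
                                      dropped_levels = drop_levels))))
}

#' Impute a training/validation subsample pair
#'
#' Completes missing entries using statistics computed on the *training*
#' rows only: the median for numeric features, the mode for
#' binary/categorical-coded features. Validation rows are imputed
#' with the same training statistics, so no validation information leaks
#' into training. A feature that is all-missing within the training rows
#' falls back to its full-dataset statistic, with a warning.
#'
#' @param train Numeric matrix of training rows.
#' @param validation Optional numeric matrix of validation rows with the
#'   same columns.
#' @param categorical_max_levels Features with at most this many distinct
#'   non-missing training values are imputed with the mode rather than the
#'   median (default 2, i.e. binary codes; raise it for multi-level
#'   categorical codes).
#' @param full_data Optional full-column matrix supplying the fallback
#'   statistic for all-missing training columns.
#' @return A list with completed `train` and `validation` matrices.
#' @export
impute_subsample <- function(train, validation = NULL,
                             categorical_max_levels = 2, full_data = NULL) {
  train <- as.matrix(train)
  if (!is.null(validation)) {
    validation <- as.matrix(validation)
    stopifnot(ncol(validation) == ncol(train))
  }
  stat_of <- function(col) {
    v <- col[!is.na(col)]
    if (!length(v)) return(NA_real_)
    if (length(unique(v)) <= categorical_max_levels) {
      tab <- table(v)
      as.numeric(names(tab)[which.max(tab)])  # mode; ties -> smallest value
    } else {
      stats::median(v)
    }
  }
  for (j in seq_len(ncol(train))) {
    s <- stat_of(train[, j])
    if (is.na(s)) {
      warning(sprintf(
        "column %d all-missing in training subsample; using full-data statistic", j))
      s <- if (!is.null(full_data)) stat_of(full_data[, j]) else NA_real_
      if (is.na(s)) {
        stop(sprintf("column %d has no non-missing values anywhere", j),
             call. = FALSE)
      }
    }
    train[is.na(train[, j]), j] <- s
    if (!is.null(validation)) validation[is.na(validation[, j]), j] <- s
  }
  list(train = train, validation = validation)
}
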