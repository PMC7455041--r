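#' Labeled case-by-feature dataset
#'
#' The basic container mined by the protocol: a numeric case-by-feature
#' matrix `X`, an outcome vector `y` (binary 0/1 or continuous), unique case
#' identifiers and feature names. This is the "universe" from which training
#' and validation subsamples are drawn.
#'
#' @param X Numeric matrix, cases in rows, features in columns. `NA` entries
#'   denote missing values.
#' @param y Outcome vector of length `nrow(X)`; for `outcome_type = "binary"`
#'   all non-missing values must be 0 or 1.
#' @param outcome_type Either `"binary"` or `"continuous"`.
#' @param feature_names Character vector of `ncol(X)` unique feature names;
#'   defaults to `colnames(X)` or `f0001 ...` style names.
#' @param case_ids Character vector of `nrow(X)` unique case identifiers;
#'   defaults to `rownames(X)` or `case_1 ...`.
#' @param provenance Optional [generator_config()] recording how a synthetic
#'   dataset was produced (in particular its true feature indices).
#'
#' @return An object of class `cbda_dataset`: a list with elements `X`, `y`,
#'   `feature_names`, `case_ids`, `outcome_type`, `provenance`.
#' @export
#' @examples
#' d <- cbda_dataset(matrix(rnorm(20), 5, 4), y = c(0, 1, 0, 1, 1))
#' dim(d$X)
cbda_dataset <- function(X, y, outcome_type = c("binary", "continuous"),
                         feature_names = NULL, case_ids = NULL,
                         provenance = NULL) {
  outcome_type <- match.arg(outcome_type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (outcome_type == "binary" && !all(stats::na.omit(y) %in% c(0, 1))) {
    stop("binary outcome must be coded 0/1", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
  }
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%04d", seq_len(ncol(X)))
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (is.null(case_ids)) case_ids <- rownames(X)
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(nrow(X)))
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) {
    stop("case ids must be unique", call. = FALSE)
  }
  colnames(X) <- feature_names
  rownames(X) <- NULL
  structure(
    list(X = X, y = as.numeric(y), feature_names = as.character(feature_names),
         case_ids = case_ids, outcome_type = outcome_type,
         provenance = provenance),
    class = "cbda_dataset")
}

#' @export
print.cbda_dataset <- function(x, ...) {
  cat(sprintf("<cbda_dataset> %d cases x %d features, %s outcome\n",
              nrow(x$X), ncol(x$X), x$outcome_type))
  if (!is.null(x$provenance)) {
    cat(sprintf("  synthetic (%s generator, seed %d)\n",
                x$provenance$outcome_kind, x$provenance$seed))
  }
  invisible(x)
}

#' @export
dim.cbda_dataset <- function(x) dim(x$X)

#' Read a labeled dataset from a delimited text file
#'
#' Expects a header row, a case-ID column and a named outcome column; all
#' remaining columns are treated as features. Non-numeric feature columns are
#' coerced to numeric level codes.
#'
#' @param path CSV/TSV file path (separator auto-detected from the extension).
#' @param outcome Name of the outcome column.
#' @param id_col Name of the case-ID column (default `"case_id"`; if absent,
#'   row numbers are used).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @return A [cbda_dataset()].
#' @export
read_cbda_dataset <- function(path, outcome, id_col = "case_id",
                              outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!outcome %in% names(df)) {
    stop(sprintf("outcome column '%s' not found", outcome), call. = FALSE)
  }
  ids <- if (id_col %in% names(df)) as.character(df[[id_col]]) else
    as.character(seq_len(nrow(df)))
  keep <- setdiff(names(df), c(outcome, id_col))
  X <- vapply(df[keep], function(col) {
    if (is.character(col)) col <- as.numeric(factor(col))
    as.numeric(col)
  }, numeric(nrow(df)))
  X <- matrix(X, nrow = nrow(df), dimnames = list(NULL, keep))
  cbda_dataset(X, df[[outcome]], outcome_type = outcome_type,
               feature_names = keep, case_ids = ids)
}

#' Write a labeled dataset to CSV
#'
#' Writes the standard header layout `case_id, y, <features...>`; missing
#' entries become empty fields.
#'
#' @param data A [cbda_dataset()].
#' @param path Output CSV path.
#' @param sidecar If `TRUE` and the dataset has generator provenance, also
#'   write `<path>.json` recording the generator configuration.
#' @return `path`, invisibly.
#' @export
write_cbda_dataset <- function(data, path, sidecar = TRUE) {
  stopifnot(inherits(data, "cbda_dataset"))
  df <- data.frame(case_id = data$case_ids, y = data$y,
                   data$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (sidecar && !is.null(data$provenance)) {
    cfg <- data$provenance
    jsonlite::write_json(
      list(n = cfg$n, p = cfg$p, outcome_kind = cfg$outcome_kind,
           k_true = cfg$k_true, true_indices = cfg$true_indices,
           true_features = data$feature_names[cfg$true_indices],
           coefficients = cfg$coefficients, noise_sd = cfg$noise_sd,
           seed = cfg$seed),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
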