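#' Base-learner specification
#'
#' One member of the ensemble registry: a learner family plus hyperparameters.
#' Supported families and their backing implementations:
#' `glm` (stats::glm), `elastic_net` (glmnet), `random_forest` (ranger),
#' `gradient_boosting` (xgboost), `svm` (e1071), `knn` (class::knn,
#' binary only), `neural_net` (nnet), `mean` (constant predictor), and
#' `bagged_trees` (bootstrap-aggregated rpart stumps).
#'
#' @param name Unique name within a registry.
#' @param family One of the families listed above.
#' @param hyperparameters Named list of family-specific settings; anything
#'   omitted falls back to the family default.
#' @return An object of class `learner_spec`.
#' @export
#' @examples
#' learner("rf_small", "random_forest", list(num_trees = 50))
learner <- function(name, family = c("glm", "elastic_net", "random_forest",
                                     "gradient_boosting", "svm", "knn",
                                     "neural_net", "mean", "bagged_trees"),
                    hyperparameters = list()) {
  family <- match.arg(family)
  structure(list(name = name, family = family,
                 hyperparameters = hyperparameters),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters)) {
    paste0(" (", paste(names(x$hyperparameters), unlist(x$hyperparameters),
                       sep = "=", collapse = ", "), ")")
  } else ""
  cat(sprintf("<learner> %s: %s%s\n", x$name, x$family, hp))
  invisible(x)
}

check_registry <- function(learners) {
  stopifnot(length(learners) >= 1,
            all(vapply(learners, inherits, logical(1), "learner_spec")))
  nms <- vapply(learners, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("learner names must be unique within a registry", call. = FALSE)
  }
  nms
}

#' Lean learner registry
#'
#' Three fast, complementary learners — L1-regularized logistic/linear
#' regression, a random forest, and gradient boosting — tuned for the
#' scaled-down benchmark runs where thousands of small subsample models are
#' fitted on one CPU.
#'
#' @return A list of [learner()] specs.
#' @export
lean_registry <- function() {
  list(
    learner("glmnet_lasso", "elastic_net",
            list(alpha = 1, lambda = "aic", nlambda = 20)),
    learner("ranger_small", "random_forest", list(num_trees = 30)),
    learner("xgboost_small", "gradient_boosting",
            list(nrounds = 12, max_depth = 3, eta = 0.4)))
}

#' Default learner registry
#'
#' A lean mirror of the full 55-algorithm library used at HPC scale: one to
#' three hyperparameter variants per learner class rather than every
#' variant. The class structure, not the variant count, is what the
#' ensemble needs; larger grids can be declared with [learner()].
#'
#' @return A list of [learner()] specs (~12 learners across 9 families).
#' @export
default_registry <- function() {
  list(
    learner("glm", "glm"),
    learner("glmnet_ridge", "elastic_net", list(alpha = 0, lambda = "aic")),
    learner("glmnet_enet50", "elastic_net", list(alpha = 0.5, lambda = "aic")),
    learner("glmnet_lasso", "elastic_net", list(alpha = 1, lambda = "aic")),
    learner("ranger_200", "random_forest", list(num_trees = 200)),
    learner("xgboost_d3", "gradient_boosting",
            list(nrounds = 50, max_depth = 3, eta = 0.3)),
    learner("xgboost_d6", "gradient_boosting",
            list(nrounds = 50, max_depth = 6, eta = 0.3)),
    learner("svm_radial", "svm", list(kernel = "radial")),
    learner("knn_10", "knn", list(k = 10)),
    learner("nnet_4", "neural_net", list(size = 4, decay = 0.1)),
    learner("mean", "mean"),
    learner("bagged_rpart", "bagged_trees", list(n_bags = 20)))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Fit one base learner. Returns an opaque fit object consumed by
# predict_learner(); binary outcomes are always predicted on the
# probability scale.
fit_learner <- function(spec, X, y, outcome_type, seed = 1) {
  hp <- spec$hyperparameters
  binary <- outcome_type == "binary"
  fit <- switch(
    spec$family,
    mean = list(value = mean(y)),
    glm = {
      df <- data.frame(y = y, X, check.names = FALSE)
      fam <- if (binary) stats::binomial() else stats::gaussian()
      suppressWarnings(stats::glm(y ~ ., data = df, family = fam))
    },
    elastic_net = {
      if (ncol(X) < 2) {
        # glmnet needs >= 2 columns; a plain GLM is the 1-feature limit
        df <- data.frame(y = y, X, check.names = FALSE)
        fam <- if (binary) stats::binomial() else stats::gaussian()
        suppressWarnings(stats::glm(y ~ ., data = df, family = fam))
      } else {
        alpha <- hp$alpha %||% 1
        nlambda <- hp$nlambda %||% 20
        fam <- if (binary) "binomial" else "gaussian"
        lam <- hp$lambda %||% "aic"
        if (identical(lam, "cv")) {
          cv <- glmnet::cv.glmnet(X, y, family = fam, alpha = alpha,
                                  nfolds = 3, nlambda = nlambda)
          list(glmnet_fit = cv$glmnet.fit, s = cv$lambda.min)
        } else if (identical(lam, "aic")) {
          g <- glmnet::glmnet(X, y, family = fam, alpha = alpha,
                              nlambda = nlambda, lambda.min.ratio = 0.02)
          # AIC along the path with df = number of active coefficients
          aic <- stats::deviance(g) + 2 * g$df
          list(glmnet_fit = g, s = g$lambda[which.min(aic)])
        } else {
          g <- glmnet::glmnet(X, y, family = fam, alpha = alpha,
                              lambda = lam)
          list(glmnet_fit = g, s = lam[length(lam)])
        }
      }
    },
    random_forest = {
      # regression forest on the 0/1 outcome: fast, and its mean-of-trees
      # prediction is already a probability for binary outcomes
      ranger::ranger(x = X, y = y, num.trees = hp$num_trees %||% 100,
                     mtry = hp$mtry, min.node.size = hp$min_node_size %||% 5,
                     num.threads = 1, seed = seed, verbose = FALSE)
    },
    gradient_boosting = {
      obj <- if (binary) "binary:logistic" else "reg:squarederror"
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = obj, max_depth = hp$max_depth %||% 3,
                      eta = hp$eta %||% 0.3, nthread = 1),
        data = dtrain, nrounds = hp$nrounds %||% 50, verbose = 0)
    },
    svm = {
      if (binary) {
        e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                   kernel = hp$kernel %||% "radial",
                   cost = hp$cost %||% 1, probability = TRUE)
      } else {
        e1071::svm(x = X, y = y, kernel = hp$kernel %||% "radial",
                   cost = hp$cost %||% 1)
      }
    },
    knn = {
      if (!binary) stop("knn learner supports binary outcomes only",
                        call. = FALSE)
      list(X = X, y = y, k = hp$k %||% 10)  # lazy learner: keep the data
    },
    neural_net = {
      set.seed(seed)
      capture <- utils::capture.output(
        m <- nnet::nnet(X, y, size = hp$size %||% 4,
                        decay = hp$decay %||% 0.1,
                        maxit = hp$maxit %||% 200,
                        linout = !binary, trace = FALSE))
      m
    },
    bagged_trees = {
      n_bags <- hp$n_bags %||% 20
      set.seed(seed)
      df <- data.frame(y = y, X, check.names = FALSE)
      lapply(seq_len(n_bags), function(b) {
        idx <- sample.int(nrow(df), nrow(df), replace = TRUE)
        rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                     method = "anova",
                     control = rpart::rpart.control(cp = 0.01,
                                                    maxdepth = hp$maxdepth %||% 10))
      })
    })
  structure(list(spec = spec, fit = fit, binary = binary,
                 feature_names = colnames(X)),
            class = "cbda_learner_fit")
}

predict_learner <- function(object, X) {
  spec <- object$spec
  fit <- object$fit
  p <- switch(
    spec$family,
    mean = rep(fit$value, nrow(X)),
    glm = as.numeric(stats::predict(fit, newdata = data.frame(X, check.names = FALSE),
                                    type = "response")),
    elastic_net = {
      if (inherits(fit, "glm")) {
        as.numeric(stats::predict(fit, newdata = data.frame(X, check.names = FALSE),
                                  type = "response"))
      } else {
        as.numeric(stats::predict(fit$glmnet_fit, X, s = fit$s,
                                  type = "response"))
      }
    },
    random_forest = as.numeric(stats::predict(fit, data = X,
                                              num.threads = 1)$predictions),
    gradient_boosting = as.numeric(stats::predict(
      fit, xgboost::xgb.DMatrix(X, nthread = 1))),
    svm = {
      if (object$binary) {
        pr <- stats::predict(fit, X, probability = TRUE)
        as.numeric(attr(pr, "probabilities")[, "1"])
      } else {
        as.numeric(stats::predict(fit, X))
      }
    },
    knn = {
      kn <- class::knn(train = fit$X, test = X,
                       cl = factor(fit$y, levels = c(0, 1)),
                       k = fit$k, prob = TRUE)
      pr <- attr(kn, "prob")  # proportion of votes for the winning class
      as.numeric(ifelse(kn == "1", pr, 1 - pr))
    },
    neural_net = as.numeric(stats::predict(fit, X)),
    bagged_trees = {
      df <- data.frame(X, check.names = FALSE)
      rowMeans(vapply(fit, function(tree) stats::predict(tree, newdata = df),
                      numeric(nrow(X))))
    })
  if (object$binary) clamp01(p) else p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
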