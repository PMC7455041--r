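# assemble a cbda_ensemble with constant-prediction (mean-family) learners
constant_ensemble <- function(values, weights, feature_names = c("x1", "x2")) {
  nms <- paste0("m", seq_along(values))
  fits <- lapply(values, function(v) {
    structure(list(spec = learner("c", "mean"), fit = list(value = v),
                   binary = TRUE, feature_names = feature_names),
              class = "cbda_learner_fit")
  })
  names(fits) <- nms
  names(weights) <- nms
  structure(
    list(learners = lapply(nms, learner, family = "mean"), fits = fits,
         weights = weights, v_folds = 3, loss = "squared_error",
         feature_names = feature_names, outcome_type = "binary"),
    class = "cbda_ensemble")
}

test_that("a single-learner registry gets weight one", {
  set.seed(1)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(40, 1, 0.5)
  fit <- fit_superlearner(X, y, list(learner("only", "glm")), v_folds = 4)
  expect_equal(unname(fit$weights), 1)
  expect_equal(sum(fit$weights), 1)
})

test_that("a learner matching the truth dominates the weights", {
  set.seed(7)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] + 1  # deterministic linear function of one feature
  fit <- fit_superlearner(X, y, list(learner("glm", "glm"),
                                     learner("mean", "mean")),
                          outcome_type = "continuous", v_folds = 5)
  expect_gt(fit$weights[["glm"]], 0.9)
})

test_that("ensemble predictions are the weighted learner average", {
  m <- constant_ensemble(c(0.2, 0.8), c(0.25, 0.75))
  X <- matrix(0, 3, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(unname(predict(m, X)), rep(0.65, 3))
  # convexity: identical learner predictions pass through any simplex weights
  m2 <- constant_ensemble(c(0.7, 0.7, 0.7), c(0.1, 0.6, 0.3))
  expect_equal(unname(predict(m2, X)), rep(0.7, 3))
  # degenerate weights reproduce a single learner
  m3 <- constant_ensemble(c(0.2, 0.8), c(1, 0))
  expect_equal(unname(predict(m3, X)), rep(0.2, 3))
  # feature mismatch is a schema error
  bad <- matrix(0, 3, 2, dimnames = list(NULL, c("x2", "x1")))
  expect_error(predict(m, bad), "match")
})

test_that("validation scoring computes accuracy under the >=0.5 rule and mse", {
  assign("predict.stub_model",
         function(object, newdata, ...) object$preds, envir = globalenv())
  withr::defer(rm("predict.stub_model", envir = globalenv()))
  stub <- function(preds) {
    structure(list(outcome_type = "binary", feature_names = "f",
                   weights = c(m = 1), preds = preds),
              class = "stub_model")
  }
  X <- matrix(0, 4, 1, dimnames = list(NULL, "f"))
  rec <- evaluate_model(stub(c(0.9, 0.2, 0.6, 0.4)), X, c(1, 0, 0, 1),
                        subsample_id = 1)
  expect_equal(rec$accuracy, 0.5)
  expect_equal(rec$mse, 0.1925)  # mean of (0.01, 0.04, 0.36, 0.36)
  perfect <- evaluate_model(stub(c(1, 0, 0, 1)), X, c(1, 0, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mse, 0)
  # ties at 0.5 binarize to class 1
  half <- evaluate_model(stub(rep(0.5, 4)), X, c(0, 1, 0, 1))
  expect_equal(half$accuracy, 0.5)
  expect_error(evaluate_model(stub(numeric(0)),
                              X[integer(0), , drop = FALSE], numeric(0)),
               "empty")
})

test_that("weights stay on the simplex when a learner fails", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(100, 0, 0.1)  # continuous outcome: knn must fail
  expect_warning(
    fit <- fit_superlearner(X, y, list(learner("glm", "glm"),
                                       learner("knn", "knn")),
                            outcome_type = "continuous", v_folds = 4),
    "failed")
  expect_equal(unname(fit$weights[["knn"]]), 0)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(fit$weights >= 0))
})

test_that("degenerate single-class subsamples are rejected", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fit_superlearner(X, rep(1, 20), lean_registry(),
                                v_folds = 4),
               "single-class")
})

test_that("registry order does not change predictions", {
  set.seed(11)
  X <- matrix(rnorm(450), 150, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(150, 1, plogis(2 * X[, 1]))
  Xnew <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  reg <- list(learner("glm", "glm"), learner("mean", "mean"),
              learner("lasso", "elastic_net", list(alpha = 1)))
  f1 <- fit_superlearner(X, y, reg, v_folds = 5, seed = 2)
  f2 <- fit_superlearner(X, y, rev(reg), v_folds = 5, seed = 2)
  expect_lt(max(abs(predict(f1, Xnew) - predict(f2, Xnew))), 1e-8)
})

test_that("the meta-step solves small stacking problems exactly", {
  # one learner perfectly predicts y, the other is orthogonal noise
  set.seed(5)
  y <- rnorm(50)
  Z <- cbind(y, rnorm(50))
  w <- cbda2:::solve_meta_weights(Z, y)
  expect_equal(unname(w), c(1, 0), tolerance = 1e-6)
  # symmetric averaging case: y is the mean of two half-informative columns
  Z2 <- cbind(y + 1, y - 1)
  w2 <- cbda2:::solve_meta_weights(Z2, y)
  expect_equal(unname(w2), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("log-loss meta mode yields simplex weights with sane risk", {
  set.seed(13)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(3 * X[, 1]))
  fit <- fit_superlearner(X, y, list(learner("glm", "glm"),
                                     learner("mean", "mean")),
                          v_folds = 4, loss = "log_loss")
  expect_equal(sum(fit$weights), 1)
  expect_true(all(fit$weights >= 0))
  expect_gt(fit$weights[["glm"]], 0.5)
  expect_lt(fit$cv_risk_ensemble, log(2))  # better than coin-flip log loss
})
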