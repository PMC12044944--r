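# Base-learner registry. Each learner exposes fit(x, y01, params, seed) and
# predict_prob(model, x) returning P(positive); default hyperparameter grids
# are small caret-style grids. y01 is integer 0/1 with 1 = positive class.

learner_knn <- list(
  grid = function(p) tibble(k = c(3, 5, 7, 9)),
  fit = function(x, y, params, seed) {
    list(x = x, y = y, k = params$k, seed = seed)
  },
  predict_prob = function(model, x) {
    pr <- with_seed(model$seed, class::knn(
      train = model$x, test = x, cl = factor(model$y, levels = c(0, 1)),
      k = min(model$k, nrow(model$x)), prob = TRUE))
    win <- attr(pr, "prob")
    ifelse(pr == "1", win, 1 - win)
  }
)

learner_mlp <- list(
  grid = function(p) tibble(size = c(16, 32, 64)),
  fit = function(x, y, params, seed) {
    with_seed(seed, nnet::nnet(
      x, y, size = params$size, decay = params$decay %||% 1e-3,
      maxit = params$maxit %||% 150, entropy = TRUE, trace = FALSE,
      MaxNWts = 200000))
  },
  predict_prob = function(model, x) as.numeric(predict(model, x))
)

learner_pls <- list(
  grid = function(p) tibble(ncomp = seq(2, min(8, max(2, p - 1)))),
  fit = function(x, y, params, seed) {
    ncomp <- min(params$ncomp, ncol(x), nrow(x) - 1)
    with_seed(seed, mixOmics::plsda(
      x, factor(y, levels = c(0, 1)), ncomp = ncomp))
  },
  predict_prob = function(model, x) {
    pr <- predict(model, x)$predict
    score <- pr[, "1", dim(pr)[3]]
    pmin(1, pmax(0, as.numeric(score)))
  }
)

learner_rf <- list(
  grid = function(p) tibble(mtry = unique(pmax(1, round(c(sqrt(p), p / 4))))),
  fit = function(x, y, params, seed) {
    with_seed(seed, randomForest::randomForest(
      x, factor(y, levels = c(0, 1)),
      ntree = params$ntree %||% 500, mtry = min(params$mtry, ncol(x))))
  },
  predict_prob = function(model, x) {
    unname(predict(model, x, type = "prob")[, "1"])
  }
)

learner_svm <- list(
  grid = function(p) tidyr::expand_grid(cost = c(0.1, 1, 10),
                                        gamma = c(NA, 0.01)),
  fit = function(x, y, params, seed) {
    gamma <- params$gamma
    if (is.null(gamma) || is.na(gamma)) gamma <- 1 / ncol(x)
    # constant columns trip e1071's internal scaling; the warning is benign
    with_seed(seed, suppressWarnings(e1071::svm(
      x, factor(y, levels = c(0, 1)), kernel = "radial",
      cost = params$cost %||% 1, gamma = gamma, probability = TRUE)))
  },
  predict_prob = function(model, x) {
    pr <- suppressWarnings(predict(model, x, probability = TRUE))
    unname(attr(pr, "probabilities")[, "1"])
  }
)

learner_xgb <- list(
  grid = function(p) tidyr::expand_grid(max_depth = c(3, 6),
                                        eta = c(0.1, 0.3)),
  fit = function(x, y, params, seed) {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    max_depth = params$max_depth %||% 6,
                    eta = params$eta %||% 0.3),
      data = dtrain, nrounds = params$nrounds %||% 300, verbose = 0))
  },
  predict_prob = function(model, x) {
    as.numeric(predict(model, xgboost::xgb.DMatrix(x)))
  }
)

#' Base-learner registry
#'
#' The six classification algorithms available as base learners, each with a
#' small default hyperparameter grid: `KNN` (k in 3..9), `MLP` (one hidden
#' layer of 16/32/64 units), `PLS` (2..8 components, class scores clipped to
#' probabilities), `RF` (500 trees, mtry in {sqrt(p), p/4}), `SVM` (RBF
#' kernel, cost x gamma grid, Platt probability outputs), `XGB` (depth 3/6,
#' learning rate 0.1/0.3, 300 rounds).
#'
#' @return Named list of learner definitions (`grid`, `fit`,
#'   `predict_prob`).
#' @export
base_learners <- function() {
  list(KNN = learner_knn, MLP = learner_mlp, PLS = learner_pls,
       RF = learner_rf, SVM = learner_svm, XGB = learner_xgb)
}

get_learner <- function(algorithm) {
  reg <- base_learners()
  assert_that(algorithm %in% names(reg),
              sprintf("unknown algorithm '%s'; valid: %s", algorithm,
                      paste(names(reg), collapse = ", ")),
              class = "stackscreen_config_error")
  reg[[algorithm]]
}

#' Tune and fit one base classifier
#'
#' Grid-searches the learner's hyperparameters by stratified k-fold
#' cross-validation on the (balanced) training subset, maximizing the
#' Matthews correlation coefficient of the pooled out-of-fold predictions,
#' then refits the winning configuration on the full subset.
#'
#' @param x Feature matrix (rows = subset compounds).
#' @param y Binary labels (0/1, logical, or factor with positive level
#'   `"active"`/second level).
#' @param algorithm Name from [base_learners()].
#' @param grid Data frame of candidate hyperparameter rows; `NULL` for the
#'   learner default; a single-row grid skips the search.
#' @param folds CV folds for tuning (default 10).
#' @param seed Integer seed.
#' @return A `base_model` list: `algorithm`, `params`, `cv_mcc`, `fit`.
#' @export
tune_base_classifier <- function(x, y, algorithm, grid = NULL, folds = 10,
                                 seed = 1) {
  x <- as.matrix(x)
  learner <- get_learner(algorithm)
  y01 <- as_binary(y, "active")
  if (is.null(grid)) grid <- learner$grid(ncol(x))
  grid <- as.data.frame(grid)
  assert_that(nrow(grid) >= 1, "empty hyperparameter grid",
              class = "stackscreen_config_error")
  cv_mcc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      cv <- cross_validate(
        x, y01,
        fit = function(xt, yt) learner$fit(xt, yt, params,
                                           derive_seed(seed, "tune", g)),
        predict_prob = learner$predict_prob,
        folds = folds, seed = derive_seed(seed, "folds"))
      cv_mcc[g] <- cv$pooled$mcc
    }
    best <- which.max(cv_mcc)
  } else {
    best <- 1L
  }
  params <- as.list(grid[best, , drop = FALSE])
  structure(
    list(algorithm = algorithm, params = params,
         cv_mcc = cv_mcc[best],
         fit = learner$fit(x, y01, params, derive_seed(seed, "final"))),
    class = "base_model")
}

#' Predict positive-class probabilities from a base model
#'
#' @param object A `base_model` from [tune_base_classifier()].
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict.base_model <- function(object, newdata, ...) {
  p <- get_learner(object$algorithm)$predict_prob(object$fit,
                                                  as.matrix(newdata))
  pmin(1, pmax(0, p))
}

#' Out-of-fold probability scores
#'
#' Scores every training compound with the fold model that excluded it,
#' using fixed (already tuned) hyperparameters, so the resulting
#' probabilities are not contaminated by in-sample fitting.
#'
#' @inheritParams tune_base_classifier
#' @param params Hyperparameter list (e.g. `model$params`).
#' @return Numeric vector of probabilities aligned with rows of `x`.
#' @export
oof_probability <- function(x, y, algorithm, params, folds = 10, seed = 1) {
  x <- as.matrix(x)
  y01 <- as_binary(y, "active")
  assert_that(folds <= nrow(x), "more folds than subset compounds",
              class = "stackscreen_fold_error")
  learner <- get_learner(algorithm)
  cv <- cross_validate(
    x, y01,
    fit = function(xt, yt) learner$fit(xt, yt, params,
                                       derive_seed(seed, "oof")),
    predict_prob = learner$predict_prob,
    folds = folds, seed = derive_seed(seed, "folds"))
  pmin(1, pmax(0, cv$oof$score))
}
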