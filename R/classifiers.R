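#' Classifier specification
#'
#' Names one of the supported classifier families with optional
#' hyperparameters. Families map onto established implementations:
#' `knn` ([class::knn()], `k = 5` by default), `naive_bayes`
#' ([e1071::naiveBayes()]), `svm_rbf` / `svm_linear` ([e1071::svm()];
#' the RBF kernel scale defaults to `1 / (n_features * mean feature
#' variance)`), `decision_tree` ([rpart::rpart()]), `random_forest`
#' ([randomForest::randomForest()]), `adaboost` (discrete AdaBoost.M1 over
#' depth-1 rpart stumps, implemented in this package), `xgboost`
#' ([xgboost::xgboost()]), and `majority` (a constant majority-class
#' baseline useful for null checks).
#'
#' @param family Classifier family name.
#' @param ... Family hyperparameters, e.g. `k = 5` for `knn`, `nrounds` for
#'   boosting families, `cost` for SVMs.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm_rbf", "knn", "naive_bayes",
                                       "decision_tree", "random_forest",
                                       "adaboost", "xgboost", "svm_linear",
                                       "majority"),
                            ...) {
  family <- match.arg(family)
  hp <- list(...)
  defaults <- switch(family,
    knn = list(k = 5L),
    svm_rbf = list(cost = 1),
    svm_linear = list(cost = 1),
    decision_tree = list(),
    random_forest = list(ntree = 500L),
    adaboost = list(nrounds = 50L),
    xgboost = list(nrounds = 50L, max_depth = 3L, eta = 0.3),
    naive_bayes = list(),
    majority = list()
  )
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hp)
  structure(list(family = family, hyperparameters = hp),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters)) {
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = "=", collapse = ", ")
  } else "defaults"
  cat("<classifier_spec> ", x$family, " (", hp, ")\n", sep = "")
  invisible(x)
}

# Fit/predict dispatch. X: numeric matrix; y: factor with >= 2 levels
# (majority baseline excepted). Returns a model object consumed by
# predict_classifier().
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- factor(y)
  hp <- spec$hyperparameters
  model <- switch(spec$family,
    knn = list(X = X, y = y, k = min(hp$k, nrow(X))),  # cap at n_train
    naive_bayes = e1071::naiveBayes(X, y),
    svm_rbf = e1071::svm(X, y, kernel = "radial", cost = hp$cost,
                         gamma = svm_scale_gamma(X)),
    svm_linear = e1071::svm(X, y, kernel = "linear", cost = hp$cost),
    decision_tree = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    random_forest = randomForest::randomForest(X, y, ntree = hp$ntree),
    adaboost = fit_adaboost_stumps(X, y, hp$nrounds),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y) - 1)
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
      list(booster = bst, levels = levels(y))
    },
    majority = list(level = names(which.max(table(y))), levels = levels(y))
  )
  structure(list(family = spec$family, model = model, levels = levels(y)),
            class = "mw_classifier")
}

# RBF kernel scale convention: 1 / (d * mean feature variance)
svm_scale_gamma <- function(X) {
  v <- mean(apply(X, 2, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

predict_classifier <- function(fit, X) {
  stopifnot(inherits(fit, "mw_classifier"))
  X <- as.matrix(X)
  m <- fit$model
  pred <- switch(fit$family,
    knn = class::knn(m$X, X, m$y, k = m$k),
    naive_bayes = stats::predict(m, X),
    svm_rbf = ,
    svm_linear = stats::predict(m, X),
    decision_tree = {
      df <- data.frame(X, check.names = FALSE)
      stats::predict(m, df, type = "class")
    },
    random_forest = stats::predict(m, X),
    adaboost = predict_adaboost_stumps(m, X),
    xgboost = {
      p <- stats::predict(m$booster, xgboost::xgb.DMatrix(X))
      factor(m$levels[1 + (p > 0.5)], levels = m$levels)
    },
    majority = factor(rep(m$level, nrow(X)), levels = m$levels)
  )
  factor(as.character(pred), levels = fit$levels)
}

# Discrete AdaBoost.M1 with depth-1 rpart stumps; two-class only.
fit_adaboost_stumps <- function(X, y, nrounds) {
  stopifnot(nlevels(y) == 2)
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, X, check.names = FALSE)
  stumps <- list(); alphas <- numeric(0)
  for (r in seq_len(nrounds)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = -1, minsplit = 2,
                                                         xval = 0))
    pred <- stats::predict(stump, df, type = "class")
    err <- sum(w * (pred != y))
    if (err <= 1e-12) {  # perfect stump: keep it with a large finite vote
      stumps[[length(stumps) + 1]] <- stump
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break  # no better than chance under current weights
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {  # fall back to a single stump vote
    stumps <- list(rpart::rpart(.y ~ ., data = df, method = "class",
                                control = rpart::rpart.control(maxdepth = 1,
                                                               xval = 0)))
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost_stumps <- function(m, X) {
  df <- data.frame(X, check.names = FALSE)
  score <- rep(0, nrow(df))
  for (i in seq_along(m$stumps)) {
    pred <- stats::predict(m$stumps[[i]], df, type = "class")
    score <- score + m$alphas[i] * ifelse(pred == m$levels[2], 1, -1)
  }
  factor(m$levels[1 + (score > 0)], levels = m$levels)
}
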