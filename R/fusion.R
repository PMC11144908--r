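#' Aggregate slice-wise deep features to one case vector
#'
#' Per-feature mean across the 4 slices (permutation-invariant; keeps 200
#' nameable features for the importance ranking).
#'
#' @param deep 4 x 200 matrix from [extract_deep_features()]
#' @return named numeric vector of 200 values
#' @export
aggregate_case_features <- function(deep) {
  if (is.null(dim(deep)) || nrow(deep) != 4L) {
    stop("deep features must be a complete 4 x d matrix")
  }
  if (anyNA(deep)) stop("deep features contain missing rows")
  colMeans(deep)
}

#' Rank features by mean decrease in impurity over repeated random forests
#'
#' Fits `n_runs` random forests with distinct derived seeds, normalizes
#' each run's impurity importances to sum 1, averages, and returns the
#' descending rank.
#'
#' @param X case x feature matrix
#' @param y binary labels
#' @param n_runs number of forest fits (default 100)
#' @param seed master seed
#' @param ntree trees per forest
#' @return object of class `mdi_ranking`: `importance` (named means),
#'   `rank` (feature names, best first), `n_runs`
#' @export
mdi_rank <- function(X, y, n_runs = 100L, seed = 1L, ntree = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("at least 2 classes are required")
  if (all(apply(X, 2L, stats::sd) == 0)) stop("X is constant")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  imp <- matrix(0, n_runs, ncol(X))
  for (r in seq_len(n_runs)) {
    rf <- with_seed(derive_seed(seed, r), {
      randomForest::randomForest(X, y, ntree = ntree, importance = FALSE)
    })
    gi <- rf$importance[, "MeanDecreaseGini"]
    s <- sum(gi)
    imp[r, ] <- if (s > 0) gi / s else rep(1 / ncol(X), ncol(X))
  }
  mi <- stats::setNames(colMeans(imp), colnames(X))
  structure(list(importance = mi,
                 rank = names(sort(mi, decreasing = TRUE)),
                 n_runs = n_runs),
            class = "mdi_ranking")
}

#' Fuse selected radiomics features with top-ranked deep features
#'
#' Concatenates the selected radiomics values with the top `k` deep
#' features by MDI rank; at the defaults (10 radiomics + 20 deep) the
#' result is the 1 x 30 hybrid vector.
#'
#' @param radiomics_selected named numeric vector of selected radiomics
#'   values for one case
#' @param deep_ranked named numeric vector of the case's 200 aggregated
#'   deep features
#' @param ranking an [mdi_rank()] result covering all deep features
#' @param k number of deep features to keep (default 20)
#' @return named numeric vector of length `length(radiomics_selected) + k`
#' @export
fuse <- function(radiomics_selected, deep_ranked, ranking, k = 20L) {
  if (k > length(deep_ranked)) stop("k exceeds the number of deep features")
  if (!all(ranking$rank %in% names(deep_ranked))) {
    stop("ranking does not cover the deep features")
  }
  top <- ranking$rank[seq_len(k)]
  c(radiomics_selected, deep_ranked[top])
}

# ---- six classifiers -------------------------------------------------------

# Hand-written SAMME AdaBoost over depth-1 rpart stumps.
fit_adaboost <- function(X, y, n_rounds = 50L, seed = 1L) {
  df <- data.frame(y = factor(y), X, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- c()
  lv <- levels(df$y)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(y ~ ., data = df, weights = w,
                          control = rpart::rpart.control(maxdepth = 1L,
                                                         cp = -1, minsplit = 2L,
                                                         xval = 0L))
      pred <- predict(fit, df, type = "class")
      err <- sum(w * (pred != df$y)) / sum(w)
      if (err >= 0.5 || err <= 1e-10) {
        if (err <= 1e-10) {
          stumps[[m]] <- fit; alphas[m] <- 10
        }
        break
      }
      a <- 0.5 * log((1 - err) / err)
      stumps[[m]] <- fit; alphas[m] <- a
      w <- w * exp(a * ifelse(pred != df$y, 1, -1))
      w <- w / sum(w)
    }
  })
  structure(list(stumps = stumps, alphas = alphas, levels = lv),
            class = "adaboost_model")
}

predict_adaboost <- function(model, X) {
  df <- as.data.frame(X, check.names = FALSE)
  f <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    f <- f + model$alphas[m] * ifelse(pred == model$levels[2L], 1, -1)
  }
  stot <- sum(abs(model$alphas))
  1 / (1 + exp(-2 * f / max(stot, 1e-12) * 5))  # squashed normalized margin
}

classifier_names <- function() c("KNN", "RF", "LR", "SVM", "MLP", "AdaBoost")

fit_one_classifier <- function(name, X, y, seed) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c("HC", "PD"))
  switch(name,
    KNN = list(kind = "KNN", X = X, y = yf, k = 5L),
    RF = list(kind = "RF",
              fit = with_seed(seed, randomForest::randomForest(
                X, yf, ntree = 100L))),
    LR = list(kind = "LR",
              fit = suppressWarnings(stats::glm(
                yf ~ ., data = data.frame(yf = yf, X, check.names = FALSE),
                family = stats::binomial()))),
    SVM = list(kind = "SVM",
               fit = with_seed(seed, e1071::svm(
                 X, yf, kernel = "radial", probability = TRUE))),
    MLP = list(kind = "MLP",
               fit = with_seed(seed, nnet::nnet(
                 X, stats::model.matrix(~ yf - 1), size = 16L, decay = 1e-3,
                 maxit = 300L, softmax = TRUE, trace = FALSE))),
    AdaBoost = list(kind = "AdaBoost",
                    fit = fit_adaboost(X, yf, n_rounds = 50L, seed = seed)))
}

#' PD probability from a fitted classifier
#'
#' @param model one element of [train_classifiers()]
#' @param X feature matrix of new cases (same columns/scaling as training)
#' @return numeric vector of P(PD)
#' @export
predict_prob <- function(model, X) {
  X <- as.matrix(X)
  switch(model$kind,
    KNN = {
      pr <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "PD", p, 1 - p)
    },
    RF = stats::predict(model$fit, X, type = "prob")[, "PD"],
    LR = {
      p <- suppressWarnings(stats::predict(
        model$fit, newdata = as.data.frame(X, check.names = FALSE),
        type = "response"))
      as.numeric(p)
    },
    SVM = {
      pr <- stats::predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "PD"]
    },
    MLP = stats::predict(model$fit, X)[, "yfPD"],
    AdaBoost = predict_adaboost(model$fit, X))
}

#' Train the six classical classifiers on fused features
#'
#' Fits KNN, random forest, logistic regression, RBF SVM, a one-hidden-
#' layer MLP and AdaBoost (SAMME over stumps) on the training rows, and
#' reports case-level cross-validated accuracy per model.
#'
#' @param X standardized fused feature matrix (training cases)
#' @param y labels ("HC"/"PD")
#' @param seed master seed
#' @param n_folds CV folds for the reported validation accuracy
#' @return named list of fitted models (class `classifier_set`), with a
#'   `cv_accuracy` attribute
#' @export
train_classifiers <- function(X, y, seed = 1L, n_folds = 5L) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c("HC", "PD"))
  if (nlevels(droplevels(yf)) < 2L) stop("both classes are required")
  nms <- classifier_names()
  folds <- with_seed(derive_seed(seed, 77L), {
    sample(rep(seq_len(n_folds), length.out = nrow(X)))
  })
  cv_acc <- stats::setNames(numeric(length(nms)), nms)
  for (nm in nms) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (length(unique(yf[tr])) < 2L) next
      m <- fit_one_classifier(nm, X[tr, , drop = FALSE], yf[tr],
                              derive_seed(seed, f))
      p <- predict_prob(m, X[!tr, , drop = FALSE])
      correct <- correct + sum((p > 0.5) == (yf[!tr] == "PD"))
    }
    cv_acc[nm] <- correct / nrow(X)
  }
  models <- lapply(nms, function(nm) {
    fit_one_classifier(nm, X, yf, derive_seed(seed, 500L))
  })
  names(models) <- nms
  attr(models, "cv_accuracy") <- cv_acc
  class(models) <- "classifier_set"
  models
}
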