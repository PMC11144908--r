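#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, computed
#' from the two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n subjects and k = 2 raters.
#'
#' @param ratings_rater1,ratings_rater2 paired per-subject values
#' @return ICC value in [-1, 1]
#' @export
icc <- function(ratings_rater1, ratings_rater2) {
  if (length(ratings_rater1) != length(ratings_rater2)) {
    stop("ratings must be paired")
  }
  n <- length(ratings_rater1)
  if (n < 3L) stop("at least 3 subjects are required")
  Y <- cbind(ratings_rater1, ratings_rater2)
  k <- 2L
  grand <- mean(Y)
  if (sum((Y - grand)^2) == 0) stop("zero total variance: ICC undefined")
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Filter features by inter-rater reproducibility
#'
#' Keeps feature names whose ICC(2,1) between the two raters' feature tables
#' is strictly greater than `threshold`. Features that are constant across
#' both tables (ICC undefined) are dropped.
#'
#' @param table_r1,table_r2 numeric matrices/data.frames with identical
#'   feature columns; rows are the double-delineated subjects
#' @param threshold retention cut (default 0.8)
#' @return list with `retained` (character vector) and `icc` (named values)
#' @export
icc_filter <- function(table_r1, table_r2, threshold = 0.8) {
  X1 <- as.matrix(table_r1)
  X2 <- as.matrix(table_r2)
  if (!identical(colnames(X1), colnames(X2))) {
    stop("feature columns do not match between raters")
  }
  vals <- vapply(seq_len(ncol(X1)), function(j) {
    tryCatch(icc(X1[, j], X2[, j]), error = function(e) NA_real_)
  }, numeric(1L))
  names(vals) <- colnames(X1)
  list(retained = names(vals)[!is.na(vals) & vals > threshold], icc = vals)
}

#' LASSO feature selection (L1-penalized logistic regression)
#'
#' Fits the binomial LASSO path with \pkg{glmnet}, chooses lambda by
#' `n_folds`-fold cross-validated deviance (`lambda.min`), and returns the
#' features with nonzero coefficients at the chosen lambda. `X` is assumed
#' standardized by the caller (training statistics only); glmnet's internal
#' standardization is disabled.
#'
#' @param X standardized feature matrix (rows = cases)
#' @param y binary labels (two classes)
#' @param n_folds CV folds (default 5)
#' @param seed fold-assignment seed
#' @param max_features optional cap: keep at most this many features, by
#'   absolute coefficient (default `Inf`, i.e. off)
#' @return list with `selected`, `coefficients`, `lambda`, `lambda_path`,
#'   `nonzero_path`
#' @export
lasso_select <- function(X, y, n_folds = 5L, seed = 1L, max_features = Inf) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain NA")
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  with_seed(seed, {
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                            nfolds = n_folds, standardize = FALSE)
    co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
    sel <- names(co)[co != 0]
    if (is.finite(max_features) && length(sel) > max_features) {
      sel <- names(sort(abs(co[sel]), decreasing = TRUE))[seq_len(max_features)]
    }
    nz <- cv$nzero
    list(selected = sel,
         coefficients = co[sel],
         lambda = cv$lambda.min,
         lambda_path = cv$lambda,
         nonzero_path = as.integer(nz))
  })
}

#' Run the full selection stage (ICC filter then LASSO)
#'
#' @param features feature data.frame from [extract_cohort()] (rater 1)
#' @param features_r2 rater-2 table for the double-delineated subset
#'   (matched by case_id)
#' @param labels named or positional binary labels for `features` rows
#' @param icc_threshold ICC retention cut
#' @param n_folds,seed passed to [lasso_select()]
#' @param max_features optional cap on the number of selected features
#' @return list with `icc`, `retained_after_icc`, `selected_features`,
#'   `scaler`, `lasso`
#' @export
select_features <- function(features, features_r2, labels,
                            icc_threshold = 0.8, n_folds = 5L, seed = 1L,
                            max_features = Inf) {
  fcols <- setdiff(colnames(features), c("case_id", "label"))
  common <- intersect(features$case_id, features_r2$case_id)
  f1 <- features[match(common, features$case_id), fcols, drop = FALSE]
  f2 <- features_r2[match(common, features_r2$case_id), fcols, drop = FALSE]
  icf <- icc_filter(f1, f2, icc_threshold)
  kept <- icf$retained
  if (length(kept) == 0L) stop("no feature passed the ICC filter")
  scaler <- fit_scaler(features[, kept, drop = FALSE])
  Xs <- apply_scaler(scaler, features[, kept, drop = FALSE])
  las <- lasso_select(Xs, labels, n_folds = n_folds, seed = seed,
                      max_features = max_features)
  list(icc = icf$icc, retained_after_icc = kept,
       selected_features = las$selected, scaler = scaler, lasso = las)
}
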