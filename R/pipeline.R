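#' Pipeline configuration
#'
#' Defaults mirror the study conditions: a 65 HC / 73 PD cohort split 8:2
#' at case level, 30 double-delineated cases for the ICC filter, five-fold
#' cross-validation, and 10 + 20 hybrid fusion. Every random stage draws an
#' explicit seed derived from `seed`.
#'
#' @param n_hc,n_pd cohort sizes
#' @param split_ratio training-validation fraction (case-level, stratified)
#' @param n_icc_cases cases delineated by the second rater
#' @param phantom a [phantom_params()]
#' @param extraction an [extraction_config()]
#' @param cnn_epochs,cnn_folds,cnn_lr,cnn_batch CNN training settings
#' @param k_deep deep features fused (default 20)
#' @param max_radiomics optional cap on selected radiomics features
#' @param mdi_runs random-forest repetitions for the MDI ranking
#' @param use_trained_detector train the centre regressor instead of the
#'   heuristic fallback
#' @param seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_hc = 65L, n_pd = 73L, split_ratio = 0.8,
                            n_icc_cases = 30L,
                            phantom = phantom_params(),
                            extraction = extraction_config(),
                            cnn_epochs = 15L, cnn_folds = 5L,
                            cnn_lr = 1e-3, cnn_batch = 32L,
                            k_deep = 20L, max_radiomics = Inf,
                            mdi_runs = 100L,
                            use_trained_detector = FALSE,
                            seed = 1L) {
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must be in (0,1)")
  structure(list(n_hc = n_hc, n_pd = n_pd, split_ratio = split_ratio,
                 n_icc_cases = n_icc_cases, phantom = phantom,
                 extraction = extraction, cnn_epochs = cnn_epochs,
                 cnn_folds = cnn_folds, cnn_lr = cnn_lr,
                 cnn_batch = cnn_batch, k_deep = k_deep,
                 max_radiomics = max_radiomics, mdi_runs = mdi_runs,
                 use_trained_detector = use_trained_detector, seed = seed),
            class = "pipeline_config")
}

#' Stratified case-level train/test split
#'
#' Each class contributes `floor((1 - ratio) * n_class)` test cases, which
#' reproduces the 111/27 split of a 65/73 cohort at ratio 0.8.
#'
#' @param labels case labels
#' @param ratio training fraction (default 0.8)
#' @param seed shuffle seed
#' @return list with integer `train` and `test` index vectors
#' @export
split_cases <- function(labels, ratio = 0.8, seed = 1L) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("at least 2 cases are required")
  tab <- table(labels)
  if (any(tab < 2L)) stop("every class needs at least 2 cases")
  test <- integer(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_test <- floor((1 - ratio) * length(idx) + 1e-9)
      if (n_test > 0L) test <- c(test, sample(idx, n_test))
    }
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# setMag + patch stack per case.
build_stacks <- function(cases, detector = NULL) {
  lapply(cases, function(cs) {
    vol <- reconstruct_setmag(cs$echoes)
    zs <- select_slices(cs$snpc_mask, dim(vol$intensity)[3L])
    detect_brainstem(vol, zs, model = detector, case_id = cs$case_id)
  })
}

metrics_row <- function(feature_set, model_name, pred_label, prob, truth,
                        seed = 1L, n_boot = 500L) {
  cm <- confusion_metrics(pred_label, truth)
  au <- roc_auc(prob, truth, n_boot = n_boot, seed = seed)
  data.frame(feature = feature_set, model = model_name, ACC = cm$ACC,
             SEN = cm$SEN, SPE = cm$SPE, PPV = cm$PPV, NPV = cm$NPV,
             F1 = cm$F1, AUC = au$auc, AUC_lo = au$ci_lower,
             AUC_hi = au$ci_upper, NRI = NA_real_, NRI_p = NA_real_,
             IDI = NA_real_, IDI_p = NA_real_)
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Generates the cohort, reconstructs setMag volumes, localizes the
#' brainstem, and trains/evaluates the requested variant: `"radiomics"`
#' (ICC + LASSO + six classifiers), `"cnn"` (modified LeNet with 3-of-4
#' patient voting), or `"hybrid"` (both, plus MDI fusion and NRI/IDI
#' against the radiomics baseline). All fitted components (scalers, LASSO,
#' MDI ranking, CNN weights) see training cases only.
#'
#' @param config a [pipeline_config()]
#' @param variant pipeline variant
#' @param out_dir optional directory for the metrics CSV and manifest JSON
#' @param cases optional pre-generated cohort (bypasses generation)
#' @return list with `report` (Table-style data.frame), `fit` (frozen
#'   models for external validation), `split`, `manifest`, `predictions`
#' @export
run_pipeline <- function(config = pipeline_config(),
                         variant = c("hybrid", "radiomics", "cnn"),
                         out_dir = NULL, cases = NULL) {
  variant <- match.arg(variant)
  t0 <- Sys.time()
  stage_times <- c()
  manifest <- list(config_checksum = object_checksum(unclass(config)),
                   variant = variant, stages = list())
  tick <- function(name, start) {
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), start,
                                                units = "secs"))
  }

  st <- Sys.time()
  if (is.null(cases)) {
    cases <- generate_cohort(config$n_hc, config$n_pd, config$phantom,
                             seed = derive_seed(config$seed, 1L))
  }
  labels <- vapply(cases, `[[`, "", "label")
  manifest$stages$simulate <- list(n_cases = length(cases),
                                   checksum = object_checksum(labels))
  tick("simulate", st)

  st <- Sys.time()
  split <- split_cases(labels, config$split_ratio,
                       seed = derive_seed(config$seed, 2L))
  tick("split", st)

  st <- Sys.time()
  detector <- NULL
  if (config$use_trained_detector) {
    detector <- train_detector(cases[split$train],
                               seed = derive_seed(config$seed, 3L))
  }
  stacks <- build_stacks(cases, detector)
  manifest$stages$detect <- list(checksum = object_checksum(
    lapply(stacks, function(s) dim(s$patches))))
  tick("detect", st)

  truth_test <- as.integer(labels[split$test] == "PD")
  report <- list()
  predictions <- list()
  fit <- list(config = config, detector = detector)

  need_radiomics <- variant %in% c("radiomics", "hybrid")
  need_cnn <- variant %in% c("cnn", "hybrid")

  if (need_radiomics) {
    st <- Sys.time()
    feats <- extract_cohort(cases, config$extraction)
    icc_ids <- split$train[seq_len(min(config$n_icc_cases,
                                       length(split$train)))]
    feats_r2 <- extract_cohort(cases[icc_ids], config$extraction,
                               rater = "rater2")
    tick("extract", st)
    manifest$stages$extract <- list(
      n_features = ncol(feats) - 2L,
      checksum = object_checksum(colnames(feats)))

    st <- Sys.time()
    ftr <- feats[split$train, , drop = FALSE]
    sel <- select_features(ftr, feats_r2, labels[split$train],
                           n_folds = 5L, seed = derive_seed(config$seed, 4L),
                           max_features = config$max_radiomics)
    fit$selection <- sel
    Xtr <- apply_scaler(sel$scaler,
                        ftr[, sel$retained_after_icc, drop = FALSE])
    Xte <- apply_scaler(sel$scaler,
                        feats[split$test, sel$retained_after_icc,
                              drop = FALSE])
    Xtr_sel <- Xtr[, sel$selected_features, drop = FALSE]
    Xte_sel <- Xte[, sel$selected_features, drop = FALSE]
    tick("select", st)
    manifest$stages$select <- list(
      n_selected = length(sel$selected_features),
      checksum = object_checksum(sel$selected_features))

    st <- Sys.time()
    rad_models <- train_classifiers(Xtr_sel, labels[split$train],
                                    seed = derive_seed(config$seed, 5L))
    fit$radiomics_models <- rad_models
    for (nm in classifier_names()) {
      p <- predict_prob(rad_models[[nm]], Xte_sel)
      predictions[[paste0("radiomics_", nm)]] <- p
      report[[paste0("radiomics_", nm)]] <-
        metrics_row("Radiomics", nm, p > 0.5, p, truth_test,
                    seed = derive_seed(config$seed, 6L))
    }
    tick("fit_radiomics", st)
  }

  if (need_cnn) {
    st <- Sys.time()
    bundle <- train_cnn(stacks[split$train], labels[split$train],
                        n_folds = config$cnn_folds,
                        seed = derive_seed(config$seed, 7L),
                        epochs = config$cnn_epochs, lr = config$cnn_lr,
                        batch_size = config$cnn_batch)
    fit$cnn <- bundle
    cnn_pat <- vapply(split$test, function(i) {
      pp <- patient_prediction(predict_stack(bundle, stacks[[i]]))
      c(pp$patient_label, pp$patient_prob)
    }, numeric(2L))
    predictions$cnn <- cnn_pat[2L, ]
    report$cnn <- metrics_row("Deep", "CNN", cnn_pat[1L, ] == 1,
                              cnn_pat[2L, ], truth_test,
                              seed = derive_seed(config$seed, 8L))
    tick("train_cnn", st)
    manifest$stages$train_cnn <- list(best_epoch = bundle$best_epoch,
                                      checksum = object_checksum(bundle$folds))
  }

  if (variant == "hybrid") {
    st <- Sys.time()
    deep_all <- t(vapply(stacks, function(s) {
      aggregate_case_features(extract_deep_features(fit$cnn, s))
    }, numeric(200L)))
    deep_scaler <- fit_scaler(deep_all[split$train, , drop = FALSE])
    deep_std <- apply_scaler(deep_scaler, deep_all)
    ranking <- mdi_rank(deep_std[split$train, , drop = FALSE],
                        labels[split$train], n_runs = config$mdi_runs,
                        seed = derive_seed(config$seed, 9L))
    fit$deep_scaler <- deep_scaler
    fit$mdi_ranking <- ranking
    top <- ranking$rank[seq_len(config$k_deep)]
    Xtr_h <- cbind(Xtr_sel, deep_std[split$train, top, drop = FALSE])
    Xte_h <- cbind(Xte_sel, deep_std[split$test, top, drop = FALSE])
    hyb_models <- train_classifiers(Xtr_h, labels[split$train],
                                    seed = derive_seed(config$seed, 11L))
    fit$hybrid_models <- hyb_models
    for (nm in classifier_names()) {
      p <- predict_prob(hyb_models[[nm]], Xte_h)
      predictions[[paste0("hybrid_", nm)]] <- p
      row <- metrics_row("Hybrid", nm, p > 0.5, p, truth_test,
                         seed = derive_seed(config$seed, 12L))
      p_old <- predictions[[paste0("radiomics_", nm)]]
      nr <- nri(p_old, p, truth_test)
      id <- idi(p_old, p, truth_test)
      row$NRI <- nr$nri; row$NRI_p <- nr$p_value
      row$IDI <- id$idi; row$IDI_p <- id$p_value
      report[[paste0("hybrid_", nm)]] <- row
    }
    tick("fuse_fit", st)
    manifest$stages$fuse <- list(k_deep = config$k_deep,
                                 checksum = object_checksum(top))
  }

  report_df <- do.call(rbind, report)
  rownames(report_df) <- NULL
  manifest$stage_seconds <- as.list(stage_times)
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report_df, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(report = report_df, fit = fit, split = split, manifest = manifest,
       predictions = predictions, labels = labels)
}

#' Evaluate frozen models on an external cohort
#'
#' Applies the fitted radiomics SVM, CNN, and hybrid SVM of a
#' [run_pipeline()] result to a new cohort without refitting anything.
#'
#' @param result a `run_pipeline(variant = "hybrid")` result
#' @param cases external cohort (list of `synthetic_case`)
#' @param model classifier to report for the radiomics/hybrid paths
#' @return data.frame shaped like the per-model report
#' @export
evaluate_external <- function(result, cases, model = "SVM") {
  fit <- result$fit
  labels <- vapply(cases, `[[`, "", "label")
  truth <- as.integer(labels == "PD")
  stacks <- build_stacks(cases, fit$detector)
  feats <- extract_cohort(cases, fit$config$extraction)
  X <- apply_scaler(fit$selection$scaler,
                    feats[, fit$selection$retained_after_icc, drop = FALSE])
  Xs <- X[, fit$selection$selected_features, drop = FALSE]
  p_rad <- predict_prob(fit$radiomics_models[[model]], Xs)
  cnn_pat <- vapply(stacks, function(s) {
    pp <- patient_prediction(predict_stack(fit$cnn, s))
    c(pp$patient_label, pp$patient_prob)
  }, numeric(2L))
  deep_all <- t(vapply(stacks, function(s) {
    aggregate_case_features(extract_deep_features(fit$cnn, s))
  }, numeric(200L)))
  deep_std <- apply_scaler(fit$deep_scaler, deep_all)
  top <- fit$mdi_ranking$rank[seq_len(fit$config$k_deep)]
  Xh <- cbind(Xs, deep_std[, top, drop = FALSE])
  p_hyb <- predict_prob(fit$hybrid_models[[model]], Xh)
  rbind(
    metrics_row("Radiomics", model, p_rad > 0.5, p_rad, truth, n_boot = 0L),
    metrics_row("Deep", "CNN", cnn_pat[1L, ] == 1, cnn_pat[2L, ], truth,
                n_boot = 0L),
    metrics_row("Hybrid", model, p_hyb > 0.5, p_hyb, truth, n_boot = 0L))
}
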