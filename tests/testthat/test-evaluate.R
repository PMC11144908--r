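test_that("the 3-of-4 vote matches the 16-pattern truth table", {
  for (a in 0:1) for (b in 0:1) for (c in 0:1) for (d in 0:1) {
    pattern <- c(a, b, c, d)
    expect_identical(vote_patient(pattern),
                     as.integer(a + b + c + d >= 3L))
  }
  expect_identical(vote_patient(c(1, 1, 1, 0)), 1L)
  expect_identical(vote_patient(c(1, 1, 0, 0)), 0L)
  expect_error(vote_patient(c(1, 1, 1)), "4 image labels")
})

test_that("confusion metrics reproduce the 27-case hand table", {
  # TP=12, FN=1, TN=14, FP=0
  truth <- c(rep(1, 13), rep(0, 14))
  pred <- c(rep(1, 12), 0, rep(0, 14))
  m <- confusion_metrics(pred, truth)
  expect_equal(m$ACC, 26 / 27)
  expect_equal(m$SEN, 12 / 13)
  expect_equal(m$SPE, 1)
  expect_equal(m$PPV, 1)
  expect_equal(m$NPV, 14 / 15)
  expect_equal(m$F1, 2 * 1 * (12 / 13) / (1 + 12 / 13))
  perf <- confusion_metrics(truth, truth)
  expect_true(all(unlist(perf[c("ACC", "SEN", "SPE", "PPV", "NPV", "F1")]) == 1))
  allpd <- confusion_metrics(rep(1, 27), truth)
  expect_equal(allpd$SEN, 1)
  expect_equal(allpd$SPE, 0)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
})

test_that("rank AUC equals the exhaustive pairwise oracle", {
  truth <- c(rep(1, 8), rep(0, 12))
  perfect <- c(seq(2, 3, length.out = 8), seq(0, 1, length.out = 12))
  expect_equal(roc_auc(perfect, truth, n_boot = 0)$auc, 1)
  set.seed(24)
  for (i in 1:10) {
    sc <- round(rnorm(20), 1)  # rounding forces ties
    expect_equal(roc_auc(sc, truth, n_boot = 0)$auc,
                 oracle_auc_pairs(sc, truth))
  }
  set.seed(25)
  t2 <- rep(c(0, 1), 100)
  s2 <- rnorm(200)
  expect_lt(abs(roc_auc(s2, t2, n_boot = 0)$auc - 0.5), 0.08)
  ci <- roc_auc(perfect, truth, n_boot = 200, seed = 1)
  expect_lte(ci$ci_lower, ci$auc)
  expect_gte(ci$ci_upper, ci$auc)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  truth <- rep(c(0, 1), 25)
  sc <- rnorm(50) + truth
  ours <- roc_auc(sc, truth, n_boot = 0)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, sc, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("NRI matches the 8-subject hand count and is antisymmetric", {
  p_old <- rep(0.5, 8)
  # events: 3 up, 1 down; nonevents: 1 up, 3 down
  p_new <- c(0.6, 0.7, 0.8, 0.4, 0.6, 0.4, 0.3, 0.2)
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0)
  r <- nri(p_old, p_new, truth)
  expect_equal(r$nri, 1.0)
  same <- nri(p_old, p_old, truth)
  expect_equal(same$nri, 0)
  expect_equal(same$p_value, 1)
  expect_equal(nri(p_new, p_old, truth)$nri, -r$nri)
})

test_that("IDI matches hand arithmetic and is antisymmetric", {
  truth <- c(rep(1, 5), rep(0, 5))
  p_old <- c(rep(0.6, 5), rep(0.4, 5))
  p_new <- c(rep(0.8, 5), rep(0.3, 5))
  r <- idi(p_old, p_new, truth)
  expect_equal(r$idi, 0.3)
  expect_equal(idi(p_old, p_old, truth)$idi, 0)
  expect_equal(idi(p_new, p_old, truth)$idi, -0.3)
})

test_that("Dice matches hand arithmetic and its invariants", {
  a <- array(FALSE, c(3, 3, 2)); b <- a
  a[1:4] <- TRUE
  b[3:8] <- TRUE  # |A|=4, |B|=6, overlap {3,4} = 2 -> adjust to 3
  b2 <- array(FALSE, c(3, 3, 2)); b2[c(2, 3, 4, 10, 11, 12)] <- TRUE
  expect_equal(dice(a, b2), 2 * 3 / (4 + 6))
  expect_equal(dice(a, a), 1)
  disj <- array(FALSE, c(3, 3, 2)); disj[15:18] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(a, b2), dice(b2, a))
  empty <- array(FALSE, c(3, 3, 2))
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(a, array(FALSE, c(2, 2, 2))), "shape")
})

test_that("patient predictions aggregate image probabilities", {
  pp <- patient_prediction(c(0.9, 0.8, 0.7, 0.2))
  expect_identical(pp$patient_label, 1L)
  expect_equal(pp$patient_prob, mean(c(0.9, 0.8, 0.7, 0.2)))
  pp2 <- patient_prediction(c(0.9, 0.8, 0.4, 0.2))
  expect_identical(pp2$patient_label, 0L)
  expect_error(patient_prediction(c(0.5, 0.5)), "4 image")
})
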