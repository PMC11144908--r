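#' Patient-level 3-of-4 voting rule
#'
#' A patient is called PD iff at least 3 of the 4 image-level calls are PD.
#'
#' @param image_labels exactly 4 binary labels (1/TRUE = PD)
#' @return 1 if PD, 0 otherwise
#' @export
vote_patient <- function(image_labels) {
  if (length(image_labels) != 4L) stop("exactly 4 image labels are required")
  as.integer(sum(as.logical(image_labels)) >= 3L)
}

#' Classification metrics from predicted and true labels
#'
#' Standard 2x2-table definitions; PPV/NPV/F1 fall back to 0 when their
#' denominator is empty.
#'
#' @param pred,truth binary vectors (1 = PD)
#' @return named list: ACC, SEN, SPE, PPV, NPV, F1 and the confusion counts
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  pred <- as.integer(as.logical(pred))
  truth <- as.integer(as.logical(truth))
  tp <- sum(pred == 1L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 0
  f1 <- if (!is.na(sen) && ppv + sen > 0) 2 * ppv * sen / (ppv + sen) else 0
  list(ACC = (tp + tn) / length(pred), SEN = sen, SPE = spe, PPV = ppv,
       NPV = npv, F1 = f1, TP = tp, TN = tn, FP = fp, FN = fn)
}

#' ROC area under the curve with a bootstrap confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank tie handling;
#' the CI is a stratified percentile bootstrap (resampling events and
#' non-events separately).
#'
#' @param scores numeric risk scores (higher = more PD-like)
#' @param truth binary truth (1 = PD)
#' @param n_boot bootstrap resamples (default 2000); 0 skips the CI
#' @param seed bootstrap seed
#' @param conf confidence level
#' @return list with `auc`, `ci_lower`, `ci_upper`
#' @export
roc_auc <- function(scores, truth, n_boot = 2000L, seed = 1L, conf = 0.95) {
  truth <- as.integer(as.logical(truth))
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  auc_point <- auc_rank(scores, truth)
  if (n_boot <= 0L) {
    return(list(auc = auc_point, ci_lower = NA_real_, ci_upper = NA_real_))
  }
  pos <- which(truth == 1L); neg <- which(truth == 0L)
  bs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
      auc_rank(scores[i], truth[i])
    }, numeric(1L))
  })
  a <- (1 - conf) / 2
  qs <- stats::quantile(bs, c(a, 1 - a), names = FALSE)
  list(auc = auc_point, ci_lower = qs[1L], ci_upper = qs[2L])
}

auc_rank <- function(scores, truth) {
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  r <- rank(scores)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Continuous (category-free) net reclassification improvement
#'
#' NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) - P(up|nonevent)],
#' where up/down compare the new and old probabilities and exact ties count
#' as neither. The p-value is the asymptotic z-test.
#'
#' @param p_old,p_new paired probabilities from the baseline and new model
#' @param truth binary truth (1 = event/PD)
#' @return list with `nri`, `z`, `p_value`
#' @export
nri <- function(p_old, p_new, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  up <- p_new > p_old
  dn <- p_new < p_old
  ev <- truth == 1L
  ne <- length(p_old)
  n_e <- sum(ev); n_ne <- sum(!ev)
  pu_e <- mean(up[ev]); pd_e <- mean(dn[ev])
  pu_n <- mean(up[!ev]); pd_n <- mean(dn[!ev])
  val <- (pu_e - pd_e) + (pd_n - pu_n)
  if (all(!up & !dn)) {
    return(list(nri = 0, z = 0, p_value = 1))
  }
  se <- sqrt((pu_e + pd_e - (pu_e - pd_e)^2) / n_e +
               (pu_n + pd_n - (pd_n - pu_n)^2) / n_ne)
  z <- if (se > 0) val / se else 0
  list(nri = val, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Integrated discrimination improvement
#'
#' IDI = [mean(p_new|event) - mean(p_old|event)] -
#' [mean(p_new|nonevent) - mean(p_old|nonevent)]; the p-value is a Welch
#' t-test on the per-subject probability differences between events and
#' non-events.
#'
#' @inheritParams nri
#' @return list with `idi`, `p_value`
#' @export
idi <- function(p_old, p_new, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  d <- p_new - p_old
  ev <- truth == 1L
  val <- mean(d[ev]) - mean(d[!ev])
  pv <- if (stats::sd(d[ev]) == 0 && stats::sd(d[!ev]) == 0) {
    if (val == 0) 1 else 0
  } else {
    tryCatch(stats::t.test(d[ev], d[!ev])$p.value, error = function(e) 1)
  }
  list(idi = val, p_value = pv)
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b binary arrays of the same shape
#' @return 2|A \eqn{\cap} B| / (|A| + |B|); 1 when both masks are empty
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks differ in shape")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Patient-level predictions from image-level probabilities
#'
#' @param image_probs 4 image probabilities for one case
#' @param threshold image-level decision threshold
#' @return list: `image_labels`, `patient_label` (3-of-4 vote),
#'   `patient_prob` (mean of the image probabilities)
#' @export
patient_prediction <- function(image_probs, threshold = 0.5) {
  if (length(image_probs) != 4L) stop("exactly 4 image probabilities required")
  il <- as.integer(image_probs > threshold)
  list(image_labels = il, patient_label = vote_patient(il),
       patient_prob = mean(image_probs))
}
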