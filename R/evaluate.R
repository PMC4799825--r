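# ROC/AUC evaluation: trapezoidal ROC over all score thresholds,
# Hanley-McNeil standard error, AUC comparison z-test, Youden-index
# operating cutoff, confusion-matrix performance, and the noise-factor
# (k) robustness sweep.

pos_neg <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (symptomatic) or 1 (nonsymptomatic)",
         call. = FALSE)
  pos <- labels == 0L   # positive class = symptomatic
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  list(pos = scores[pos], neg = scores[!pos])
}

#' ROC curve, AUC and operating point
#'
#' Sweeps every distinct score as a threshold (symptomatic predicted
#' iff score >= threshold), computes sensitivity/specificity per
#' threshold, the trapezoidal AUC — which equals the Mann-Whitney
#' probability of correctly ranking a random symptomatic/nonsymptomatic
#' pair, ties counted one half — its Hanley-McNeil standard error, the
#' Youden-index cutoff and the performance at that cutoff.
#'
#' @param scores Numeric scores (probability of symptomatic).
#' @param labels 0/1 labels, study encoding: 0 = symptomatic (the
#'   positive class).
#' @return An object of class `hd_roc`: `thresholds` (descending),
#'   `sensitivity`, `specificity`, `auc`, `auc_se`, `youden_cutoff`,
#'   `accuracy`, `sens_at_cutoff`, `spec_at_cutoff` (percent),
#'   `n_pos`, `n_neg`.
#' @export
roc_and_auc <- function(scores, labels) {
  pn <- pos_neg(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pn$pos >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(pn$neg >= t), numeric(1))
  sens <- tp / length(pn$pos)
  spec <- 1 - fp / length(pn$neg)
  # trapezoid over (FPR, TPR), anchored at (0,0) and (1,1)
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # Youden index maximised on integer counts so exact ties break toward
  # the higher threshold (fewer alarms), immune to rounding noise
  j_exact <- tp * length(pn$neg) - fp * length(pn$pos)
  cutoff <- thr[which.max(j_exact)]
  perf <- performance_at(scores, labels, cutoff)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 auc_se = auc_standard_error(auc, length(pn$pos),
                                             length(pn$neg)),
                 youden_cutoff = cutoff,
                 accuracy = perf[["accuracy"]],
                 sens_at_cutoff = perf[["sensitivity"]],
                 spec_at_cutoff = perf[["specificity"]],
                 n_pos = length(pn$pos), n_neg = length(pn$neg)),
            class = "hd_roc")
}

#' @export
print.hd_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f +/- %.3f (%d symptomatic / %d nonsymptomatic)\n",
              x$auc, x$auc_se, x$n_pos, x$n_neg))
  cat(sprintf(
    "Youden cutoff %.3f: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
    x$youden_cutoff, x$accuracy, x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form SE of a trapezoidal AUC from the class counts, with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param auc AUC in \[0, 1\].
#' @param n_pos,n_neg Positive/negative class counts, >= 1.
#' @return Standard error.
#' @export
auc_standard_error <- function(auc, n_pos, n_neg) {
  assert_scalar_num(auc, "auc")
  if (auc < 0 || auc > 1) stop("`auc` must lie in [0, 1]", call. = FALSE)
  assert_scalar_num(n_pos, "n_pos", positive = TRUE)
  assert_scalar_num(n_neg, "n_neg", positive = TRUE)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Bootstrap standard error of an AUC (cross-check utility)
#'
#' @param scores,labels As in [roc_and_auc()].
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return Standard deviation of the bootstrap AUC distribution.
#' @export
auc_bootstrap_se <- function(scores, labels, n_boot = 500, seed = 1) {
  labels <- as.integer(labels)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample(length(scores), replace = TRUE)
      while (length(unique(labels[idx])) < 2L)
        idx <- sample(length(scores), replace = TRUE)
      roc_and_auc(scores[idx], labels[idx])$auc
    }, numeric(1))
    stats::sd(reps)
  })
}

#' z-test comparing two AUCs
#'
#' Unpaired normal comparison: `z = (auc1 - auc2) / sqrt(se1^2 + se2^2)`
#' with a two-sided p-value.
#'
#' @param auc1,auc2 AUCs.
#' @param se1,se2 Their standard errors, > 0.
#' @return A list with `z` and `p_value`.
#' @export
compare_aucs <- function(auc1, se1, auc2, se2) {
  assert_scalar_num(se1, "se1", positive = TRUE)
  assert_scalar_num(se2, "se2", positive = TRUE)
  z <- (auc1 - auc2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Youden-index operating cutoff
#'
#' The threshold maximising `sensitivity + specificity - 1`; ties are
#' broken toward the higher threshold (fewer alarms).
#'
#' @param roc An `hd_roc` object.
#' @return The cutoff score.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "hd_roc"))
  roc$youden_cutoff
}

#' Confusion-matrix performance at a cutoff
#'
#' Predicts symptomatic iff score >= cutoff (ties toward alarm, which
#' favours sensitivity).
#'
#' @param scores,labels As in [roc_and_auc()].
#' @param cutoff Score threshold.
#' @return Named numeric vector `accuracy`, `sensitivity`,
#'   `specificity`, all in percent.
#' @export
performance_at <- function(scores, labels, cutoff) {
  pn <- pos_neg(scores, labels)
  tp <- sum(pn$pos >= cutoff)
  tn <- sum(pn$neg < cutoff)
  c(accuracy = 100 * (tp + tn) / (length(pn$pos) + length(pn$neg)),
    sensitivity = 100 * tp / length(pn$pos),
    specificity = 100 * tn / length(pn$neg))
}

#' Noise-factor robustness sweep
#'
#' Reruns the full leave-one-out evaluation for each oversampling noise
#' factor `k` and tabulates the AUC and its Hanley-McNeil SE per stage
#' (and for the fused score). Supports the stability claim that the
#' classification performance is insensitive to `k`.
#'
#' @param cohort An `hd_cohort` of real sessions.
#' @param k_values Positive noise factors to evaluate.
#' @param rf_cfg An [rf_config()].
#' @param seed Master seed, shared across `k` values.
#' @return A data frame: `k`, `stage` (`rf1`, `rf2`, `fused`), `auc`,
#'   `auc_se`, `n_pos`, `n_neg`.
#' @export
k_sweep <- function(cohort, k_values, rf_cfg = rf_config(), seed = 1) {
  if (any(!is.finite(k_values)) || any(k_values <= 0))
    stop("all `k_values` must be > 0", call. = FALSE)
  rows <- lapply(k_values, function(k) {
    sc <- loocv_scores(cohort, rf_cfg, k = k, seed = seed)
    do.call(rbind, lapply(c("rf1", "rf2", "fused"), function(st) {
      lab <- if (st == "rf2") sc$label_rf2 else sc$label_rf1
      score <- sc[[paste0("score_", if (st == "fused") "fused" else st)]]
      roc <- roc_and_auc(score, lab)
      data.frame(k = k, stage = st, auc = roc$auc, auc_se = roc$auc_se,
                 n_pos = roc$n_pos, n_neg = roc$n_neg,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
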