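test_that("trapezoidal AUC equals the pairwise-ranking oracle", {
  set.seed(61)
  for (i in 1:200) {
    inst <- random_roc_instance()
    roc <- roc_and_auc(inst$scores, inst$labels)
    expect_equal(roc$auc, oracle_auc(inst$scores, inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals exhaustive search", {
  set.seed(62)
  for (i in 1:200) {
    inst <- random_roc_instance()
    roc <- roc_and_auc(inst$scores, inst$labels)
    expect_identical(youden_cutoff(roc),
                     oracle_youden(inst$scores, inst$labels))
  }
})

test_that("ROC endpoints and degenerate cases behave", {
  lab <- c(0L, 0L, 1L, 1L)
  perfect <- roc_and_auc(c(0.9, 0.8, 0.2, 0.1), lab)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sens_at_cutoff, 100)
  expect_equal(perfect$spec_at_cutoff, 100)
  # perfect separation: the highest zero-error threshold is returned
  expect_equal(perfect$youden_cutoff, 0.8)
  flat <- roc_and_auc(rep(0.4, 4), lab)      # uninformative scorer
  expect_equal(flat$auc, 0.5)
  expect_equal(max(flat$sensitivity + flat$specificity - 1), 0)
  expect_error(roc_and_auc(1:4, rep(0L, 4)), "both classes")
  expect_error(roc_and_auc(1:4, c(2L, 0L, 1L, 1L)), "labels")
})

test_that("null scores give chance AUC; score negation flips it", {
  set.seed(63)
  scores <- runif(2000)
  labels <- rep(c(0L, 1L), 1000)
  expect_equal(roc_and_auc(scores, labels)$auc, 0.5, tolerance = 0.06)
  expect_equal(roc_and_auc(scores, labels)$auc +
                 roc_and_auc(-scores, labels)$auc, 1, tolerance = 1e-12)
})

test_that("Hanley-McNeil SE is exact in closed form and sane vs bootstrap", {
  expect_equal(auc_standard_error(1, 17, 183), 0)
  # direct evaluation of the closed form at A = 0.76, 17/183
  a <- 0.76; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 16 * (q1 - a^2) + 182 * (q2 - a^2)) / (17 * 183))
  expect_equal(auc_standard_error(0.76, 17, 183), se)
  expect_error(auc_standard_error(1.2, 5, 5), "\\[0, 1\\]")
  expect_error(auc_standard_error(0.5, 0, 5), "n_pos")
  set.seed(64)
  scores <- runif(200)
  labels <- rep(c(0L, 1L), 100)
  hm <- auc_standard_error(roc_and_auc(scores, labels)$auc, 100, 100)
  bs <- auc_bootstrap_se(scores, labels, n_boot = 400, seed = 9)
  expect_lt(abs(hm - bs) / bs, 0.2)
})

test_that("AUC z-test matches the normal-tail computation", {
  eq <- compare_aucs(0.8, 0.05, 0.8, 0.05)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  near <- compare_aucs(0.76, 0.05, 0.73, 0.05)
  expect_lt(abs(near$z), 2.576)            # not significant at 1%
  expect_gt(near$p_value, 0.01)
  far <- compare_aucs(0.9, 0.01, 0.5, 0.01)
  expect_lt(far$p_value, 0.01)
  expect_equal(far$z, 0.4 / sqrt(2e-4))
  expect_error(compare_aucs(0.8, 0, 0.7, 0.05), "se1")
})

test_that("performance_at counts the confusion matrix in percent", {
  lab <- c(0L, 0L, 1L, 1L)
  perf <- performance_at(c(0.9, 0.6, 0.4, 0.1), lab, 0.5)
  expect_equal(unname(perf), c(100, 100, 100))
  # everyone flagged: perfect sensitivity, zero specificity
  all_pos <- performance_at(c(0.9, 0.6, 0.7, 0.8), lab, 0.5)
  expect_equal(unname(all_pos), c(50, 100, 0))
  # ties at the cutoff predict symptomatic (alarm-favouring)
  tied <- performance_at(c(0.5, 0.5, 0.5, 0.4), lab, 0.5)
  expect_equal(unname(tied["sensitivity"]), 100)
  expect_error(performance_at(1:3, rep(0L, 3), 0.5), "both classes")
})

test_that("accuracy lies between the class-weighted extremes", {
  set.seed(65)
  for (i in 1:50) {
    inst <- random_roc_instance()
    perf <- performance_at(inst$scores, inst$labels, runif(1))
    expect_gte(perf[["accuracy"]],
               min(perf[["sensitivity"]], perf[["specificity"]]) - 1e-9)
    expect_lte(perf[["accuracy"]],
               max(perf[["sensitivity"]], perf[["specificity"]]) + 1e-9)
  }
})

test_that("k sweep returns the per-k, per-stage AUC table", {
  coh <- simulate_cohort(small_config(seed = 10))
  tab <- k_sweep(coh, c(0.5, 1.5), rf_config(n_trees = 30), seed = 10)
  expect_equal(nrow(tab), 6L)
  expect_setequal(tab$stage, c("rf1", "rf2", "fused"))
  expect_setequal(tab$k, c(0.5, 1.5))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_error(k_sweep(coh, c(1, -1), rf_config(n_trees = 5)), "> 0")
})
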