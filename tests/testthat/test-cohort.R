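test_that("default cohort has the reference composition, exactly", {
  coh <- simulate_cohort(cohort_config(seed = 11))
  pp <- patient_profiles_default()
  expect_equal(nrow(coh), 200L)
  expect_equal(sum(coh$symptomatic), 17L)
  # per-patient allocation is a hard constraint, not a sampled one
  alloc <- tapply(coh$symptomatic, coh$patient_id, sum)
  expect_equal(as.integer(alloc[pp$patient_id]), pp$n_symptomatic_sessions)
  expect_equal(sum(coh$onset_index >= 7, na.rm = TRUE), round(14 / 17 * 17))
  expect_true(all(is.na(coh$onset_index) != coh$symptomatic))
  expect_true(all(coh$onset_index %in% c(NA, 1:8)))
  expect_false(any(coh$is_synthetic))
  vit <- as.matrix(coh[, vital_cols()])
  expect_true(all(vit > 0))
})

test_that("simulation is byte-reproducible given the seed", {
  a <- simulate_cohort(cohort_config(seed = 5))
  b <- simulate_cohort(cohort_config(seed = 5))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_config(seed = 6))
  expect_false(identical(a, c))
})

test_that("configuration errors are caught", {
  pr <- patient_profiles_default()
  pr$n_symptomatic_sessions[1] <- 25L
  expect_error(cohort_config(profiles = pr), "n_symptomatic_sessions")
  pr <- patient_profiles_default()
  pr$sbp_sd[3] <- 0
  expect_error(cohort_config(profiles = pr), "positive")
  ct <- corr_targets_default()
  ct$gain_hourly <- 1.4
  expect_error(cohort_config(corr_targets = ct), "\\[-1, 1\\]")
})

test_that("per-class target matrices reproduce every stated pairwise target", {
  ct <- corr_targets_default()
  for (cls in c("asymptomatic", "symptomatic")) {
    r <- vitals_corr_matrix(ct[[cls]], ct$weight_auto)
    expect_true(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) > 0)
    for (j in 0:8) {
      w <- paste0("weight_t", j)
      expect_equal(r[w, paste0("sbp_t", j)], ct[[cls]]$weight_sbp[j + 1])
      expect_equal(r[w, paste0("dbp_t", j)], ct[[cls]]$weight_dbp[j + 1])
      expect_equal(r[w, paste0("hr_t", j)], ct[[cls]]$weight_hr[j + 1])
      expect_equal(r[paste0("sbp_t", j), paste0("dbp_t", j)],
                   ct[[cls]]$sbp_dbp[j + 1])
      if (j > 0) expect_equal(r["weight_t0", w], ct$weight_auto)
    }
  }
})

test_that("with zero class shifts, class means agree within sampling error", {
  # homogeneous profiles: with the heterogeneous defaults the classes
  # differ through patient composition even at zero shift (the
  # symptomatic sessions sit in 5 specific patients)
  hits <- 0L; total <- 0L
  for (s in 1:30) {
    cfg <- cohort_config(profiles = homogeneous_profiles(),
                         class_shift_sbp = rep(0, 9),
                         class_shift_dbp = rep(0, 9), seed = s)
    st <- verify_cohort_stats(simulate_cohort(cfg))
    cd <- st$class_diff
    tt <- abs(cd$t[cd$param %in% c("sbp", "dbp")])
    hits <- hits + sum(tt < 3)
    total <- total + length(tt)
  }
  expect_gte(hits / total, 0.99)
})

test_that("per-patient moments converge to profile values at n = 500", {
  big <- simulate_cohort(cohort_config(sessions_per_patient = 500, seed = 2))
  pp <- patient_profiles_default()
  rel <- function(obs, tgt) abs(obs - tgt) / tgt
  wt_sd_err <- numeric(0)
  for (i in seq_len(nrow(pp))) {
    b <- big[big$patient_id == pp$patient_id[i], ]
    for (v in c("weight", "sbp", "dbp", "hr")) {
      x <- unlist(b[, vital_cols(v)])
      expect_lt(rel(mean(x), pp[[paste0(v, "_mean")]][i]), 0.05)
      if (v == "weight") {
        # the 0.99 across-grid autocorrelation leaves ~one independent
        # weight draw per session, so the per-patient SD estimate keeps
        # ~3% sampling error at n = 500; check it unbiased on average
        wt_sd_err <- c(wt_sd_err, rel(sd(x), pp$weight_sd[i]))
      } else {
        expect_lt(rel(sd(x), pp[[paste0(v, "_sd")]][i]), 0.05)
      }
    }
  }
  expect_lt(mean(wt_sd_err), 0.05)
})

test_that("recovered asymptomatic weight-DBP correlations match target signs", {
  big <- simulate_cohort(cohort_config(sessions_per_patient = 500, seed = 3))
  st <- verify_cohort_stats(big, cohort_config())
  cc <- st$correlations
  wd <- cc[cc$class == "asymptomatic" & cc$pair == "weight_dbp", ]
  expect_equal(sign(wd$r), sign(wd$target))
  expect_true(all(abs(wd$r - wd$target) < 0.2))
})

test_that("prescription couplings hold at scale", {
  big <- simulate_cohort(cohort_config(sessions_per_patient = 500, seed = 4))
  gain <- interdialytic_weight_gain(big$weight_t0, big$prev_end_weight,
                                    big$dry_weight)
  expect_equal(cor(gain, big$hourly_weight_loss), 0.48, tolerance = 0.1)
  expect_gt(cor(big$target_end_weight, big$weight_t0), 0.98)
  one <- big[big$patient_id == "sbj01", ]
  expect_gt(cor(one$weight_t0, one$weight_t8), 0.95)
})

test_that("verify_cohort_stats rejects degenerate cohorts", {
  coh <- simulate_cohort(cohort_config(seed = 1))
  expect_error(verify_cohort_stats(coh[!coh$symptomatic, ]), ">= 3")
  expect_error(verify_cohort_stats(coh[coh$symptomatic, ]), ">= 3")
  st <- verify_cohort_stats(coh)
  expect_s3_class(st, "hd_stat_report")
  expect_equal(st$n_symptomatic, 17L)
  expect_output(print(st), "17 symptomatic")
})

test_that("null-config class-difference p-values look uniform", {
  cfg <- null_config(seed = 9)
  st <- verify_cohort_stats(simulate_cohort(cfg))
  p <- st$class_diff$p_value
  expect_gte(mean(p > 0.01), 0.95)
})
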