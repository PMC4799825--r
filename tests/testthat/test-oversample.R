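test_that("pairwise correlation induction obeys its algebraic identities", {
  set.seed(21)
  u <- rnorm(500, 2, 3)   # deliberately non-standard scores
  v <- rnorm(500, -1, 0.5)
  for (rho in c(-0.8, 0, 0.3, 1)) {
    z <- correlate_pair(u, v, rho)
    expect_identical(z$v_prime, v)               # v preserved exactly
    lhs <- var(z$u_prime)
    rhs <- (1 - rho^2) * var(u) + rho^2 * var(v) +
      2 * rho * sqrt(1 - rho^2) * cov(u, v)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_equal(correlate_pair(u, v, 0)$u_prime, u)   # identity limit
  expect_equal(correlate_pair(u, v, 1)$u_prime, v)   # degenerate limit
  expect_error(correlate_pair(u, v, 1.2), "\\[-1, 1\\]")
  expect_error(correlate_pair(u, v[-1], 0.5), "length")
})

test_that("induced pair correlation converges to rho", {
  set.seed(31)
  z <- correlate_pair(rnorm(1e5), rnorm(1e5), 0.7)
  expect_equal(cor(z$u_prime, z$v_prime), 0.7, tolerance = 0.01)
})

test_that("scale_shift restores native moments, scaled by k", {
  expect_equal(scale_shift(rep(0, 5), mu = 120, sigma = 10), rep(120, 5))
  set.seed(41)
  z <- rnorm(1e5)
  expect_equal(sd(scale_shift(z, 120, 10, k = 1)), 10, tolerance = 0.02)
  expect_equal(sd(scale_shift(z, 120, 10, k = 0.5)), 5, tolerance = 0.01)
  expect_equal(mean(scale_shift(z, 120, 10, k = 0.5)), 120, tolerance = 0.1)
  expect_error(scale_shift(z, 120, 0, 1), "sigma")
  expect_error(scale_shift(z, 120, 10, 0), "k")
})

test_that("normality screen separates normal from skewed data", {
  pass_null <- vapply(1:100, function(s) {
    set.seed(s)
    all(normality_screen(list(x = rnorm(1000)))$pass)
  }, logical(1))
  expect_gte(mean(pass_null), 0.96)
  fail_exp <- vapply(1:100, function(s) {
    set.seed(s)
    r <- suppressWarnings(normality_screen(list(x = rexp(1000))))
    !any(r$pass)
  }, logical(1))
  expect_gte(mean(fail_exp), 0.99)
  expect_error(normality_screen(list(x = rnorm(3))), "at least 5")
  expect_warning(normality_screen(list(bad = rexp(500))), "failed")
})

test_that("multivariate induction reproduces a full target matrix", {
  # random well-conditioned correlation matrix from a factor model
  set.seed(51)
  lam <- matrix(rnorm(6 * 3), 6)
  r <- cov2cor(tcrossprod(lam) + diag(0.5, 6))
  z <- matrix(rnorm(10000 * 6), ncol = 6)
  x <- induce_correlations(z, r)
  expect_lt(max(abs(cor(x) - r)), 0.02)
  # the weight-block case: start value vs every later value at 0.99
  r99 <- matrix(0.99, 9, 9); diag(r99) <- 1
  x99 <- induce_correlations(matrix(rnorm(10000 * 9), ncol = 9), r99)
  expect_lt(max(abs(cor(x99)[1, -1] - 0.99)), 0.01)
})

test_that("indefinite matrices are repaired to valid correlations", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- -0.9       # jointly infeasible triple
  expect_lt(min(eigen(r, only.values = TRUE)$values), 0)
  fixed <- nearest_corr(r)
  expect_gte(min(eigen(fixed, only.values = TRUE)$values), 1e-7)
  expect_equal(diag(fixed), rep(1, 3))
  expect_error(nearest_corr(matrix(2, 2, 2)), "\\[-1, 1\\]")
})

test_that("balance_count returns the class deficit", {
  expect_identical(balance_count(183, 17), 166L)
  expect_identical(balance_count(50, 50), 0L)
  expect_error(balance_count(10, 20), ">=")
})

test_that("oversampled sessions are flagged, fresh and reproducible", {
  coh <- simulate_cohort(cohort_config(seed = 12))
  sym <- coh[coh$symptomatic, ]
  synth <- suppressWarnings(oversample_sessions(sym, 166, k = 1, seed = 9))
  expect_equal(nrow(synth), 166L)
  expect_true(all(synth$is_synthetic))
  expect_true(all(synth$symptomatic))
  expect_length(intersect(synth$session_id, coh$session_id), 0)
  expect_true(all(synth$onset_index %in% sym$onset_index))
  again <- suppressWarnings(oversample_sessions(sym, 166, k = 1, seed = 9))
  expect_identical(synth, again)
  expect_equal(nrow(suppressWarnings(
    oversample_sessions(sym, 0, seed = 1))), 0L)
  expect_error(oversample_sessions(sym[1:2, ], 10), "at least 3")
  expect_error(oversample_sessions(coh, 10), "symptomatic sessions only")
})

test_that("oversampling recovers the estimating sample's moments", {
  coh <- simulate_cohort(cohort_config(seed = 13))
  sym <- coh[coh$symptomatic, ]
  synth <- suppressWarnings(oversample_sessions(sym, 10000, k = 1, seed = 2))
  vars <- c(vital_cols(), "dry_weight", "target_end_weight",
            "hourly_weight_loss", "prev_end_weight")
  for (v in vars) {   # expect_equal tolerance is relative
    expect_equal(mean(synth[[v]]), mean(sym[[v]]), tolerance = 0.02)
    expect_equal(sd(synth[[v]]), sd(sym[[v]]), tolerance = 0.1)
  }
  # k scales the synthetic spread
  half <- suppressWarnings(oversample_sessions(sym, 10000, k = 0.5, seed = 2))
  expect_equal(sd(half$sbp_t4) / sd(synth$sbp_t4), 0.5, tolerance = 0.05)
})
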