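# Synthetic cohort generation: stand-in for the undeposited clinical
# dataset. Sessions live on a fixed 9-point grid (T0..T8, 30-minute
# spacing); per-patient vital means/SDs, per-timepoint symptomatic
# class shifts and cross-parameter correlation targets are configurable
# and default to the reference study's printed statistics.

#' Cohort generation configuration
#'
#' @param profiles Data frame of per-patient generative parameters, as
#'   returned by [patient_profiles_default()].
#' @param sessions_per_patient Sessions simulated per patient (default
#'   20, giving a 200-session cohort for the 10 default profiles).
#' @param class_shift_sbp,class_shift_dbp Length-9 numeric vectors of
#'   symptomatic-minus-asymptomatic mean differences (mmHg) applied per
#'   timepoint to symptomatic sessions. Defaults are the study values;
#'   negative entries mean symptomatic sessions run hypotensive.
#' @param corr_targets Correlation target list as returned by
#'   [corr_targets_default()].
#' @param frac_last_hour_onsets Fraction of symptomatic sessions whose
#'   onset falls in the last treatment hour (T7/T8); default 14/17.
#' @param marginals Physiological marginals for prescription fields not
#'   constrained by the correlation analysis; see
#'   [session_marginals_default()].
#' @param seed Integer seed; simulation is byte-reproducible given it.
#' @return An object of class `hd_cohort_config`.
#' @export
cohort_config <- function(profiles = patient_profiles_default(),
                          sessions_per_patient = 20,
                          class_shift_sbp = class_shift_sbp_default(),
                          class_shift_dbp = class_shift_dbp_default(),
                          corr_targets = corr_targets_default(),
                          frac_last_hour_onsets = 14 / 17,
                          marginals = session_marginals_default(),
                          seed = 1) {
  profiles <- as.data.frame(profiles)
  need <- c("patient_id", "n_symptomatic_sessions",
            "weight_mean", "weight_sd", "sbp_mean", "sbp_sd",
            "dbp_mean", "dbp_sd", "hr_mean", "hr_sd")
  missing <- setdiff(need, names(profiles))
  if (length(missing))
    stop("`profiles` lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sds <- unlist(profiles[, c("weight_sd", "sbp_sd", "dbp_sd", "hr_sd")])
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("all profile SDs must be positive", call. = FALSE)
  assert_scalar_num(sessions_per_patient, "sessions_per_patient",
                    positive = TRUE)
  sessions_per_patient <- as.integer(sessions_per_patient)
  if (any(profiles$n_symptomatic_sessions < 0) ||
      any(profiles$n_symptomatic_sessions > sessions_per_patient))
    stop("n_symptomatic_sessions must lie in [0, sessions_per_patient] ",
         "for every patient", call. = FALSE)
  if (length(class_shift_sbp) != 9L || length(class_shift_dbp) != 9L)
    stop("class shifts must have one entry per timepoint T0..T8",
         call. = FALSE)
  cr <- unlist(corr_targets, use.names = FALSE)
  if (any(!is.finite(cr)) || any(abs(cr) > 1))
    stop("correlation targets must lie in [-1, 1]", call. = FALSE)
  if (frac_last_hour_onsets < 0 || frac_last_hour_onsets > 1)
    stop("`frac_last_hour_onsets` must lie in [0, 1]", call. = FALSE)
  structure(list(profiles = profiles,
                 sessions_per_patient = sessions_per_patient,
                 class_shift_sbp = as.numeric(class_shift_sbp),
                 class_shift_dbp = as.numeric(class_shift_dbp),
                 corr_targets = corr_targets,
                 frac_last_hour_onsets = frac_last_hour_onsets,
                 marginals = marginals,
                 seed = as.integer(seed)),
            class = "hd_cohort_config")
}

#' Target correlation matrix of the standardised vitals grid
#'
#' Assembles the 36 x 36 correlation matrix over the standardised vitals
#' (weights, SBPs, DBPs, HRs at T0..T8, canonical order) implied by the
#' per-class pairwise targets: start-weight/later-weight autocorrelation,
#' same-timepoint weight-vital correlations and same-timepoint SBP-DBP
#' coupling. The matrix is built as `L %*% t(L)` from an explicit
#' latent-factor loading, so it is positive semi-definite by
#' construction and reproduces each stated pairwise target exactly.
#'
#' @param class_targets Per-class target list (element `asymptomatic` or
#'   `symptomatic` of [corr_targets_default()]).
#' @param weight_auto Weight autocorrelation across timepoints
#'   (default 0.99).
#' @return A 36 x 36 correlation matrix with dimnames in
#'   `vital_cols()` order.
#' @export
vitals_corr_matrix <- function(class_targets, weight_auto = 0.99) {
  a <- class_targets$weight_sbp
  b <- class_targets$weight_dbp
  cc <- class_targets$weight_hr
  d <- class_targets$sbp_dbp
  stopifnot(length(a) == 9L, length(b) == 9L, length(cc) == 9L,
            length(d) == 9L, weight_auto >= 0, weight_auto <= 1)
  # Latent columns: shared weight factor F0; per-timepoint weight
  # residuals Fw_j; SBP residuals U_j (shared with DBP to hit the
  # SBP-DBP coupling); DBP-only residuals V_j; HR residuals Q_j.
  lam <- matrix(0, nrow = 36, ncol = 1 + 4 * 9)
  rownames(lam) <- vital_cols()
  f0 <- 1; fw <- 1 + 1:9; uu <- 10 + 1:9; vv <- 19 + 1:9; qq <- 28 + 1:9
  for (j in 1:9) {
    wt <- numeric(ncol(lam))
    wt[f0] <- sqrt(weight_auto)
    wt[fw[j]] <- sqrt(1 - weight_auto)
    lam[j, ] <- wt                                   # weight_t(j-1)
    s_j <- sqrt(1 - a[j]^2)
    g_j <- if (s_j > 0) (d[j] - a[j] * b[j]) / s_j else 0
    if (b[j]^2 + g_j^2 > 1) {                        # infeasible triple
      warning(sprintf(
        "correlation targets at timepoint T%d are jointly infeasible; ",
        j - 1), "SBP-DBP coupling clamped", call. = FALSE)
      g_j <- sign(g_j) * sqrt(1 - b[j]^2) * 0.999
    }
    h_j <- sqrt(max(0, 1 - b[j]^2 - g_j^2))
    lam[9 + j, ] <- a[j] * wt;  lam[9 + j, uu[j]] <- s_j          # sbp
    lam[18 + j, ] <- b[j] * wt; lam[18 + j, uu[j]] <- g_j
    lam[18 + j, vv[j]] <- h_j                                     # dbp
    lam[27 + j, ] <- cc[j] * wt
    lam[27 + j, qq[j]] <- sqrt(1 - cc[j]^2)                       # hr
  }
  r <- tcrossprod(lam)
  dimnames(r) <- list(vital_cols(), vital_cols())
  diag(r) <- 1
  r
}

#' Simulate a hemodialysis-session cohort
#'
#' Generates `sessions_per_patient` sessions per patient. Symptomatic
#' sessions are allocated exactly per profile (a hard constraint, not a
#' sampled one); `round(frac_last_hour_onsets * total)` of them get a
#' last-hour onset (T7/T8), the rest an onset uniform on T1..T6. Vitals
#' are drawn per patient as correlated normals around the profile
#' means, with the per-timepoint class shifts added to symptomatic
#' sessions' pressures; cross-parameter correlations are induced via
#' [induce_correlations()] from the per-class target matrices. Weight
#' decreases linearly by half the prescribed hourly loss per 30-minute
#' step; the interdialytic gain (start weight minus previous session's
#' final weight) and the prescribed hourly loss are coupled at the
#' configured target (default 0.48), and the end-of-session target
#' weight tracks the start weight at 0.99.
#'
#' @param config An [cohort_config()] object.
#' @return A data frame of class `hd_cohort`, one row per session:
#'   identifiers, prescription fields, `symptomatic`, `onset_index`
#'   (NA when asymptomatic), `is_synthetic = FALSE`, and the 36 vitals
#'   columns `weight_t0..t8`, `sbp_t0..t8`, `dbp_t0..t8`, `hr_t0..t8`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7))
#' nrow(coh)                 # 200
#' sum(coh$symptomatic)      # 17
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "hd_cohort_config"))
  pr <- config$profiles
  S <- config$sessions_per_patient
  np <- nrow(pr)
  n <- np * S
  mg <- config$marginals

  with_seed(config$seed, {
    # --- session skeleton, patient-major order -------------------------
    pat_idx <- rep(seq_len(np), each = S)
    symptomatic <- logical(n)
    for (p in seq_len(np)) {
      ns <- pr$n_symptomatic_sessions[p]
      if (ns > 0) {
        pick <- sample(seq_len(S), ns)
        symptomatic[(p - 1L) * S + pick] <- TRUE
      }
    }
    sym_rows <- which(symptomatic)
    n_sym <- length(sym_rows)
    onset <- rep(NA_integer_, n)
    if (n_sym > 0) {
      n_last <- round(config$frac_last_hour_onsets * n_sym)
      last_rows <- if (n_last > 0) sample(sym_rows, n_last) else integer(0)
      onset[last_rows] <- sample(7:8, n_last, replace = TRUE)
      early <- setdiff(sym_rows, last_rows)
      onset[early] <- sample(1:6, length(early), replace = TRUE)
    }

    # --- standardised vitals with per-class correlation structure ------
    x <- matrix(NA_real_, n, 36, dimnames = list(NULL, vital_cols()))
    wa <- config$corr_targets$weight_auto
    for (cls in c(FALSE, TRUE)) {
      rows <- which(symptomatic == cls)
      if (!length(rows)) next
      tgt <- if (cls) config$corr_targets$symptomatic
             else config$corr_targets$asymptomatic
      r <- vitals_corr_matrix(tgt, wa)
      z <- matrix(stats::rnorm(length(rows) * 36), ncol = 36)
      x[rows, ] <- induce_correlations(z, r)
    }

    # --- prescription fields ------------------------------------------
    gain_kg <- stats::rnorm(n, mg$gain_mean, mg$gain_sd)
    # couple the hourly prescription to the dry-weight-normalised gain
    # (the quantity the correlation target refers to), not the raw kg
    delta <- gain_kg / (pr$weight_mean[pat_idx] - mg$dry_offset)
    hz <- correlate_pair(stats::rnorm(n),
                         (delta - mean(delta)) / stats::sd(delta),
                         config$corr_targets$gain_hourly)$u_prime
    hourly <- pmax(mg$hourly_min, mg$hourly_mean + mg$hourly_sd * hz)
    tz <- correlate_pair(stats::rnorm(n), x[, "weight_t0"],
                         config$corr_targets$target_start)$u_prime

    # --- native units ---------------------------------------------------
    # The profile weight SD describes total across-grid dispersion, so
    # the stochastic part is deflated by the variance the deterministic
    # intra-session trend (half the hourly loss per 30-min step) adds.
    wm <- pr$weight_mean[pat_idx]; ws <- pr$weight_sd[pat_idx]
    jj <- 0:8
    trend_var <- mean(((2 - jj / 2) * mg$hourly_mean)^2) +
      mean((jj / 2)^2) * mg$hourly_sd^2
    ws_noise <- sqrt(pmax(ws^2 - trend_var, (0.5 * ws)^2))
    weight <- matrix(NA_real_, n, 9)
    for (j in 0:8)    # linear fluid removal: half the hourly loss per step
      weight[, j + 1] <- wm + 2 * mg$hourly_mean - j * hourly / 2 +
        ws_noise * x[, paste0("weight_t", j)]
    sbp <- dbp <- hr <- matrix(NA_real_, n, 9)
    for (j in 0:8) {
      sh_s <- ifelse(symptomatic, config$class_shift_sbp[j + 1], 0)
      sh_d <- ifelse(symptomatic, config$class_shift_dbp[j + 1], 0)
      sbp[, j + 1] <- pr$sbp_mean[pat_idx] + sh_s +
        pr$sbp_sd[pat_idx] * x[, paste0("sbp_t", j)]
      dbp[, j + 1] <- pr$dbp_mean[pat_idx] + sh_d +
        pr$dbp_sd[pat_idx] * x[, paste0("dbp_t", j)]
      hr[, j + 1] <- pr$hr_mean[pat_idx] +
        pr$hr_sd[pat_idx] * x[, paste0("hr_t", j)]
    }
    colnames(weight) <- paste0("weight_t", 0:8)
    colnames(sbp) <- paste0("sbp_t", 0:8)
    colnames(dbp) <- paste0("dbp_t", 0:8)
    colnames(hr) <- paste0("hr_t", 0:8)

    cohort <- data.frame(
      patient_id = pr$patient_id[pat_idx],
      session_id = sprintf("%s_s%03d", pr$patient_id[pat_idx],
                           rep(seq_len(S), np)),
      dry_weight = wm - mg$dry_offset,
      target_end_weight = wm - 2 * mg$hourly_mean + ws_noise * tz,
      hourly_weight_loss = hourly,
      prev_end_weight = weight[, 1] - gain_kg,
      symptomatic = symptomatic,
      onset_index = onset,
      is_synthetic = FALSE,
      stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, weight, sbp, dbp, hr)
    class(cohort) <- c("hd_cohort", "data.frame")
    cohort
  })
}

#' Recompute the cohort's class-difference and correlation statistics
#'
#' The verification counterpart of the generator: two-sample t-tests of
#' the symptomatic/asymptomatic mean differences of SBP, DBP, HR and
#' per-step weight loss at every timepoint, and per-class
#' Bravais-Pearson correlations (with significance tests) between
#' weight and SBP/DBP/HR and between SBP and DBP at every timepoint.
#'
#' @param cohort An `hd_cohort` data frame containing both classes.
#' @param config Optional [cohort_config()]; when supplied, the
#'   configured correlation targets are attached as a `target` column.
#' @return A list of class `hd_stat_report` with elements `class_diff`
#'   (param, timepoint, mean_diff, t, p_value) and `correlations`
#'   (class, pair, timepoint, r, p_value, target), plus class counts.
#' @export
verify_cohort_stats <- function(cohort, config = NULL) {
  cohort <- as.data.frame(cohort)
  n_sym <- sum(cohort$symptomatic)
  n_asym <- sum(!cohort$symptomatic)
  if (n_sym < 3L || n_asym < 3L)
    stop(sprintf(
      "both classes need >= 3 sessions (symptomatic %d, asymptomatic %d)",
      n_sym, n_asym), call. = FALSE)
  sym <- cohort$symptomatic

  col_of <- function(param, j) cohort[[paste0(param, "_t", j)]]
  diff_row <- function(param, j, vals) {
    tt <- stats::t.test(vals[sym], vals[!sym], var.equal = TRUE)
    data.frame(param = param, timepoint = j,
               mean_diff = mean(vals[sym]) - mean(vals[!sym]),
               t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }
  cd <- list()
  for (param in c("sbp", "dbp", "hr"))
    for (j in 0:8)
      cd[[length(cd) + 1L]] <- diff_row(param, j, col_of(param, j))
  for (j in 1:8)   # per-step weight loss, attributed to the later timepoint
    cd[[length(cd) + 1L]] <- diff_row(
      "weight_loss", j, col_of("weight", j - 1) - col_of("weight", j))
  class_diff <- do.call(rbind, cd)

  tgt_of <- function(cls, pair, j) {
    if (is.null(config)) return(NA_real_)
    key <- if (cls) "symptomatic" else "asymptomatic"
    config$corr_targets[[key]][[pair]][j + 1]
  }
  cors <- list()
  pairs <- list(weight_sbp = c("weight", "sbp"),
                weight_dbp = c("weight", "dbp"),
                weight_hr  = c("weight", "hr"),
                sbp_dbp    = c("sbp", "dbp"))
  for (cls in c(FALSE, TRUE)) {
    idx <- which(sym == cls)
    for (pn in names(pairs)) {
      pq <- pairs[[pn]]
      for (j in 0:8) {
        ct <- stats::cor.test(col_of(pq[1], j)[idx], col_of(pq[2], j)[idx])
        cors[[length(cors) + 1L]] <- data.frame(
          class = if (cls) "symptomatic" else "asymptomatic",
          pair = pn, timepoint = j,
          r = unname(ct$estimate), p_value = ct$p.value,
          target = tgt_of(cls, pn, j),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(class_diff = class_diff,
                 correlations = do.call(rbind, cors),
                 n_symptomatic = n_sym, n_asymptomatic = n_asym),
            class = "hd_stat_report")
}

#' @export
print.hd_stat_report <- function(x, ...) {
  cat(sprintf("Cohort statistics: %d symptomatic / %d asymptomatic sessions\n",
              x$n_symptomatic, x$n_asymptomatic))
  sig <- x$class_diff$p_value < 0.05
  cat(sprintf("Class mean differences significant at 5%%: %d of %d tests\n",
              sum(sig), length(sig)))
  invisible(x)
}
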