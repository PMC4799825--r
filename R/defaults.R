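# Default generative parameters for the synthetic cohort: the published
# per-patient summary statistics of the ten-patient home-hemodialysis
# study the package emulates (per-patient means/SDs, symptomatic counts,
# per-timepoint class mean shifts, and cross-parameter correlations).

#' Default patient profiles
#'
#' Per-patient generative parameters of the reference ten-patient cohort:
#' across-session means and standard deviations of weight, systolic and
#' diastolic blood pressure and heart rate, plus the number of
#' symptomatic (malaise) sessions observed for each patient. Five of the
#' ten patients had symptomatic sessions, 17 in total out of 200.
#'
#' @return A data frame with one row per patient and columns
#'   `patient_id`, `age`, `sex`, `n_symptomatic_sessions`,
#'   `weight_mean`, `weight_sd`, `sbp_mean`, `sbp_sd`, `dbp_mean`,
#'   `dbp_sd`, `hr_mean`, `hr_sd`.
#' @export
#' @examples
#' pp <- patient_profiles_default()
#' sum(pp$n_symptomatic_sessions)  # 17
patient_profiles_default <- function() {
  data.frame(
    patient_id = sprintf("sbj%02d", 1:10),
    age = c(66, 65, 65, 65, 37, 47, 52, 67, 69, 68),
    sex = c("M", "M", "M", "M", "M", "M", "M", "F", "F", "F"),
    n_symptomatic_sessions = c(0L, 3L, 5L, 6L, 2L, 0L, 0L, 0L, 1L, 0L),
    weight_mean = c(80.6, 93.7, 72.1, 80.0, 60.2, 47.9, 82.7, 62.0, 61.8, 92.0),
    weight_sd   = c(3.3, 3.8, 3.1, 3.3, 3.0, 2.4, 5.2, 2.9, 2.6, 3.7),
    sbp_mean = c(143.2, 118.2, 111.9, 117.4, 109.5, 130.5, 116.4, 131.3, 151.6, 124.3),
    sbp_sd   = c(8.2, 8.3, 10.8, 9.3, 7.3, 4.7, 6.5, 7.9, 8.7, 7.9),
    dbp_mean = c(70.4, 64.6, 54.5, 65.0, 71.9, 74.5, 75.9, 82.5, 84.2, 59.5),
    dbp_sd   = c(4.2, 3.7, 6.2, 5.8, 4.9, 3.4, 4.3, 4.0, 5.6, 4.1),
    hr_mean = c(68.6, 58.1, 78.0, 67.4, 66.5, 72.8, 67.2, 69.8, 69.3, 70.3),
    hr_sd   = c(3.5, 4.1, 4.5, 5.3, 4.6, 3.3, 4.2, 3.1, 4.6, 3.8),
    stringsAsFactors = FALSE
  )
}

#' Default class mean shifts and correlation targets
#'
#' `class_shift_sbp_default()` / `class_shift_dbp_default()` return the
#' symptomatic-minus-asymptomatic mean pressure differences (mmHg) per
#' timepoint T0..T8; negative entries mean symptomatic sessions run
#' hypotensive. `corr_targets_default()` returns the cross-parameter
#' correlation targets: per class and timepoint the weight-SBP,
#' weight-DBP, weight-HR and SBP-DBP correlations, plus the
#' start-weight autocorrelation (0.99), start-weight/target-end-weight
#' coupling (0.99) and interdialytic-gain/hourly-loss coupling (0.48).
#' The SBP-DBP coupling was reported for symptomatic sessions only and
#' is reused for the asymptomatic class. `session_marginals_default()`
#' returns the physiological marginals the correlation analysis does
#' not pin down (see the methods vignette).
#'
#' @return Numeric vectors of length 9, or a nested list of targets.
#' @name cohort_defaults
NULL

#' @rdname cohort_defaults
#' @export
class_shift_sbp_default <- function() {
  c(-7.86, -9.34, -7.33, -12.53, -13.80, -16.69, -16.43, -22.70, -21.52)
}

#' @rdname cohort_defaults
#' @export
class_shift_dbp_default <- function() {
  c(-4.43, -5.92, -4.68, -6.01, -7.22, -8.80, -8.21, -12.97, -7.39)
}

#' @rdname cohort_defaults
#' @export
corr_targets_default <- function() {
  list(
    asymptomatic = list(
      weight_sbp = c(0.04, -0.11, -0.15, -0.15, -0.16, -0.22, -0.28, -0.33, -0.30),
      weight_dbp = c(-0.49, -0.45, -0.50, -0.55, -0.49, -0.45, -0.47, -0.46, -0.64),
      weight_hr  = c(-0.25, -0.29, -0.25, -0.25, -0.23, -0.29, -0.35, -0.33, -0.30),
      sbp_dbp    = c(0.76, 0.76, 0.83, 0.83, 0.84, 0.80, 0.85, 0.57, 0.70)
    ),
    symptomatic = list(
      weight_sbp = c(-0.59, -0.22, -0.22, -0.13, -0.18, -0.06, -0.31, 0.23, -0.15),
      weight_dbp = c(-0.63, -0.35, 0.13, -0.04, -0.15, -0.19, -0.16, 0.06, -0.16),
      weight_hr  = c(-0.53, -0.46, -0.47, -0.43, -0.34, -0.47, -0.54, -0.29, -0.34),
      sbp_dbp    = c(0.76, 0.76, 0.83, 0.83, 0.84, 0.80, 0.85, 0.57, 0.70)
    ),
    weight_auto  = 0.99,
    target_start = 0.99,
    gain_hourly  = 0.48
  )
}

# Interdialytic gain ~ N(2, 0.5^2) kg; prescribed hourly weight loss
# ~ 0.5 +/- 0.1 kg/h (floored at 0.1); dry weight = mean weight - 2 kg.
#' @rdname cohort_defaults
#' @export
session_marginals_default <- function() {
  list(gain_mean = 2.0, gain_sd = 0.5,
       hourly_mean = 0.5, hourly_sd = 0.1, hourly_min = 0.1,
       dry_offset = 2.0)
}

#' Canonical vitals column order
#'
#' Weights, SBPs, DBPs, HRs by timepoint. Fixed so that triangular
#' correlation induction is seed-reproducible.
#'
#' @param params Vital parameters to include.
#' @return Character vector of column names (`weight_t0` ...).
#' @export
vital_cols <- function(params = c("weight", "sbp", "dbp", "hr")) {
  as.vector(vapply(params, function(p) paste0(p, "_t", 0:8), character(9)))
}

prescription_cols <- function() {
  c("dry_weight", "target_end_weight", "hourly_weight_loss", "prev_end_weight")
}
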