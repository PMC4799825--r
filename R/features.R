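# Engineered features and label vectors for the two warning stages.
# Stage "rf1" scores the session one hour in (T0 + T2 vitals, critical
# indicators at T1/T2); stage "rf2" three hours in (T0 + T6 vitals,
# indicators at T5/T6).

stage_spec <- function(stage) {
  stage <- match.arg(tolower(stage), c("rf1", "rf2"))
  if (stage == "rf1") list(stage = "rf1", late = 2L, pp = c(1L, 2L))
  else list(stage = "rf2", late = 6L, pp = c(5L, 6L))
}

#' Interdialytic weight gain
#'
#' Fluid-driven weight gain between sessions: the difference between the
#' weight at the start of the session and the final weight of the
#' previous session, normalised by the clinician-set dry weight. A
#' dimensionless fraction; may be negative.
#'
#' @param weight_t0 Weight at session start (kg).
#' @param prev_end_weight Weight at the end of the previous session (kg).
#' @param dry_weight Dry weight (kg), must be > 0.
#' @return `(weight_t0 - prev_end_weight) / dry_weight`. Vectorised.
#' @export
#' @examples
#' interdialytic_weight_gain(80, 78, 75)  # 0.02667
interdialytic_weight_gain <- function(weight_t0, prev_end_weight, dry_weight) {
  if (any(!is.finite(dry_weight)) || any(dry_weight <= 0))
    stop("`dry_weight` must be > 0", call. = FALSE)
  (weight_t0 - prev_end_weight) / dry_weight
}

#' Critical indicator of an intradialytic systolic pressure drop
#'
#' A normalised score in \[0, 1\] flagging a systolic pressure that
#' started above 100 mmHg and is falling toward or below 90 mmHg:
#' 1 when the current SBP is at or below 90, 0 at or above 100, and
#' linearly interpolated in between. Sessions that already start at or
#' below 100 mmHg are not flagged (score 0 throughout): for them a low
#' absolute pressure is baseline, not a drop.
#'
#' @param sbp_initial SBP at session start (mmHg), > 0.
#' @param sbp_current SBP at the current timepoint (mmHg), > 0.
#' @return Score in \[0, 1\]. Vectorised with recycling.
#' @export
#' @examples
#' critical_indicator(110, 88)   # 1
#' critical_indicator(110, 95)   # 0.5
#' critical_indicator(95, 85)    # 0  (initial SBP not above 100)
critical_indicator <- function(sbp_initial, sbp_current) {
  if (any(!is.finite(sbp_initial)) || any(!is.finite(sbp_current)) ||
      any(sbp_initial <= 0) || any(sbp_current <= 0))
    stop("pressures must be positive", call. = FALSE)
  raw <- pmin(1, pmax(0, 1 - (sbp_current - 90) / 10))
  ifelse(sbp_initial <= 100, 0, raw)
}

# Last-observation-carried-forward over the vitals grid, per parameter.
# T0 must be observed; later gaps inherit the most recent value.
locf_vitals <- function(cohort) {
  for (param in c("weight", "sbp", "dbp", "hr")) {
    t0 <- cohort[[paste0(param, "_t0")]]
    if (anyNA(t0))
      stop(sprintf("missing %s at T0 for session(s): %s", param,
                   paste(cohort$session_id[is.na(t0)], collapse = ", ")),
           call. = FALSE)
    for (j in 1:8) {
      cur <- paste0(param, "_t", j)
      prev <- paste0(param, "_t", j - 1)
      nas <- is.na(cohort[[cur]])
      if (any(nas)) cohort[[cur]][nas] <- cohort[[prev]][nas]
    }
  }
  cohort
}

#' Assemble the classifier input rows for a warning stage
#'
#' Thirteen numeric features per session: the four vitals at T0 and at
#' the stage's late timepoint (T2 for `rf1`, T6 for `rf2`), the
#' prescribed hourly weight loss, the target end-of-session weight, the
#' interdialytic weight gain, and the critical indicators at the
#' stage's two indicator timepoints (T1/T2 for `rf1`, T5/T6 for `rf2`).
#' Missing non-T0 vitals are imputed by last observation carried
#' forward; a missing T0 is an error.
#'
#' @param cohort An `hd_cohort` data frame (real and/or synthetic rows).
#' @param stage `"rf1"` or `"rf2"`.
#' @return A data frame of 13 numeric columns, one row per session,
#'   with `session_id` row metadata kept as an attribute-free leading
#'   column excluded from the feature count.
#' @export
build_features <- function(cohort, stage) {
  sp <- stage_spec(stage)
  cohort <- locf_vitals(as.data.frame(cohort))
  late <- sp$late
  out <- data.frame(
    session_id = cohort$session_id,
    sbp_start = cohort$sbp_t0,
    dbp_start = cohort$dbp_t0,
    hr_start = cohort$hr_t0,
    weight_start = cohort$weight_t0,
    sbp_late = cohort[[paste0("sbp_t", late)]],
    dbp_late = cohort[[paste0("dbp_t", late)]],
    hr_late = cohort[[paste0("hr_t", late)]],
    weight_late = cohort[[paste0("weight_t", late)]],
    hourly_weight_loss = cohort$hourly_weight_loss,
    target_end_weight = cohort$target_end_weight,
    interdialytic_gain = interdialytic_weight_gain(
      cohort$weight_t0, cohort$prev_end_weight, cohort$dry_weight),
    pp_a = critical_indicator(cohort$sbp_t0,
                              cohort[[paste0("sbp_t", sp$pp[1])]]),
    pp_b = critical_indicator(cohort$sbp_t0,
                              cohort[[paste0("sbp_t", sp$pp[2])]]),
    stringsAsFactors = FALSE
  )
  out
}

feature_names <- function() {
  c("sbp_start", "dbp_start", "hr_start", "weight_start",
    "sbp_late", "dbp_late", "hr_late", "weight_late",
    "hourly_weight_loss", "target_end_weight", "interdialytic_gain",
    "pp_a", "pp_b")
}

#' Stage label vectors
#'
#' Labels use the study's encoding: 0 = symptomatic, 1 = nonsymptomatic.
#' Stage `rf1` marks every symptomatic session 0 regardless of onset;
#' stage `rf2`, which predicts a crisis in the last treatment hour,
#' marks 0 only the symptomatic sessions with onset at T7 or T8 —
#' earlier-onset crises are already past by the time of the second
#' warning and are labelled 1.
#'
#' @param cohort An `hd_cohort` data frame.
#' @param stage `"rf1"` or `"rf2"`.
#' @return Integer vector of 0/1 labels, one per session.
#' @export
build_labels <- function(cohort, stage) {
  sp <- stage_spec(stage)
  cohort <- as.data.frame(cohort)
  if (sp$stage == "rf1") {
    as.integer(!cohort$symptomatic)
  } else {
    pos <- cohort$symptomatic & !is.na(cohort$onset_index) &
      cohort$onset_index >= 7L
    as.integer(!pos)
  }
}
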