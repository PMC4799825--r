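# Session-table interchange (CSV, long form + per-session header),
# pipeline configuration and the seeded end-to-end driver.

sessions_header_cols <- function() {
  c("patient_id", "session_id", "dry_weight", "target_end_weight",
    "hourly_weight_loss", "prev_end_weight", "symptomatic", "onset_index",
    "is_synthetic")
}

#' Write a cohort as CSV
#'
#' Two files: `sessions.csv`, one row per session with identifiers,
#' prescription fields and labels; and `timepoints.csv`, long form with
#' one row per (session, timepoint): `session_id`, `timepoint` (0..8),
#' `minutes` (30 * timepoint), `sbp`, `dbp`, `hr`, `weight`.
#'
#' @param cohort An `hd_cohort` data frame.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sessions <- function(cohort, dir) {
  cohort <- as.data.frame(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort[, sessions_header_cols()],
                   file.path(dir, "sessions.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(0:8, function(j) {
    data.frame(session_id = cohort$session_id, timepoint = j,
               minutes = 30L * j,
               sbp = cohort[[paste0("sbp_t", j)]],
               dbp = cohort[[paste0("dbp_t", j)]],
               hr = cohort[[paste0("hr_t", j)]],
               weight = cohort[[paste0("weight_t", j)]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(match(long$session_id, cohort$session_id),
                     long$timepoint), ]
  utils::write.csv(long, file.path(dir, "timepoints.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_sessions()]
#'
#' Validates the schema and reassembles the wide per-session table.
#' Missing columns, non-numeric vitals and duplicate
#' (session, timepoint) pairs are errors naming the offending
#' column/rows; sessions with fewer than 9 timepoints are retained with
#' a warning and `NA` vitals at the absent timepoints (imputed
#' downstream by last observation carried forward).
#'
#' @param dir Directory holding `sessions.csv` and `timepoints.csv`.
#' @return An `hd_cohort` data frame.
#' @export
read_sessions <- function(dir) {
  spath <- file.path(dir, "sessions.csv")
  tpath <- file.path(dir, "timepoints.csv")
  for (p in c(spath, tpath))
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
  hdr <- utils::read.csv(spath, stringsAsFactors = FALSE)
  miss <- setdiff(sessions_header_cols(), names(hdr))
  if (length(miss))
    stop("sessions.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  long <- utils::read.csv(tpath, stringsAsFactors = FALSE)
  need <- c("session_id", "timepoint", "sbp", "dbp", "hr", "weight")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("timepoints.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (v in c("sbp", "dbp", "hr", "weight"))
    if (!is.numeric(long[[v]]))
      stop(sprintf("timepoints.csv column '%s' is not numeric", v),
           call. = FALSE)
  dup <- duplicated(long[, c("session_id", "timepoint")])
  if (any(dup))
    stop("duplicate (session, timepoint) rows in timepoints.csv at line(s): ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  unknown <- setdiff(long$session_id, hdr$session_id)
  if (length(unknown))
    stop("timepoints.csv references unknown session(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)

  cohort <- hdr
  cohort$symptomatic <- as.logical(cohort$symptomatic)
  cohort$is_synthetic <- as.logical(cohort$is_synthetic)
  cohort$onset_index <- suppressWarnings(as.integer(cohort$onset_index))
  for (param in c("weight", "sbp", "dbp", "hr"))
    for (j in 0:8) cohort[[paste0(param, "_t", j)]] <- NA_real_
  key <- match(long$session_id, cohort$session_id)
  for (param in c("weight", "sbp", "dbp", "hr")) {
    src <- c(weight = "weight", sbp = "sbp", dbp = "dbp", hr = "hr")[param]
    for (j in 0:8) {
      rows <- long$timepoint == j
      cohort[key[rows], paste0(param, "_t", j)] <- long[[src]][rows]
    }
  }
  counts <- table(factor(long$session_id, levels = cohort$session_id))
  short <- names(counts)[counts < 9L]
  if (length(short))
    warning("session(s) with an incomplete timepoint grid (retained, ",
            "missing vitals imputed downstream): ",
            paste(short, collapse = ", "), call. = FALSE)
  class(cohort) <- c("hd_cohort", "data.frame")
  cohort
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param oversample_k Noise proportionality factor for the balancing
#'   generator (default 1).
#' @param rf An [rf_config()].
#' @param output_dir Artifact directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An object of class `hd_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), oversample_k = 1,
                            rf = rf_config(), output_dir = tempfile("dialrisk_"),
                            seed = 1) {
  stopifnot(inherits(cohort, "hd_cohort_config"),
            inherits(rf, "hd_rf_config"))
  assert_scalar_num(oversample_k, "oversample_k", positive = TRUE)
  structure(list(cohort = cohort, oversample_k = oversample_k, rf = rf,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "hd_pipeline_config")
}

#' Run the full pipeline
#'
#' Simulate the cohort, score every session by leave-one-out
#' cross-validation with per-fold oversampling, and write the
#' artifacts: cohort CSVs, `scores.csv`, `report.csv` (AUC +/- SE,
#' Youden cutoff, accuracy, sensitivity, specificity for the two stages
#' and the fused score) and `manifest.json` (config, seeds, package
#' version). Identical manifests imply identical outputs.
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, a list with the cohort, scores, report data frame
#'   and the output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "hd_pipeline_config"))
  cfg_cohort <- config$cohort
  cfg_cohort$seed <- derive_seed(config$seed, 101L)
  message("stage simulate: ", cfg_cohort$sessions_per_patient, " sessions x ",
          nrow(cfg_cohort$profiles), " patients")
  cohort <- tryCatch(simulate_cohort(cfg_cohort),
                     error = function(e) stop("simulate: ", conditionMessage(e),
                                              call. = FALSE))
  message("stage train-eval: leave-one-out over ", nrow(cohort), " sessions")
  scores <- tryCatch(
    loocv_scores(cohort, config$rf, k = config$oversample_k,
                 seed = derive_seed(config$seed, 202L)),
    error = function(e) stop("train-eval: ", conditionMessage(e),
                             call. = FALSE))
  report <- tryCatch(score_report(scores),
                     error = function(e) stop("report: ", conditionMessage(e),
                                              call. = FALSE))
  dir <- config$output_dir
  write_sessions(cohort, dir)
  utils::write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(report, file.path(dir, "report.csv"), row.names = FALSE)
  manifest <- list(
    package = "dialrisk",
    version = as.character(utils::packageVersion("dialrisk")),
    seed = config$seed,
    oversample_k = config$oversample_k,
    rf = unclass(config$rf),
    cohort = list(sessions_per_patient = cfg_cohort$sessions_per_patient,
                  n_patients = nrow(cfg_cohort$profiles),
                  seed = cfg_cohort$seed,
                  frac_last_hour_onsets = cfg_cohort$frac_last_hour_onsets))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, scores = scores, report = report,
                 output_dir = dir))
}

#' Tabulate stage and fused performance from LOOCV scores
#'
#' @param scores An `hd_scores` data frame from [loocv_scores()].
#' @return Data frame with one row per stage (`rf1`, `rf2`, `fused`):
#'   AUC, SE, Youden cutoff and percent accuracy/sensitivity/specificity
#'   at the cutoff.
#' @export
score_report <- function(scores) {
  do.call(rbind, lapply(c("rf1", "rf2", "fused"), function(st) {
    lab <- if (st == "rf2") scores$label_rf2 else scores$label_rf1
    sc <- scores[[paste0("score_", if (st == "fused") "fused" else st)]]
    roc <- roc_and_auc(sc, lab)
    data.frame(stage = st, auc = roc$auc, auc_se = roc$auc_se,
               cutoff = roc$youden_cutoff, accuracy = roc$accuracy,
               sensitivity = roc$sens_at_cutoff,
               specificity = roc$spec_at_cutoff,
               n_pos = roc$n_pos, n_neg = roc$n_neg,
               stringsAsFactors = FALSE)
  }))
}
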