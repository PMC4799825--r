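# Shared fixtures and independent oracles. Oracles are deliberately
# brute-force and share no code with the package implementation.

# Small cohort configuration: 4 patients x 8 sessions, 4 symptomatic.
small_config <- function(seed = 1, sessions = 8) {
  pr <- patient_profiles_default()[1:4, ]
  pr$n_symptomatic_sessions <- c(2L, 1L, 1L, 0L)
  cohort_config(profiles = pr, sessions_per_patient = sessions, seed = seed)
}

# Homogeneous profiles: identical generative parameters for every
# patient, so patient composition cannot distinguish the classes.
homogeneous_profiles <- function() {
  pp <- patient_profiles_default()
  for (v in c("weight_mean", "weight_sd", "sbp_mean", "sbp_sd",
              "dbp_mean", "dbp_sd", "hr_mean", "hr_sd"))
    pp[[v]] <- mean(pp[[v]])
  pp
}

# Null-world configuration: homogeneous patients, no class shifts and a
# shared correlation structure, so the two classes are identically
# distributed. (With the heterogeneous default profiles the classes
# differ through patient composition alone: the symptomatic sessions
# sit in 5 specific patients.)
null_config <- function(seed = 1) {
  ct <- corr_targets_default()
  ct$symptomatic <- ct$asymptomatic
  cohort_config(profiles = homogeneous_profiles(),
                class_shift_sbp = rep(0, 9), class_shift_dbp = rep(0, 9),
                corr_targets = ct, seed = seed)
}

# Brute-force pairwise-ranking AUC (Mann-Whitney probability of correct
# ranking, ties counted one half). Positive class = label 0.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 0]
  neg <- scores[labels != 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden-index maximisation over all distinct scores,
# ties broken toward the higher threshold.
oracle_youden <- function(scores, labels) {
  pos <- scores[labels == 0]
  neg <- scores[labels != 0]
  thr <- sort(unique(scores), decreasing = TRUE)
  j <- vapply(thr, function(t)
    sum(pos >= t) * length(neg) - sum(neg >= t) * length(pos), numeric(1))
  thr[which.max(j)]
}

# Random small ROC instance, with ties made likely by a coarse grid.
random_roc_instance <- function() {
  n_pos <- sample(2:8, 1)
  n_neg <- sample(2:8, 1)
  scores <- sample(seq(0, 1, by = 0.125), n_pos + n_neg, replace = TRUE)
  list(scores = scores, labels = rep(c(0L, 1L), c(n_pos, n_neg)))
}
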