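# Dual Random-Forest classification with per-fold oversampling and
# score fusion. Internally the positive class is "symptomatic"; the
# study's 0/1 label encoding (0 = symptomatic) is kept at the
# interface, and scores are reported as the fraction of trees voting
# symptomatic.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Features considered per split; `NULL` (default) uses the
#'   floor of the square root of the feature count.
#' @param min_leaf Minimum observations per leaf (default 1).
#' @param seed Integer seed; training is byte-reproducible given it.
#' @return An object of class `hd_rf_config`.
#' @export
rf_config <- function(n_trees = 500, mtry = NULL, min_leaf = 1, seed = 1) {
  assert_scalar_num(n_trees, "n_trees", positive = TRUE)
  assert_scalar_num(min_leaf, "min_leaf", positive = TRUE)
  if (!is.null(mtry)) assert_scalar_num(mtry, "mtry", positive = TRUE)
  structure(list(n_trees = as.integer(n_trees),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "hd_rf_config")
}

#' Train a random forest on feature rows
#'
#' Bagged CART trees with Gini splitting and a random feature subset at
#' every node; each tree votes a class by leaf majority and the model
#' score of a row is the fraction of trees voting symptomatic.
#'
#' @param features Data frame or matrix of numeric feature columns (a
#'   `session_id` column, if present, is dropped).
#' @param labels 0/1 labels, study encoding: 0 = symptomatic.
#' @param config An [rf_config()].
#' @return An object of class `hd_rf` with a [predict.hd_rf()] method.
#' @export
train_rf <- function(features, labels, config = rf_config()) {
  stopifnot(inherits(config, "hd_rf_config"))
  x <- as.data.frame(features)
  x$session_id <- NULL
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("`labels` must have one entry per feature row", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (symptomatic) or 1 (nonsymptomatic)",
         call. = FALSE)
  y_pos <- as.integer(labels == 0L)   # positive class = symptomatic
  if (length(unique(y_pos)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(x))))
  forest <- rf_build(x, y_pos, config$n_trees, as.integer(mtry),
                     config$min_leaf, as.double(config$seed))
  structure(list(forest = forest, feature_names = colnames(x),
                 mtry = as.integer(mtry), config = config),
            class = "hd_rf")
}

#' Score sessions with a trained forest
#'
#' @param object An `hd_rf` model.
#' @param newdata Feature rows with the training columns.
#' @param ... Unused.
#' @return Numeric vector in \[0, 1\]: fraction of trees voting the
#'   symptomatic class.
#' @export
predict.hd_rf <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)
  x$session_id <- NULL
  missing <- setdiff(object$feature_names, names(x))
  if (length(missing))
    stop("`newdata` lacks feature columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- as.matrix(x[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  rf_score(object$forest, x)
}

#' Leave-one-out cross-validated stage scores
#'
#' For every real session: hold it out, rebalance the remaining
#' training set by generating synthetic symptomatic sessions with
#' [oversample_sessions()] (the oversampler's moments and correlations
#' are estimated on the fold's training symptomatic sessions only, so
#' the held-out session never leaks into training), train the early
#' (`rf1`) and late (`rf2`) stage forests on the augmented set, and
#' score the held-out session with both. The fused score is the
#' arithmetic mean of the two stage scores. Synthetic sessions are
#' never scored.
#'
#' @param cohort An `hd_cohort` of real sessions only.
#' @param rf_cfg An [rf_config()]; per-fold and per-stage seeds are
#'   derived deterministically from `seed`.
#' @param k Oversampling noise proportionality factor (default 1).
#' @param seed Master seed for fold-level derivations.
#' @param fold_hook Optional function called once per completed fold
#'   with `(held_out_id, train_ids, synth_ids)`; used by audits of the
#'   leakage guard.
#' @return A data frame of class `hd_scores`: `session_id`,
#'   `score_rf1`, `score_rf2`, `score_fused`, `label_rf1`, `label_rf2`.
#'   Degenerate folds (a stage's training classes emptied by the
#'   holdout, or fewer than 3 symptomatic sessions left to estimate
#'   the oversampler's moments) are skipped with a warning.
#' @export
loocv_scores <- function(cohort, rf_cfg = rf_config(), k = 1, seed = 1,
                         fold_hook = NULL) {
  cohort <- as.data.frame(cohort)
  if (any(cohort$is_synthetic))
    stop("`cohort` must contain real (non-synthetic) sessions only",
         call. = FALSE)
  assert_scalar_num(k, "k", positive = TRUE)
  n <- nrow(cohort)
  lab1_all <- build_labels(cohort, "rf1")
  lab2_all <- build_labels(cohort, "rf2")
  if (min(table(factor(lab1_all, levels = 0:1))) < 2L ||
      min(table(factor(lab2_all, levels = 0:1))) < 2L)
    stop("need >= 2 sessions per class under each stage's labelling",
         call. = FALSE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    train <- cohort[-i, , drop = FALSE]
    lab1 <- lab1_all[-i]
    lab2 <- lab2_all[-i]
    if (length(unique(lab1)) < 2L || length(unique(lab2)) < 2L ||
        sum(train$symptomatic) < 3L) {
      warning(sprintf("fold %d (%s): degenerate training set; skipped",
                      i, cohort$session_id[i]), call. = FALSE)
      next
    }
    fold_seed <- derive_seed(seed, i)
    n_new <- balance_count(sum(lab1 == 1L), sum(lab1 == 0L))
    synth <- oversample_sessions(train[train$symptomatic, , drop = FALSE],
                                 n_new, k = k, seed = fold_seed,
                                 screen = FALSE)
    stopifnot(!cohort$session_id[i] %in% synth$session_id,
              !cohort$session_id[i] %in% train$session_id)  # leakage guard
    if (!is.null(fold_hook))
      fold_hook(cohort$session_id[i], train$session_id, synth$session_id)
    aug <- rbind(train, synth)
    scores <- numeric(2)
    for (s in 1:2) {
      stage <- c("rf1", "rf2")[s]
      cfg <- rf_cfg
      cfg$seed <- derive_seed(fold_seed, s)
      model <- train_rf(build_features(aug, stage),
                        build_labels(aug, stage), cfg)
      scores[s] <- predict(model, build_features(cohort[i, , drop = FALSE],
                                                 stage))
    }
    out[[i]] <- data.frame(session_id = cohort$session_id[i],
                           score_rf1 = scores[1], score_rf2 = scores[2],
                           score_fused = mean(scores),
                           label_rf1 = lab1_all[i], label_rf2 = lab2_all[i],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  class(res) <- c("hd_scores", "data.frame")
  res
}
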