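# ---- study evaluation protocol ----------------------------------------------

#' Repeated random-split evaluation of the MT-MSPCNN
#'
#' Implements the repeated-holdout evaluation protocol: per repeat, `n_test` subjects
#' per class are held out as an independent test set; of the remainder,
#' `n_trainval` per class are drawn and split 7:3 (stratified) into
#' training and validation sets; the five task models are trained
#' (phase 1 + phase 2) and the fused majority vote plus each single-task
#' model are scored on the test subjects. All splits are re-drawn on every
#' repeat, and means and standard deviations over repeats are reported.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param seed RNG seed; fixed seed reproduces all metrics bit-identically.
#' @param repeats Number of repeats (default 10).
#' @param n_test Test subjects per class (default 5).
#' @param n_trainval Training+validation subjects per class (default 15).
#' @param train_frac Training share of the 7:3 split (default 0.7).
#' @param window A [window_spec()].
#' @param cfg1 Phase-1 [soft_weight_config()].
#' @param epochs2 Phase-2 epochs.
#' @param tasks Tasks to use (default all five).
#' @param task_mats Optional precomputed matrices from an earlier call
#'   (invisible attribute `task_mats` of the result), to skip
#'   re-preprocessing.
#' @return List with `summary` (mean and sd of accuracy / precision /
#'   recall / F1 per model, fused model last), `per_repeat` (long
#'   data.frame), and `predictions`. The per-subject task matrices are
#'   attached as attribute `task_mats`.
#' @export
evaluate_protocol <- function(cohort, seed = 1, repeats = 10L, n_test = 5L,
                              n_trainval = 15L, train_frac = 0.7,
                              window = window_spec(),
                              cfg1 = soft_weight_config(),
                              epochs2 = 30L,
                              tasks = setdiff(task_labels(), "NONE"),
                              task_mats = NULL) {
  set.seed(seed)
  groups <- vapply(cohort$sessions, `[[`, "", "group")
  ids_hc <- names(groups)[groups == "HC"]
  ids_cd <- names(groups)[groups == "CD"]
  if (length(ids_hc) < n_test + n_trainval || length(ids_cd) < n_test + n_trainval)
    stop("class too small for the split specification")
  if (is.null(task_mats))
    task_mats <- cohort_task_matrices(cohort, tasks = tasks)
  labels <- setNames(ifelse(groups == "CD", 1L, 0L), names(groups))

  rows <- list(); preds <- list()
  for (r in seq_len(repeats)) {
    test_ids <- c(sample(ids_hc, n_test), sample(ids_cd, n_test))
    pool_hc <- sample(setdiff(ids_hc, test_ids), n_trainval)
    pool_cd <- sample(setdiff(ids_cd, test_ids), n_trainval)
    n_tr <- ceiling(train_frac * n_trainval)
    train_ids <- c(pool_hc[seq_len(n_tr)], pool_cd[seq_len(n_tr)])
    val_ids <- c(pool_hc[-seq_len(n_tr)], pool_cd[-seq_len(n_tr)])

    fit <- mtmspcnn_train(cohort, train_ids, val_ids, tasks = tasks,
                          window = window, cfg1 = cfg1, epochs2 = epochs2,
                          task_mats = task_mats)
    y_true <- labels[test_ids]
    task_votes <- matrix(NA_real_, length(test_ids), length(tasks),
                         dimnames = list(test_ids, tasks))
    fused <- integer(length(test_ids))
    for (i in seq_along(test_ids)) {
      tm <- lapply(tasks, function(tk) task_mats[[tk]][[test_ids[i]]])
      names(tm) <- tasks
      vr <- predict_subject(fit, task_mats = tm)
      task_votes[i, ] <- vr$votes[tasks]
      fused[i] <- vr$prediction
    }
    for (tk in tasks) {
      m <- classification_metrics(y_true, task_votes[, tk])
      rows[[length(rows) + 1L]] <- data.frame(repeat_i = r, model = tk,
                                              t(m))
    }
    m <- classification_metrics(y_true, fused)
    rows[[length(rows) + 1L]] <- data.frame(repeat_i = r, model = "fused",
                                            t(m))
    preds[[r]] <- data.frame(repeat_i = r, subject_id = test_ids,
                             y_true = y_true, fused = fused, task_votes)
  }
  per_repeat <- do.call(rbind, rows)
  agg <- function(fun) aggregate(
    per_repeat[c("accuracy", "precision", "recall", "f1")],
    by = list(model = per_repeat$model), FUN = fun)
  mu <- agg(mean); sdev <- agg(sd)
  ord <- c(tasks, "fused")
  mu <- mu[match(ord, mu$model), ]
  sdev <- sdev[match(ord, sdev$model), ]
  names(sdev)[-1] <- paste0(names(sdev)[-1], "_sd")
  summary <- cbind(mu, sdev[-1])
  rownames(summary) <- NULL
  out <- list(summary = summary, per_repeat = per_repeat,
              predictions = do.call(rbind, preds))
  attr(out, "task_mats") <- task_mats
  out
}

#' @importFrom stats aggregate
NULL

#' Repeated-split evaluation of the tabular baselines
#'
#' Applies the same repeated split protocol to the 40-feature baseline
#' table: per repeat, 5+5 test subjects, 15+15 train/validation at 7:3,
#' and the three baseline classifiers fitted and scored at the subject
#' level.
#'
#' @param table Baseline table from [assemble_baseline_table()].
#' @param seed RNG seed.
#' @param repeats Number of repeats (default 10).
#' @param n_test,n_trainval,train_frac Split sizes as in
#'   [evaluate_protocol()].
#' @param models Baseline model names (default LR, GNB, SVM).
#' @return List with `summary` and `per_repeat` as in
#'   [evaluate_protocol()].
#' @export
evaluate_baselines <- function(table, seed = 1, repeats = 10L, n_test = 5L,
                               n_trainval = 15L, train_frac = 0.7,
                               models = c("LR", "GNB", "SVM")) {
  set.seed(seed)
  idx_hc <- which(table$group == "HC")
  idx_cd <- which(table$group == "CD")
  rows <- list()
  for (r in seq_len(repeats)) {
    test_idx <- c(sample(idx_hc, n_test), sample(idx_cd, n_test))
    pool_hc <- sample(setdiff(idx_hc, test_idx), n_trainval)
    pool_cd <- sample(setdiff(idx_cd, test_idx), n_trainval)
    n_tr <- ceiling(train_frac * n_trainval)
    train_idx <- c(pool_hc[seq_len(n_tr)], pool_cd[seq_len(n_tr)])
    val_idx <- c(pool_hc[-seq_len(n_tr)], pool_cd[-seq_len(n_tr)])
    for (mo in models) {
      fit <- train_baseline(baseline_spec(mo), table, train_idx, val_idx,
                            test_idx)
      rows[[length(rows) + 1L]] <- data.frame(repeat_i = r, model = mo,
                                              t(fit$metrics))
    }
  }
  per_repeat <- do.call(rbind, rows)
  mu <- aggregate(per_repeat[c("accuracy", "precision", "recall", "f1")],
                  by = list(model = per_repeat$model), FUN = mean)
  sdev <- aggregate(per_repeat[c("accuracy", "precision", "recall", "f1")],
                    by = list(model = per_repeat$model), FUN = sd)
  names(sdev)[-1] <- paste0(names(sdev)[-1], "_sd")
  list(summary = cbind(mu, sdev[-1]), per_repeat = per_repeat)
}
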