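# ---- classification metrics --------------------------------------------------

#' Binary classification metrics
#'
#' Accuracy, precision, recall (sensitivity) and F1 with the cognitive
#' decline class (1) as the positive class. Precision is 0 (with a
#' `no_positive_predictions` flag) when nothing is predicted positive.
#'
#' @param y_true,y_pred Binary vectors (0 = HC, 1 = CD).
#' @return Named numeric vector `c(accuracy, precision, recall, f1)`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  out <- c(accuracy = (tp + tn) / length(y_true), precision = prec,
           recall = rec, f1 = f1)
  if (tp + fp == 0) attr(out, "no_positive_predictions") <- TRUE
  out
}

# ---- Mann-Whitney group statistics -------------------------------------------

#' Mann-Whitney U tests over all feature columns
#'
#' Two-sided tests (normal approximation with tie correction, the standard
#' choice at n = 20 per group) of every feature column between the two
#' groups, with group medians and the direction of the CD-vs-HC median
#' difference. No multiplicity correction is applied (raw p-values are
#' reported). Results are sorted by p-value.
#'
#' @param table Data.frame containing `group` and the feature columns.
#' @param features Columns to test (default: the 27 behavioral features
#'   present in the table).
#' @param group_col Name of the group column (levels `"HC"`, `"CD"`).
#' @return Data.frame with `feature`, `U` (statistic for the CD group),
#'   `p`, `median_hc`, `median_cd`, `direction` (+1 when CD > HC).
#' @export
mannwhitney_all <- function(table, features = NULL, group_col = "group") {
  if (is.null(features))
    features <- intersect(feature_names(), names(table))
  g <- table[[group_col]]
  stopifnot(all(g %in% c("HC", "CD")))
  if (min(table(g)) < 3) stop("need at least 3 subjects per group")
  rows <- lapply(features, function(f) {
    x <- table[[f]][g == "CD"]; y <- table[[f]][g == "HC"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(unique(c(x, y))) == 1) {
      u <- length(x) * length(y) / 2; p <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
      u <- unname(wt$statistic); p <- wt$p.value
    }
    mhc <- median(y); mcd <- median(x)
    data.frame(feature = f, U = u, p = p, median_hc = mhc, median_cd = mcd,
               direction = sign(mcd - mhc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}

# ---- baseline classifiers ----------------------------------------------------

#' Baseline model specification
#'
#' The three tabular reference classifiers fit on the 40-feature table:
#' `"LR"` -- L2-penalized logistic regression with inverse regularization
#' strength 1.0; `"GNB"` -- Gaussian naive Bayes; `"SVM"` -- RBF-kernel
#' support vector machine with the `"scale"` kernel-width rule and the
#' regularization grid C in \{0.1, 0.4, 0.7, 1\} selected on validation
#' accuracy.
#'
#' @param model One of `"LR"`, `"GNB"`, `"SVM"`.
#' @param C_grid SVM regularization grid.
#' @param C Inverse L2 penalty strength of the logistic regression.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(model = c("LR", "GNB", "SVM"),
                          C_grid = c(0.1, 0.4, 0.7, 1), C = 1.0) {
  model <- match.arg(model)
  structure(list(model = model, C_grid = C_grid, C = C),
            class = "baseline_spec")
}

#' Train and evaluate one baseline classifier
#'
#' Features are standardized with training-split statistics; missing values
#' are imputed with training-split medians; constant training columns are
#' dropped with a warning. The SVM's C is chosen on the validation split
#' (the validation rows join the training set for the other models only
#' when `refit_with_val = TRUE`).
#'
#' @param spec A [baseline_spec()].
#' @param table Baseline table from [assemble_baseline_table()].
#' @param train_idx,val_idx,test_idx Row index vectors of the three splits.
#' @param features Feature columns (default the 40 baseline features).
#' @return List with `model` (fitted object), `spec`, chosen `C` (SVM),
#'   `pred` (test predictions), `metrics` (test metrics) and the columns
#'   used.
#' @export
train_baseline <- function(spec, table, train_idx, val_idx, test_idx,
                           features = baseline_feature_names()) {
  stopifnot(inherits(spec, "baseline_spec"))
  table <- impute_missing_features(table, train_idx, features)
  y <- ifelse(table$group == "CD", 1L, 0L)
  Xall <- as.matrix(table[features])
  sds <- apply(Xall[train_idx, , drop = FALSE], 2, sd)
  keep <- is.finite(sds) & sds > 1e-10
  if (any(!keep))
    warning("dropping constant feature column(s): ",
            paste(features[!keep], collapse = ", "))
  X <- Xall[, keep, drop = FALSE]
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdv <- apply(X[train_idx, , drop = FALSE], 2, sd)
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  fit_predict <- function(tr_idx, C = NULL) {
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    if (spec$model == "LR") {
      # glmnet ridge objective (1/n) * loss + lambda/2 ||w||^2 matches an
      # L2 logistic regression with inverse strength C at lambda = 1/(n C)
      fit <- glmnet::glmnet(Xtr, factor(ytr, levels = 0:1),
                            family = "binomial", alpha = 0,
                            lambda = 1 / (length(ytr) * spec$C),
                            standardize = FALSE)
      pr <- function(Xn) as.integer(
        predict(fit, Xn, type = "response")[, 1] > 0.5)
    } else if (spec$model == "GNB") {
      fit <- e1071::naiveBayes(Xtr, factor(ytr, levels = 0:1))
      pr <- function(Xn) as.integer(as.character(predict(fit, Xn)))
    } else {
      gam <- 1 / (ncol(Xtr) * max(var(as.numeric(Xtr)), 1e-12))  # "scale"
      fit <- e1071::svm(Xtr, factor(ytr, levels = 0:1), kernel = "radial",
                        gamma = gam, cost = C, scale = FALSE)
      pr <- function(Xn) as.integer(as.character(predict(fit, Xn)))
    }
    list(fit = fit, pr = pr)
  }

  chosen_C <- NA_real_
  if (spec$model == "SVM") {
    accs <- vapply(spec$C_grid, function(C) {
      m <- fit_predict(train_idx, C)
      mean(m$pr(X[val_idx, , drop = FALSE]) == y[val_idx])
    }, numeric(1))
    chosen_C <- spec$C_grid[which.max(accs)]
    m <- fit_predict(c(train_idx, val_idx), chosen_C)
  } else {
    m <- fit_predict(train_idx)
  }
  pred <- m$pr(X[test_idx, , drop = FALSE])
  list(model = m$fit, spec = spec, C = chosen_C, pred = pred,
       metrics = classification_metrics(y[test_idx], pred),
       features = features[keep])
}
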