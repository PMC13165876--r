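test_that("classification metrics match their closed forms", {
  perfect <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unname(perfect), rep(1, 4))
  # TP=5, TN=4, FP=1, FN=0
  y <- c(rep(1, 5), rep(0, 5))
  p <- c(rep(1, 5), 1, rep(0, 4))
  m <- classification_metrics(y, p)
  expect_equal(m[["accuracy"]], 0.9)
  expect_equal(m[["precision"]], 5 / 6)
  expect_equal(m[["recall"]], 1)
  expect_equal(m[["f1"]], 2 * (5 / 6) / (5 / 6 + 1))
  # closed-form agreement on random confusion matrices
  set.seed(20)
  for (i in 1:20) {
    tp <- sample(0:8, 1); fp <- sample(0:8, 1)
    fn <- sample(0:8, 1); tn <- sample(1:8, 1)
    yy <- c(rep(1, tp + fn), rep(0, fp + tn))
    pp <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
    mm <- classification_metrics(yy, pp)
    expect_equal(mm[["accuracy"]], (tp + tn) / (tp + tn + fp + fn))
    expect_equal(mm[["precision"]], if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(mm[["recall"]], if (tp + fn > 0) tp / (tp + fn) else 0)
  }
  # no positive predictions: precision 0 with a flag
  m0 <- classification_metrics(c(1, 0), c(0, 0))
  expect_equal(m0[["precision"]], 0)
  expect_true(isTRUE(attr(m0, "no_positive_predictions")))
  # swapping the positive class swaps precision with the negative
  # predictive value
  m1 <- classification_metrics(y, p)
  m2 <- classification_metrics(1 - y, 1 - p)
  npv <- 4 / 4  # TN / (TN + FN) in the original coding
  expect_equal(m2[["precision"]], npv)
})

test_that("Mann-Whitney tests agree with brute-force rank-sum enumeration", {
  # exact null distribution of U by enumerating all group assignments
  brute_p <- function(x, y) {
    nx <- length(x); ny <- length(y)
    pool <- c(x, y)
    r <- rank(pool)
    u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combs <- combn(nx + ny, nx)
    us <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(21)
  for (i in 1:5) {
    nx <- sample(3:4, 1); ny <- sample(3:4, 1)
    x <- round(rnorm(nx, 1), 2); y <- round(rnorm(ny), 2)
    tab <- data.frame(group = c(rep("CD", nx), rep("HC", ny)), f = c(x, y))
    res <- mannwhitney_all(tab, features = "f")
    # brute-force U: count of CD-beats-HC pairs (ties counted half)
    u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(res$U, u_brute, tolerance = 1e-12)
    # the normal-approximation p tracks the exact enumeration p
    expect_lt(abs(res$p - brute_p(x, y)), 0.12)
  }
  # identical groups: U at its null mean, p near 1
  tab <- data.frame(group = rep(c("CD", "HC"), each = 4),
                    f = rep(c(1, 2, 3, 4), 2))
  res <- mannwhitney_all(tab, "f")
  expect_equal(res$U, 4 * 4 / 2)
  expect_gt(res$p, 0.9)
  # fully separated groups at n = 20/20 reach a tiny p
  tab2 <- data.frame(group = rep(c("CD", "HC"), each = 20),
                     f = c(rnorm(20, 10), rnorm(20, 0)))
  res2 <- mannwhitney_all(tab2, "f")
  expect_lt(res2$p, 1e-6)
  expect_equal(res2$direction, 1)
  # direction matches the sign of the group median difference
  tab3 <- data.frame(group = rep(c("CD", "HC"), each = 10),
                     f = c(rnorm(10, -2), rnorm(10, 2)))
  expect_equal(mannwhitney_all(tab3, "f")$direction, -1)
  expect_error(mannwhitney_all(data.frame(group = c("CD", "CD", "HC"),
                                          f = 1:3), "f"), "at least 3")
})

test_that("baseline classifiers fit, select C from the grid, and score", {
  set.seed(22)
  n <- 60
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    group = rep(c("HC", "CD"), each = n / 2))
  for (cc in baseline_feature_names()) tab[[cc]] <- rnorm(n)
  # make the toy problem strongly separable through several features
  shift <- ifelse(tab$group == "CD", 4, 0)
  for (cc in c("mct_lc", "prt_t1", "fet_l_happy", "st_ls_ps", "vsst_tf_roi"))
    tab[[cc]] <- shift + rnorm(n, 0, 0.3)
  tab$age <- ifelse(tab$group == "CD", 80, 70) + rnorm(n, 0, 1)
  tr <- c(1:18, 31:48); va <- c(19:24, 49:54); te <- c(25:30, 55:60)
  for (mo in c("LR", "GNB", "SVM")) {
    fit <- train_baseline(baseline_spec(mo), tab, tr, va, te)
    expect_gte(fit$metrics[["accuracy"]], 0.95)
    if (mo == "SVM") expect_true(fit$C %in% c(0.1, 0.4, 0.7, 1))
  }
  # label-permuted table scores near chance
  set.seed(23)
  accs <- replicate(8, {
    tabp <- tab
    tabp$group <- sample(tabp$group)
    train_baseline(baseline_spec("LR"), tabp, tr, va, te)$metrics[["accuracy"]]
  })
  expect_lt(abs(mean(accs) - 0.5), 0.2)
  # constant columns are dropped with a warning
  tabc <- tab; tabc$moca1 <- 1
  expect_warning(train_baseline(baseline_spec("LR"), tabc, tr, va, te),
                 "constant")
})
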