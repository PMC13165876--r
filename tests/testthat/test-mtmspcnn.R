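test_that("subspace counts match brute-force window enumeration", {
  spec <- window_spec(150, 50)
  expect_equal(n_subspaces(250, spec), 3)   # floor((250-150)/50)+1
  expect_equal(n_subspaces(150, spec), 1)
  expect_equal(n_subspaces(149, spec), 0)
  # property: formula equals enumeration for random (L, W, S) with S <= W
  brute <- function(L, W, S) {
    n <- 0; s <- 1
    while (s + W - 1 <= L) { n <- n + 1; s <- s + S }
    n
  }
  set.seed(14)
  for (i in 1:50) {
    W <- sample(2:80, 1); S <- sample(seq_len(W), 1)
    L <- sample(1:400, 1)
    expect_equal(n_subspaces(L, window_spec(W, S)), brute(L, W, S))
  }
})

test_that("bags hold the defined overlapping windows and discard tails", {
  X <- matrix(seq_len(2 * 250), nrow = 2, byrow = TRUE)
  bag <- make_subspaces(X, window_spec(150, 50), bag_label = 1L)
  expect_equal(bag$n, 3)
  expect_equal(dim(bag$instances), c(2, 150, 3))
  expect_equal(bag$instances[1, , 2], X[1, 51:200])
  expect_equal(bag$instances[2, , 3], X[2, 101:250])
  # one-window sequence is the whole sequence
  b1 <- make_subspaces(X[, 1:150], window_spec(150, 50))
  expect_equal(b1$instances[, , 1], X[, 1:150])
  expect_warning(b0 <- make_subspaces(X[, 1:149], window_spec(150, 50)),
                 "empty bag")
  expect_equal(b0$n, 0)
})

test_that("the multi-scale encoder produces 144-long embeddings", {
  expect_equal(encoder_dim(), 144)
  set.seed(15)
  enc <- gazecog:::init_encoder(17)
  x <- matrix(rnorm(17 * 150), 17)
  z <- encode(x, enc)
  expect_length(z, 144)
  # zero input with zero biases flows to a zero embedding
  z0 <- encode(matrix(0, 17, 150), enc)
  expect_equal(z0, rep(0, 144))
  # the embedding is NOT invariant to time reversal (guards against pooling
  # away all temporal structure before the convolutions)
  zr <- encode(x[, 150:1], enc)
  expect_gt(max(abs(z - zr)), 1e-6)
})

test_that("gated attention equals a hand-rolled loop and is a proper weighting", {
  set.seed(16)
  att <- gazecog:::init_attention()
  Z <- matrix(rnorm(144 * 7), 144, 7)
  ga <- gated_attention(Z, att)
  # brute-force evaluation of the gating formula per instance
  e_loop <- vapply(seq_len(7), function(n) {
    zn <- Z[, n]
    sum(att$w * (tanh(att$WV %*% zn) * (1 / (1 + exp(-(att$WU %*% zn))))))
  }, numeric(1))
  a_loop <- exp(e_loop) / sum(exp(e_loop))
  zbag_loop <- as.numeric(Z %*% a_loop)
  expect_equal(ga$e, e_loop, tolerance = 1e-10)
  expect_equal(ga$a, a_loop, tolerance = 1e-10)
  expect_equal(ga$z_bag, zbag_loop, tolerance = 1e-10)
  # weights: nonnegative, sum to one; singleton gets weight 1
  expect_true(all(ga$a >= 0))
  expect_equal(sum(ga$a), 1, tolerance = 1e-12)
  g1 <- gated_attention(Z[, 3, drop = FALSE], att)
  expect_equal(g1$a, 1)
  expect_equal(g1$z_bag, Z[, 3])
  # identical instances share the weight equally
  gi <- gated_attention(Z[, c(2, 2, 2), drop = FALSE], att)
  expect_equal(gi$a, rep(1 / 3, 3), tolerance = 1e-12)
  # permutation equivariance: weights permute, bag embedding is unchanged
  pp <- c(4, 1, 6, 2, 7, 3, 5)
  gp <- gated_attention(Z[, pp], att)
  expect_equal(gp$a, ga$a[pp], tolerance = 1e-12)
  expect_equal(gp$z_bag, ga$z_bag, tolerance = 1e-12)
  expect_error(gated_attention(Z[, 0, drop = FALSE], att), "empty")
})

test_that("soft weighting decays in the loss and is 1 at zero loss", {
  expect_equal(soft_weights(0), 1)
  ll <- seq(0, 5, by = 0.25)
  expect_true(all(diff(soft_weights(ll)) < 0))
  expect_true(all(soft_weights(ll, gamma = 2) <= soft_weights(ll)))
})

test_that("phase-1 training separates linearly separable instances", {
  set.seed(17)
  n <- 240
  X <- array(rnorm(17 * 150 * n), dim = c(17, 150, n))
  y <- rep(0:1, each = n / 2)
  for (i in which(y == 1)) X[5, , i] <- X[5, , i] + 2
  bags <- lapply(seq_len(n / 8), function(b) {
    idx <- ((b - 1) * 8 + 1):(b * 8)
    structure(list(instances = X[, , idx, drop = FALSE], n = 8L,
                   bag_label = y[idx[1]], subject_id = as.character(b),
                   task = "T"), class = "subspace_bag")
  })
  p1 <- phase1_train(bags, soft_weight_config(epochs = 8))
  expect_gte(tail(p1$history$acc, 1), 0.95)
  expect_error(phase1_train(bags[y[seq(1, n, 8)] == 1],
                            soft_weight_config(epochs = 1)),
               "single-class")
})

test_that("phase 2 freezes the encoder and finds planted signal windows", {
  set.seed(18)
  n_bags <- 30; n_inst <- 12
  bags <- lapply(seq_len(n_bags), function(b) {
    lab <- as.integer(b > n_bags / 2)
    X <- array(rnorm(17 * 150 * n_inst, 0, 0.5), dim = c(17, 150, n_inst))
    if (lab == 1) X[3, , 5] <- X[3, , 5] + 3  # only window 5 carries signal
    structure(list(instances = X, n = n_inst, bag_label = lab,
                   subject_id = as.character(b), task = "T"),
              class = "subspace_bag")
  })
  p1 <- phase1_train(bags, soft_weight_config(epochs = 6))
  enc_before <- p1$encoder
  p2 <- phase2_train(bags, p1$encoder, epochs = 15)
  expect_identical(p1$encoder, enc_before)  # bit-identical: frozen
  # attention concentrates on the signal window in most positive bags
  hits <- vapply(bags[(n_bags / 2 + 1):n_bags], function(b) {
    Z <- gazecog:::encoder_embed(p1$encoder, b$instances)
    which.max(gazecog:::attention_fw(p2$attention, Z)$a) == 5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # a perfectly predicted bag has near-zero loss
  Z <- gazecog:::encoder_embed(p1$encoder, bags[[n_bags]]$instances)
  p <- gazecog:::attention_fw(p2$attention, Z)$p
  expect_lt(-log(p[2]), 0.3)
})

test_that("majority voting follows the documented tie and abstention rules", {
  expect_equal(majority_vote(c(1, 1, 1, 0, 0))$prediction, 1)
  expect_equal(majority_vote(c(0, 0, 0, 0, 0))$prediction, 0)
  after_abstention <- majority_vote(c(1, 1, 0, 0, NA))
  expect_equal(after_abstention$prediction, 1)
  expect_true(after_abstention$tie)
  # five voters never tie
  expect_false(majority_vote(c(1, 0, 1, 0, 1))$tie)
  expect_error(majority_vote(rep(NA, 5)), "no task model")
})

test_that("subject prediction votes across tasks on a real cohort", {
  co <- small_cohort(seed = 33, n = 4)
  ids <- names(co$sessions)
  set.seed(19)
  fit <- mtmspcnn_train(co, train_ids = ids[c(1:3, 5:7)],
                        val_ids = ids[c(4, 8)],
                        cfg1 = soft_weight_config(epochs = 2), epochs2 = 4)
  expect_s3_class(fit, "mtmspcnn")
  expect_length(fit$models, 5)
  vr <- predict_subject(fit, co$sessions[[1]])
  expect_s3_class(vr, "vote_result")
  expect_length(vr$votes, 5)
  expect_true(vr$prediction %in% 0:1)
  # a session missing one task leads to abstention for that model
  rec <- co$sessions[[2]]
  tm <- setNames(lapply(names(fit$models), function(tk) task_matrix(
    preprocess_session(rec), tk)), names(fit$models))
  tm$FET <- NULL
  vr2 <- predict_subject(fit, task_mats = tm)
  expect_true(is.na(vr2$votes["FET"]))
})
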