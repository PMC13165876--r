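# ---- subspace bags -----------------------------------------------------------

#' Sliding-window specification
#'
#' @param W Window size in samples (default 150).
#' @param S Stride in samples (default 50), `0 < S <= W`; the overlap
#'   preserves temporal context between neighboring instances.
#' @return A `window_spec` list.
#' @export
window_spec <- function(W = 150L, S = 50L) {
  stopifnot(S > 0, S <= W)
  structure(list(W = as.integer(W), S = as.integer(S)), class = "window_spec")
}

#' Number of sliding-window instances for a sequence length
#'
#' `floor((L - W) / S) + 1` for `L >= W`, otherwise 0 (the tail shorter
#' than a full window is discarded).
#'
#' @param L Sequence length in samples.
#' @param spec A [window_spec()].
#' @return Integer instance count.
#' @export
n_subspaces <- function(L, spec = window_spec()) {
  if (L < spec$W) 0L else as.integer((L - spec$W) %/% spec$S + 1L)
}

#' Decompose a channel matrix into an overlapping subspace bag
#'
#' Instance `n` covers samples `(n-1)*S + 1 ...(n-1)*S + W`. A sequence
#' shorter than one window yields an empty bag with a warning.
#'
#' @param X Channels x length matrix (standardized model input).
#' @param spec A [window_spec()].
#' @param bag_label Optional bag-level class label (0 = HC, 1 = CD).
#' @param subject_id,task Optional bookkeeping fields.
#' @return A `subspace_bag`: list with `instances` (C x W x N array), `n`,
#'   `bag_label`, `subject_id`, `task`.
#' @export
make_subspaces <- function(X, spec = window_spec(), bag_label = NA_integer_,
                           subject_id = NA_character_, task = NA_character_) {
  X <- as.matrix(X)
  L <- ncol(X)
  n <- n_subspaces(L, spec)
  if (n == 0L) {
    warning("sequence shorter than one window (L = ", L, " < W = ", spec$W,
            "): empty bag")
    inst <- array(0, dim = c(nrow(X), spec$W, 0))
  } else {
    inst <- array(0, dim = c(nrow(X), spec$W, n))
    for (i in seq_len(n)) {
      s <- (i - 1L) * spec$S + 1L
      inst[, , i] <- X[, s:(s + spec$W - 1L)]
    }
  }
  structure(list(instances = inst, n = n, bag_label = bag_label,
                 subject_id = subject_id, task = task, spec = spec),
            class = "subspace_bag")
}

# ---- encoder and attention (user-facing wrappers) ---------------------------

#' Encode instances with the multi-scale encoder
#'
#' Runs a C x W instance (or a C x W x N batch) through the four parallel
#' convolutional streams (kernel sizes 3/5/7/9, each: convolution, ReLU,
#' max pooling, convolution, ReLU, global average pooling) and concatenates
#' the stream outputs into a length-144 embedding.
#'
#' @param x A C x W matrix or C x W x N array of instances.
#' @param params Encoder parameters (see [mtmspcnn_train()]; initialized
#'   internally during training).
#' @return A length-144 vector (single instance) or 144 x N matrix.
#' @export
encode <- function(x, params) {
  single <- length(dim(x)) == 2
  if (single) x <- array(x, dim = c(dim(x), 1))
  Z <- encoder_embed(params, x)
  if (single) drop(Z) else Z
}

#' Gated-attention pooling over a bag of embeddings
#'
#' Computes the unnormalized score
#' `e_n = w' (tanh(WV z_n) * sigmoid(WU z_n))`, the softmax-normalized
#' attention weights `a` across the bag's instances, and the bag embedding
#' `Z_bag = sum_n a_n z_n`.
#'
#' @param z D x N embedding matrix (one column per instance), or N x D with
#'   `transpose = TRUE`.
#' @param params Attention parameters: matrices `WV`, `WU` (K x D) and
#'   vector `w` (K x 1).
#' @param transpose Set `TRUE` when `z` is N x D.
#' @return List with `a` (length-N weights, nonnegative, summing to 1),
#'   `z_bag` (length-D) and `e` (raw scores).
#' @export
gated_attention <- function(z, params, transpose = FALSE) {
  if (transpose) z <- t(z)
  if (ncol(z) == 0) stop("empty bag: no instances to attend over")
  A <- tanh(params$WV %*% z)
  G <- 1 / (1 + exp(-(params$WU %*% z)))
  e <- as.numeric(t(params$w) %*% (A * G))
  a <- exp(e - max(e))
  a <- a / sum(a)
  list(a = a, z_bag = as.numeric(z %*% a), e = e)
}

# ---- phase 1: instance-level pretraining ------------------------------------

#' Soft-weighting configuration for phase-1 training
#'
#' Instances inherit their subject's label, which injects label noise on
#' uninformative windows; the soft weight `w_i = exp(-gamma * loss_i)`
#' (recomputed each epoch from the previous epoch's per-instance loss)
#' down-weights high-loss instances, and the epoch cap limits late-stage
#' memorization of noisy windows.
#'
#' @param gamma Decay rate of the weight function (default 1).
#' @param epochs Phase-1 epoch cap (default 30).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 0.001).
#' @param min_steps Minimum number of optimizer steps (default 0): tasks
#'   with few instances per epoch train for additional epochs until this
#'   floor is met, so every task model receives a comparable optimization
#'   budget regardless of its sequence length.
#' @return A `soft_weight_config` list.
#' @export
soft_weight_config <- function(gamma = 1, epochs = 30L, batch_size = 32L,
                               lr = 0.001, min_steps = 0L) {
  stopifnot(gamma > 0, epochs >= 1, batch_size >= 1, min_steps >= 0)
  structure(list(gamma = gamma, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 min_steps = as.integer(min_steps)),
            class = "soft_weight_config")
}

#' Soft instance weights from per-instance losses
#'
#' @param loss Numeric vector of per-instance losses.
#' @param gamma Decay rate.
#' @return Weights `exp(-gamma * loss)` in (0, 1].
#' @export
soft_weights <- function(loss, gamma = 1) exp(-gamma * loss)

#' Phase-1 training of the multi-scale encoder
#'
#' Trains the encoder plus an instance-level MLP head (one hidden layer of
#' 64 units) on all instances of the training bags, each instance carrying
#' its subject's label, minimizing soft-weighted cross-entropy with Adam.
#' Weights are 1 in the first epoch and `exp(-gamma * loss_i)` from the
#' previous epoch's losses afterwards.
#'
#' @param bags List of `subspace_bag`s with `bag_label` set (training split).
#' @param cfg A [soft_weight_config()].
#' @return List with `encoder` (parameters), `head`, `history` (per-epoch
#'   mean loss and training accuracy) and `instance_loss`.
#' @export
phase1_train <- function(bags, cfg = soft_weight_config()) {
  bags <- Filter(function(b) b$n > 0, bags)
  if (!length(bags)) stop("no non-empty training bags")
  y <- unlist(lapply(bags, function(b) rep(b$bag_label, b$n)))
  if (length(unique(y)) < 2) stop("single-class training set")
  C <- dim(bags[[1]]$instances)[1]; W <- dim(bags[[1]]$instances)[2]
  X <- array(0, dim = c(C, W, length(y)))
  off <- 0L
  for (b in bags) {
    X[, , off + seq_len(b$n)] <- b$instances
    off <- off + b$n
  }
  n <- length(y)
  enc <- init_encoder(C)
  head <- init_head()
  opt_e <- adam_init(enc); opt_h <- adam_init(head)
  inst_loss <- rep(0, n)
  wts <- rep(1, n)
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  n_epochs <- max(cfg$epochs,
                  if (cfg$min_steps > 0)
                    ceiling(cfg$min_steps / steps_per_epoch) else 0L)
  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(n)
    correct <- 0; tot_loss <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(n, s + cfg$batch_size - 1L)]
      xb <- X[, , idx, drop = FALSE]
      yb <- y[idx]
      ef <- encoder_fw(enc, xb)
      hf <- head_fw(head, ef$Z)
      cl <- ce_loss(hf$logits, yb, wts[idx])
      inst_loss[idx] <- cl$loss
      correct <- correct + sum(max.col(t(cl$P)) - 1L == yb)
      tot_loss <- tot_loss + sum(cl$loss)
      hb <- head_bw(head, hf, ef$Z, cl$dlogits)
      ge <- encoder_bw(enc, ef$cache, hb$dZ)
      up <- adam_step(head, hb$grads, opt_h, lr = cfg$lr)
      head <- up$params; opt_h <- up$state
      up <- adam_step(enc, ge, opt_e, lr = cfg$lr)
      enc <- up$params; opt_e <- up$state
    }
    wts <- soft_weights(inst_loss, cfg$gamma)
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / n,
                                   acc = correct / n))
  }
  list(encoder = enc, head = head, history = hist, instance_loss = inst_loss)
}

# ---- phase 2: bag-level attention training ----------------------------------

#' Phase-2 training of gated attention and the bag classifier
#'
#' The pretrained encoder is frozen; its embeddings are computed once per
#' bag. Only the gated-attention parameters and the linear bag classifier
#' are optimized, one bag per step (batch size 1), minimizing bag-level
#' cross-entropy with Adam. When validation bags are supplied, the
#' parameters with the best validation accuracy are returned.
#'
#' @param bags Training `subspace_bag`s with labels.
#' @param encoder Frozen encoder parameters from [phase1_train()].
#' @param epochs Number of epochs over the bags (default 30).
#' @param lr Adam learning rate (default 0.001).
#' @param val_bags Optional validation bags for model selection.
#' @return List with `attention` (parameters incl. classifier), `history`,
#'   and `val_acc` (best validation accuracy, `NA` without validation bags).
#' @export
phase2_train <- function(bags, encoder, epochs = 30L, lr = 0.001,
                         val_bags = NULL) {
  keep <- vapply(bags, function(b) b$n > 0, logical(1))
  if (any(!keep)) warning(sum(!keep), " empty bag(s) skipped")
  bags <- bags[keep]
  Zs <- lapply(bags, function(b) encoder_embed(encoder, b$instances))
  y <- vapply(bags, `[[`, 0L, "bag_label")
  Zv <- if (!is.null(val_bags)) {
    val_bags <- Filter(function(b) b$n > 0, val_bags)
    lapply(val_bags, function(b) encoder_embed(encoder, b$instances))
  }
  att <- init_attention()
  opt <- adam_init(att)
  best <- list(att = att, acc = -1)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(bags))
    tot <- 0
    for (i in ord) {
      Z <- Zs[[i]]
      g <- attention_fw(att, Z)
      p <- g$p
      yi <- y[i]
      tot <- tot - log(max(p[yi + 1L], 1e-12))
      dlog <- p; dlog[yi + 1L] <- dlog[yi + 1L] - 1
      gr <- attention_bw(att, g, Z, dlog)
      up <- adam_step(att, gr, opt, lr = lr)
      att <- up$params; opt <- up$state
    }
    hist[ep] <- tot / length(bags)
    if (!is.null(Zv)) {
      acc <- mean(vapply(seq_along(Zv), function(j) {
        pj <- attention_fw(att, Zv[[j]])$p
        (which.max(pj) - 1L) == val_bags[[j]]$bag_label
      }, logical(1)))
      if (acc > best$acc) best <- list(att = att, acc = acc)
    }
  }
  if (!is.null(Zv)) att <- best$att
  list(attention = att, history = hist,
       val_acc = if (!is.null(Zv)) best$acc else NA_real_)
}

# full attention + classifier forward for one bag
attention_fw <- function(att, Z) {
  ga <- gated_attention(Z, att)
  logits <- as.numeric(att$Wc %*% ga$z_bag + att$bc)
  e <- exp(logits - max(logits))
  list(a = ga$a, z_bag = ga$z_bag, e_raw = ga$e, logits = logits,
       p = e / sum(e))
}

attention_bw <- function(att, fwd, Z, dlog) {
  dWc <- outer(dlog, fwd$z_bag)
  dbc <- dlog
  dzbag <- as.numeric(t(att$Wc) %*% dlog)
  a <- fwd$a
  s <- as.numeric(t(Z) %*% dzbag)        # s_n = z_n . dzbag
  de <- a * (s - sum(a * s))             # softmax jacobian
  A <- tanh(att$WV %*% Z)
  G <- 1 / (1 + exp(-(att$WU %*% Z)))
  dw <- (A * G) %*% de
  dAG <- att$w %*% t(de)                 # K x N
  dA <- dAG * G * (1 - A^2)
  dG <- dAG * A * G * (1 - G)
  list(WV = dA %*% t(Z), WU = dG %*% t(Z), w = dw,
       Wc = dWc, bc = dbc)
}

# ---- per-task input assembly -------------------------------------------------

#' Build the 17-channel model input matrix for one task
#'
#' Stacks the 11 oculomotor channels and the 6 facial blend-shape channels
#' (rows) over all samples of the task, trials concatenated in order. The
#' four eye-tracking tasks carry zero-filled facial channels by protocol,
#' so a single encoder input shape serves all five tasks.
#'
#' @param rec A preprocessed `session_recording`.
#' @param task Task label.
#' @return A 17 x L matrix (`NULL` when the task is absent).
#' @export
task_matrix <- function(rec, task) {
  idx <- which(rec$task == task)
  if (!length(idx)) return(NULL)
  rbind(t(rec$eye_origin_left[idx, , drop = FALSE]),
        t(rec$eye_origin_right[idx, , drop = FALSE]),
        t(rec$gaze_point[idx, , drop = FALSE]),
        t(rec$pupil[idx, , drop = FALSE]),
        t(rec$fbs[idx, , drop = FALSE]))
}

#' @rdname task_matrix
#' @export
model_channels <- function() c(eye_channels(), fbs_channels())

# ---- training / prediction of the five-task model ---------------------------

#' Train the MT-MSPCNN on a cohort split
#'
#' For each of the five tasks: standardizes the 17 input channels with
#' training-split statistics, windows each subject's task sequence into a
#' subspace bag, pretrains the multi-scale encoder at the instance level
#' (phase 1, soft-weighted cross-entropy) and then trains gated attention
#' with the bag classifier on frozen embeddings (phase 2, batch size 1,
#' model selection on validation accuracy).
#'
#' @param cohort A cohort from [generate_cohort()] (sessions are
#'   preprocessed on the fly if needed).
#' @param train_ids,val_ids Subject ids of the training / validation split.
#' @param tasks Tasks to train (default all five).
#' @param window A [window_spec()].
#' @param cfg1 A [soft_weight_config()] for phase 1.
#' @param epochs2 Phase-2 epochs (default 30).
#' @param task_mats Optional precomputed list `task_mats[[task]][[subject]]`
#'   of 17 x L matrices (see [task_matrix()]), to avoid re-preprocessing.
#' @param standardize Channel standardization of the model input:
#'   `"center_subject"` (default) removes each subject's per-channel mean --
#'   static between-subject offsets such as baseline pupil diameter or
#'   anisocoria are nuisance, not signal -- and scales by the training-set
#'   standard deviation so physical amplitudes remain comparable across
#'   subjects; `"trainset"` applies training-set mean and sd;
#'   `"subject"` standardizes fully within subject.
#' @return An `mtmspcnn` list of per-task models (each with the frozen
#'   `encoder`, `attention`, z-score `stats` and the window spec).
#' @export
mtmspcnn_train <- function(cohort, train_ids, val_ids = NULL,
                           tasks = setdiff(task_labels(), "NONE"),
                           window = window_spec(),
                           cfg1 = soft_weight_config(),
                           epochs2 = 30L, task_mats = NULL,
                           standardize = c("center_subject", "trainset",
                                           "subject")) {
  standardize <- match.arg(standardize)
  if (is.null(task_mats))
    task_mats <- cohort_task_matrices(cohort, c(train_ids, val_ids), tasks)
  labels <- setNames(ifelse(vapply(cohort$sessions, `[[`, "", "group") == "CD",
                            1L, 0L),
                     names(cohort$sessions))
  models <- list()
  for (tk in tasks) {
    mats <- task_mats[[tk]]
    stats <- channel_stats(mats[train_ids])
    stats$mode <- standardize
    mk_bags <- function(ids) lapply(ids, function(sid)
      make_subspaces(std_input(mats[[sid]], stats), window,
                     bag_label = labels[[sid]], subject_id = sid, task = tk))
    tr_bags <- mk_bags(train_ids)
    va_bags <- if (length(val_ids)) mk_bags(val_ids)
    p1 <- phase1_train(tr_bags, cfg1)
    p2 <- phase2_train(tr_bags, p1$encoder, epochs = epochs2,
                       val_bags = va_bags)
    models[[tk]] <- list(task = tk, encoder = p1$encoder,
                         attention = p2$attention, stats = stats,
                         window = window, history1 = p1$history,
                         val_acc = p2$val_acc)
  }
  structure(list(models = models, tasks = tasks), class = "mtmspcnn")
}

# apply the configured channel standardization to one subject's task matrix
std_input <- function(X, stats) {
  s <- stats$sd
  s[!is.finite(s) | s < 1e-12] <- 1
  mode <- stats$mode %||% "center_subject"
  if (mode == "trainset") return((X - stats$mean) / s)
  if (mode == "subject") {
    ss <- apply(X, 1, sd)
    ss[!is.finite(ss) | ss < 1e-12] <- 1
    return((X - rowMeans(X)) / ss)
  }
  (X - rowMeans(X)) / s
}

# precompute per-task 17 x L matrices for a set of subjects
cohort_task_matrices <- function(cohort, ids = names(cohort$sessions),
                                 tasks = setdiff(task_labels(), "NONE"),
                                 cfg = preprocess_config()) {
  out <- setNames(vector("list", length(tasks)), tasks)
  for (sid in ids) {
    rec <- cohort$sessions[[sid]]
    if (!isTRUE(attr(rec, "preprocessed"))) rec <- preprocess_session(rec, cfg)
    for (tk in tasks) out[[tk]][[sid]] <- task_matrix(rec, tk)
  }
  out
}

#' Predict one bag's class probability
#'
#' @param model One per-task model from [mtmspcnn_train()].
#' @param X 17 x L raw (unstandardized) task matrix.
#' @return A `bag_prediction` list: attention weights `a`, bag embedding
#'   `z_bag`, class probabilities `prob` (HC, CD) and `vote` (0/1).
#' @export
predict_bag <- function(model, X) {
  bag <- make_subspaces(std_input(X, model$stats), model$window)
  if (bag$n == 0) return(NULL)
  Z <- encoder_embed(model$encoder, bag$instances)
  fw <- attention_fw(model$attention, Z)
  structure(list(a = fw$a, z_bag = fw$z_bag, prob = fw$p,
                 vote = which.max(fw$p) - 1L), class = "bag_prediction")
}

#' Subject-level prediction by majority vote over task models
#'
#' Each available task model casts a binary vote; the subject-level class
#' is the majority over the five tasks. A missing task segment makes that
#' model abstain; if the remaining votes tie, the cognitively-declined
#' class is returned with a `tie` flag (screening-conservative).
#'
#' @param models An `mtmspcnn` object (or its `models` list).
#' @param rec A `session_recording`, preprocessed if possible.
#' @param task_mats Optional precomputed named list of 17 x L matrices.
#' @return A `vote_result` list: per-task `votes`, `probs`, final
#'   `prediction` (0 = HC, 1 = CD) and `tie` flag.
#' @export
predict_subject <- function(models, rec = NULL, task_mats = NULL) {
  if (inherits(models, "mtmspcnn")) models <- models$models
  if (is.null(task_mats)) {
    if (!isTRUE(attr(rec, "preprocessed"))) rec <- preprocess_session(rec)
    task_mats <- setNames(lapply(names(models), function(tk)
      task_matrix(rec, tk)), names(models))
  }
  votes <- probs <- setNames(rep(NA_real_, length(models)), names(models))
  for (tk in names(models)) {
    X <- task_mats[[tk]]
    if (is.null(X)) next
    bp <- predict_bag(models[[tk]], X)
    if (is.null(bp)) next
    votes[tk] <- bp$vote
    probs[tk] <- bp$prob[2]
  }
  mv <- majority_vote(votes)
  structure(list(votes = votes, probs = probs, prediction = mv$prediction,
                 tie = mv$tie), class = "vote_result")
}

#' Combine per-task binary votes into a subject-level decision
#'
#' The subject-level class is the plurality of the available (non-`NA`)
#' votes. With all five task models voting, a binary tie is impossible;
#' after abstentions, a tie resolves to the cognitive-decline class and is
#' flagged (screening-conservative).
#'
#' @param votes Numeric/integer vector of 0/1 votes, `NA` = abstention.
#' @return List with `prediction` (0/1) and logical `tie`.
#' @export
majority_vote <- function(votes) {
  nv <- sum(!is.na(votes))
  if (nv == 0) stop("no task model could vote")
  n1 <- sum(votes, na.rm = TRUE)
  tie <- (n1 == nv - n1)
  list(prediction = if (n1 > nv - n1) 1L else if (tie) 1L else 0L, tie = tie)
}

#' @export
print.vote_result <- function(x, ...) {
  v <- ifelse(is.na(x$votes), "-", ifelse(x$votes == 1, "CD", "HC"))
  cat("<vote_result>", paste(names(x$votes), v, sep = ":", collapse = " "),
      "=>", if (x$prediction == 1) "CD" else "HC",
      if (x$tie) "(tie, conservative CD)", "\n")
  invisible(x)
}
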