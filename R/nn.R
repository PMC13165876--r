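# Internal neural-network machinery for the MT-MSPCNN: parameter
# initialization, encoder forward/backward over batched instance cubes
# (via the compiled conv/pool kernels), the instance MLP head, and Adam.

# Stream geometry: kernel sizes 3/5/7/9 with symmetric zero padding
# preserving length, max pooling (kernel = stride), second conv, global
# average pooling; concatenated embedding length 32+64+16+32 = 144.
encoder_streams <- function() {
  list(
    list(k1 = 3, p1 = 1, c1 = 16, pool = 2, k2 = 3, p2 = 1, c2 = 32),
    list(k1 = 5, p1 = 2, c1 = 32, pool = 4, k2 = 5, p2 = 2, c2 = 64),
    list(k1 = 7, p1 = 3, c1 = 8,  pool = 2, k2 = 3, p2 = 1, c2 = 16),
    list(k1 = 9, p1 = 4, c1 = 16, pool = 3, k2 = 5, p2 = 2, c2 = 32))
}

#' Embedding dimension of the multi-scale encoder
#'
#' Length of the concatenated representation produced by the four parallel
#' convolutional streams (32 + 64 + 16 + 32).
#'
#' @return The integer 144.
#' @export
encoder_dim <- function() {
  sum(vapply(encoder_streams(), `[[`, 0, "c2"))
}

rmat <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)

init_encoder <- function(c_in) {
  par <- list()
  for (i in seq_along(encoder_streams())) {
    sp <- encoder_streams()[[i]]
    par[[paste0("s", i, "_W1")]] <- rmat(sp$c1, c_in * sp$k1,
                                         sqrt(2 / (c_in * sp$k1)))
    par[[paste0("s", i, "_b1")]] <- numeric(sp$c1)
    par[[paste0("s", i, "_W2")]] <- rmat(sp$c2, sp$c1 * sp$k2,
                                         sqrt(2 / (sp$c1 * sp$k2)))
    par[[paste0("s", i, "_b2")]] <- numeric(sp$c2)
  }
  attr(par, "c_in") <- c_in
  par
}

init_head <- function(hidden = 64, d = encoder_dim()) {
  list(Wh = rmat(hidden, d, sqrt(2 / d)), bh = numeric(hidden),
       Wo = rmat(2, hidden, sqrt(2 / hidden)), bo = numeric(2))
}

init_attention <- function(k = 64, d = encoder_dim()) {
  list(WV = rmat(k, d, sqrt(1 / d)), WU = rmat(k, d, sqrt(1 / d)),
       w = rmat(k, 1, sqrt(1 / k)),
       Wc = rmat(2, d, sqrt(1 / d)), bc = numeric(2))
}

# forward through one stream; returns embedding rows and a cache for backward
# (convolutions carry a fused ReLU; the cached activations are rectified)
stream_fw <- function(sp, W1, b1, W2, b2, X) {
  c1 <- cpp_conv1d_fw(X, W1, b1, sp$k1, sp$p1, TRUE)
  mp <- cpp_maxpool_fw(c1, sp$pool)
  c2 <- cpp_conv1d_fw(mp$Y, W2, b2, sp$k2, sp$p2, TRUE)
  z <- cpp_gap_fw(c2)
  list(z = z, X = X, mpY = mp$Y, mpidx = mp$idx, c2 = c2, L1 = dim(c1)[2])
}

stream_bw <- function(sp, W1, W2, cache, dz) {
  dr2 <- cpp_gap_bw(dz, cache$c2)
  g2 <- cpp_conv1d_bw(cache$mpY, W2, dr2, sp$k2, sp$p2, TRUE)
  dr1 <- cpp_maxpool_bw(g2$dX, cache$mpidx, cache$mpY, cache$L1)
  g1 <- cpp_conv1d_bw(cache$X, W1, dr1, sp$k1, sp$p1, FALSE)
  list(dW1 = g1$dW, db1 = as.numeric(g1$db),
       dW2 = g2$dW, db2 = as.numeric(g2$db))
}

# X: (C, W, B) instance cube -> list(Z = (144, B), cache)
encoder_fw <- function(par, X, keep_cache = TRUE) {
  streams <- encoder_streams()
  zs <- vector("list", 4); caches <- vector("list", 4)
  for (i in 1:4) {
    sp <- streams[[i]]
    cc <- stream_fw(sp, par[[paste0("s", i, "_W1")]],
                    par[[paste0("s", i, "_b1")]],
                    par[[paste0("s", i, "_W2")]],
                    par[[paste0("s", i, "_b2")]], X)
    zs[[i]] <- cc$z
    if (keep_cache) caches[[i]] <- cc[-1]
  }
  list(Z = do.call(rbind, zs), cache = if (keep_cache) caches)
}

encoder_bw <- function(par, cache, dZ) {
  streams <- encoder_streams()
  offs <- cumsum(c(0, vapply(streams, `[[`, 0, "c2")))
  gr <- list()
  for (i in 1:4) {
    sp <- streams[[i]]
    dz <- dZ[(offs[i] + 1):offs[i + 1], , drop = FALSE]
    g <- stream_bw(sp, par[[paste0("s", i, "_W1")]],
                   par[[paste0("s", i, "_W2")]], cache[[i]], dz)
    gr[[paste0("s", i, "_W1")]] <- g$dW1
    gr[[paste0("s", i, "_b1")]] <- g$db1
    gr[[paste0("s", i, "_W2")]] <- g$dW2
    gr[[paste0("s", i, "_b2")]] <- g$db2
  }
  gr
}

# encoder forward over many instances in memory-bounded chunks (no cache)
encoder_embed <- function(par, X, chunk = 64L) {
  n <- dim(X)[3]
  if (n == 0) return(matrix(0, encoder_dim(), 0))
  out <- matrix(0, encoder_dim(), n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[, s:e] <- encoder_fw(par, X[, , s:e, drop = FALSE],
                             keep_cache = FALSE)$Z
  }
  out
}

head_fw <- function(par, Z) {
  H <- par$Wh %*% Z + par$bh
  mh <- H > 0
  H[!mh] <- 0
  logits <- par$Wo %*% H + par$bo
  list(logits = logits, H = H, mh = mh)
}

softmax_cols <- function(L) {
  L <- sweep(L, 2, apply(L, 2, max))
  E <- exp(L)
  sweep(E, 2, colSums(E), "/")
}

# weighted softmax cross-entropy; y in {0,1}; returns loss vector and dlogits
ce_loss <- function(logits, y, wts = NULL) {
  P <- softmax_cols(logits)
  iy <- cbind(y + 1L, seq_along(y))
  li <- -log(pmax(P[iy], 1e-12))
  dL <- P
  dL[iy] <- dL[iy] - 1
  if (is.null(wts)) wts <- rep(1, length(y))
  dL <- sweep(dL, 2, wts / sum(wts), "*")
  list(loss = li, dlogits = dL, P = P)
}

head_bw <- function(par, fwd, Z, dlogits) {
  dWo <- dlogits %*% t(fwd$H)
  dbo <- rowSums(dlogits)
  dH <- t(par$Wo) %*% dlogits
  dH[!fwd$mh] <- 0
  list(grads = list(Wh = dH %*% t(Z), bh = rowSums(dH), Wo = dWo, bo = dbo),
       dZ = t(par$Wh) %*% dH)
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}
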