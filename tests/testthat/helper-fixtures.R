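# Shared fixtures and explicit-loop reference implementations. The oracles
# deliberately use scalar loops so they stay independent of the vectorised
# code paths they check.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small assembled dataset for fast end-to-end unit tests.
tiny_dataset <- function() {
  cached("tiny", suppressMessages(synthetic_dataset(
    synth_config(n_genes = 60L, n_outlying = 40L, n_mirna = 20L,
                 samples_per_context = 10L, seed = 1L))))
}

tiny_config <- function(...) {
  args <- list(seed = 1L, hidden_dims = c(16L, 8L), epochs = 10L,
               pretrain_epochs = 10L, cv_folds = 3L)
  do.call(synthetic_run_config, utils::modifyList(args, list(...)))
}

# The standard benchmark instance (shared by the acceptance tests).
default_dataset <- function() {
  cached("default", suppressMessages(synthetic_dataset(synth_config(seed = 0L))))
}

rand_mat <- function(n, k, sd = 1) matrix(rnorm(n * k, sd = sd), n, k)

rand_binary <- function(n, k, p = 0.3) {
  matrix(as.numeric(runif(n * k) < p), n, k)
}

rand_symmetric <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# --- explicit-loop oracles -------------------------------------------------

hgcn_layer_oracle <- function(P, X_self, X_nbr, theta, W1, b1,
                              activation = "relu") {
  P <- as.matrix(P)
  n <- nrow(P)
  f_out <- ncol(theta)
  out <- matrix(0, n, f_out)
  for (v in seq_len(n)) {
    prop <- rep(0, ncol(X_nbr))
    for (u in seq_len(nrow(X_nbr))) prop <- prop + P[v, u] * X_nbr[u, ]
    pre <- as.numeric(prop %*% theta) +
      as.numeric((prop * X_self[v, ]) %*% W1) + as.numeric(b1)
    out[v, ] <- if (activation == "relu") pmax(pre, 0) else pre
  }
  out
}

bilinear_oracle <- function(A_row, X_self, X_nbr, W, b) {
  n <- nrow(A_row)
  f_out <- ncol(W)
  s_self <- sweep(X_self %*% W, 2, as.numeric(b), "+")
  s_nbr <- sweep(X_nbr %*% W, 2, as.numeric(b), "+")
  out <- matrix(0, n, f_out)
  for (p in seq_len(n)) {
    nbrs <- which(as.matrix(A_row)[p, ] != 0)
    S <- rbind(s_self[p, , drop = FALSE], s_nbr[nbrs, , drop = FALSE])
    d_ext <- nrow(S)
    b_p <- d_ext * (d_ext - 1) / 2
    if (b_p == 0) next
    acc <- rep(0, f_out)
    for (i in seq_len(d_ext - 1)) for (j in (i + 1):d_ext)
      acc <- acc + S[i, ] * S[j, ]
    out[p, ] <- acc / b_p
  }
  out
}

attention_oracle <- function(H, W_Q, W_K, W_V) {
  n <- nrow(H)
  d <- ncol(W_Q)
  Q <- H %*% W_Q; K <- H %*% W_K; V <- H %*% W_V
  out <- matrix(0, n, ncol(H))
  for (i in seq_len(n)) {
    sc <- rep(0, n)
    for (j in seq_len(n)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(sc - max(sc)); w <- w / sum(w)
    acc <- rep(0, ncol(V))
    for (j in seq_len(n)) acc <- acc + w[j] * V[j, ]
    out[i, ] <- acc + H[i, ]
  }
  out
}

conv1d_oracle <- function(H, W1, b1, W2, b2) {
  h <- pmax(sweep(H %*% W1, 2, as.numeric(b1), "+"), 0)
  sweep(h %*% W2, 2, as.numeric(b2), "+")
}

# Full sliding-window 2D convolution over the zero-padded channel stack,
# including the horizontal taps that only ever see padding.
conv2d_oracle <- function(h_list, kernel, bias) {
  nch <- length(h_list)
  n <- nrow(h_list[[1]])
  img <- array(0, c(nch, n + 2, 3))  # zero-padded: spatial (n+2) x 3
  for (c in seq_len(nch)) img[c, 2:(n + 1), 2] <- h_list[[c]][, 1]
  out <- matrix(0, n, 1)
  for (i in seq_len(n)) {
    acc <- 0
    for (c in seq_len(nch)) for (di in 1:3) for (dj in 1:3)
      acc <- acc + kernel[c, di, dj] * img[c, i + di - 1, dj]
    out[i, 1] <- acc + bias
  }
  out
}

mlp_oracle <- function(X, W1, b1, W2, b2, W3, b3) {
  h1 <- pmax(sweep(X %*% W1, 2, as.numeric(b1), "+"), 0)
  h2 <- pmax(sweep(h1 %*% W2, 2, as.numeric(b2), "+"), 0)
  sweep(h2 %*% W3, 2, as.numeric(b3), "+")
}

bce_oracle <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  s <- 0
  for (i in seq_along(p)) s <- s + y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i])
  -s / length(p)
}

gip_oracle <- function(profiles, gamma_prime = 1) {
  t_ <- nrow(profiles)
  gamma <- gamma_prime / mean(rowSums(profiles^2))
  K <- matrix(0, t_, t_)
  for (i in seq_len(t_)) for (j in seq_len(t_))
    K[i, j] <- exp(-gamma * sum((profiles[i, ] - profiles[j, ])^2))
  K
}
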