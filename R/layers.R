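# Forward passes of every layer in the model. Each layer is written once
# against a tiny dispatch (g_*) that routes to plain dense algebra for
# ordinary matrices and to the autodiff tape for `ad` nodes, so the exact
# same code path is unit-tested against loop oracles and differentiated
# during training.

g_matmul <- function(a, b) {
  if (is_ad(a) || is_ad(b)) ad_matmul(a, b) else a %*% b
}

g_spmm <- function(P, b) {
  if (is_ad(b)) ad_spmm(P, b) else as.matrix(P %*% b)
}

g_add <- function(a, b) {
  if (is_ad(a) || is_ad(b)) return(ad_add(a, b))
  if (is.matrix(b) && nrow(b) == 1L && nrow(a) > 1L)
    sweep(a, 2L, as.numeric(b), "+")
  else a + b
}

g_sub <- function(a, b) if (is_ad(a) || is_ad(b)) ad_sub(a, b) else a - b

g_mul <- function(a, b) if (is_ad(a) || is_ad(b)) ad_mul(a, b) else a * b

g_scale <- function(a, s) if (is_ad(a)) ad_scale(a, s) else a * s

g_relu <- function(a) if (is_ad(a)) ad_relu(a) else pmax(a, 0)

g_sigmoid <- function(a) if (is_ad(a)) ad_sigmoid(a) else stats::plogis(a)

g_softmax_rows <- function(a) {
  if (is_ad(a)) return(ad_softmax_rows(a))
  e <- exp(a - apply(a, 1L, max))
  e / rowSums(e)
}

g_transpose <- function(a) if (is_ad(a)) ad_transpose(a) else t(a)

g_rowshift <- function(a, s) {
  if (is_ad(a)) return(ad_rowshift(a, s))
  n <- nrow(a)
  out <- matrix(0, n, ncol(a))
  if (s == 0L) return(a)
  if (abs(s) < n) {
    if (s > 0L) out[(s + 1L):n, ] <- a[1L:(n - s), , drop = FALSE]
    else out[1L:(n + s), ] <- a[(1L - s):n, , drop = FALSE]
  }
  out
}

g_cbind <- function(...) {
  args <- list(...)
  if (any(vapply(args, is_ad, TRUE))) do.call(ad_cbind, args)
  else do.call(cbind, args)
}

# Inverted dropout on a value; mask drawn from the current R RNG stream.
g_dropout <- function(a, rate, training) {
  if (!training || rate <= 0) return(a)
  v <- ad_value(a)
  mask <- matrix((stats::runif(length(v)) >= rate) / (1 - rate),
                 nrow(v), ncol(v))
  g_mul(a, mask)
}

#' Heterogeneous graph convolution layer
#'
#' Updates target-side node features on one (possibly bipartite) network by
#' aggregating neighbourhood features and neighbourhood interactions:
#' \deqn{AGG_{NF} = (P X_{nbr}) \theta, \quad
#'       AGG_{NI} = ((P X_{nbr}) \odot X_{self}) W_1 + b_1, \quad
#'       H = \sigma(AGG_{NF} + AGG_{NI})}
#' where `P` is the degree-normalized adjacency with target nodes as rows.
#' `theta`, `W1` and `b1` are shared across the three networks at a given
#' layer. On the gene-gene network `X_self == X_nbr`; on bipartite networks
#' the layer is applied in both directions with `P` and its transpose.
#'
#' @param P Normalized adjacency (targets x neighbours), sparse or dense.
#' @param X_self Target-side features (targets x F_in).
#' @param X_nbr Neighbour-side features (neighbours x F_in).
#' @param theta,W1 Weight matrices (F_in x F_out).
#' @param b1 Bias row vector (1 x F_out).
#' @param activation `"relu"` (default) or `"identity"` (test hook).
#' @return Target x F_out feature matrix.
#' @export
hgcn_layer <- function(P, X_self, X_nbr, theta, W1, b1,
                       activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  prop <- g_spmm(P, X_nbr)
  agg_nf <- g_matmul(prop, theta)
  agg_ni <- g_add(g_matmul(g_mul(prop, X_self), W1), b1)
  pre <- g_add(agg_nf, agg_ni)
  if (activation == "relu") g_relu(pre) else pre
}

#' Stack of heterogeneous graph convolution layers
#'
#' Composes [hgcn_layer()] `L` times. On bipartite networks the gene side and
#' the other side alternate roles between layers (the gene-side update at
#' layer k+1 consumes the other-side output of layer k and vice versa).
#' Dropout at rate `dropout` is applied to both sides between layers.
#'
#' @param P Normalized adjacency, gene side as rows.
#' @param X_gene Gene-side input features.
#' @param X_other Other-side input features; pass `X_gene` again for the
#'   symmetric gene-gene network (`symmetric = TRUE`).
#' @param layers List with one element per layer, each holding `theta`, `W1`,
#'   `b1`.
#' @param symmetric TRUE for the gene-gene network.
#' @param dropout Dropout rate between layers (0 disables).
#' @param training TRUE to sample dropout masks.
#' @return List with `gene` (gene-side output) and `other` (other-side
#'   output; identical to `gene` when symmetric).
#' @export
hgcn_stack <- function(P, X_gene, X_other, layers, symmetric = FALSE,
                       dropout = 0, training = FALSE) {
  Pt <- Matrix::t(P)
  Hg <- X_gene
  Ho <- X_other
  L <- length(layers)
  for (k in seq_len(L)) {
    ly <- layers[[k]]
    if (symmetric) {
      Hg <- hgcn_layer(P, Hg, Hg, ly$theta, ly$W1, ly$b1)
      Ho <- Hg
    } else {
      Hg_new <- hgcn_layer(P, Hg, Ho, ly$theta, ly$W1, ly$b1)
      Ho_new <- hgcn_layer(Pt, Ho, Hg, ly$theta, ly$W1, ly$b1)
      Hg <- Hg_new
      Ho <- Ho_new
    }
    if (k < L) {
      Hg <- g_dropout(Hg, dropout, training)
      Ho <- if (symmetric) Hg else g_dropout(Ho, dropout, training)
    }
  }
  list(gene = Hg, other = Ho)
}

#' Bilinear neighbour-interaction aggregation
#'
#' For every gene `p`, averages the element-wise products of projected
#' features over all unordered pairs from the extended neighbourhood (the
#' gene's outlying-gene neighbours plus the gene itself, self-interactions
#' excluded):
#' \deqn{H^{BA}_p = \frac{1}{b_p} \sum_{i<j \in \tilde N(p)} s_i \odot s_j,
#'       \quad s_i = X(i) W + b, \quad b_p = \tfrac12 \tilde d_p(\tilde d_p - 1)}
#' computed through the identity
#' \eqn{\sum_{i<j} s_i s_j = \tfrac12[(\sum s_i)^2 - \sum s_i^2]}. Genes with
#' an empty neighbourhood (`b_p = 0`) return a zero row.
#'
#' @param A_row \{0,1\} incidence of genes over their outlying-gene
#'   neighbours (n x m).
#' @param X_self Initial gene features (n x F1).
#' @param X_nbr Initial outlying-gene features lifted to F1 (m x F1).
#' @param W Projection weight (F1 x F_out).
#' @param b Bias row vector (1 x F_out).
#' @return n x F_out matrix of bilinear aggregation features.
#' @export
bilinear_aggregate <- function(A_row, X_self, X_nbr, W, b) {
  s_self <- g_add(g_matmul(X_self, W), b)
  s_nbr <- g_add(g_matmul(X_nbr, W), b)
  sum_s <- g_add(s_self, g_spmm(A_row, s_nbr))
  sum_sq <- g_add(g_mul(s_self, s_self), g_spmm(A_row, g_mul(s_nbr, s_nbr)))
  pair_sum <- g_scale(g_sub(g_mul(sum_s, sum_s), sum_sq), 0.5)
  d_ext <- Matrix::rowSums(A_row) + 1
  b_p <- d_ext * (d_ext - 1) / 2
  inv_b <- ifelse(b_p > 0, 1 / b_p, 0)
  g_spmm(Matrix::Diagonal(x = inv_b), pair_sum)
}

#' Convex mix of HGCN and bilinear features
#'
#' `(1 - alpha) * H_P2 + alpha * H_BA`.
#'
#' @param H_P2 HGCN gene features from the gene-outlying network.
#' @param H_BA Bilinear aggregation features of the same shape.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return Mixed feature matrix.
#' @export
mix_bilinear <- function(H_P2, H_BA, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  g_add(g_scale(H_P2, 1 - alpha), g_scale(H_BA, alpha))
}

#' Shared self-attention layer with residual connection
#'
#' Scaled dot-product self-attention over all genes:
#' `Q = H W_Q`, `K = H W_K`, `V = H W_V`,
#' `out = softmax(Q K' / sqrt(d)) V + H` with `d = ncol(W_Q)`. The same
#' projection weights serve the gene features of all three networks. Dropout
#' (rate `dropout`) is applied to the attention weights during training.
#'
#' @param H Gene feature matrix (n x F).
#' @param W_Q,W_K,W_V Projection weights (F x d, with d = F for the residual).
#' @param dropout Attention dropout rate.
#' @param training TRUE to sample the dropout mask.
#' @return n x F attended feature matrix (with residual added).
#' @export
self_attention <- function(H, W_Q, W_K, W_V, dropout = 0, training = FALSE) {
  d <- ncol(ad_value(W_Q))
  Q <- g_matmul(H, W_Q)
  K <- g_matmul(H, W_K)
  V <- g_matmul(H, W_V)
  A <- g_softmax_rows(g_scale(g_matmul(Q, g_transpose(K)), 1 / sqrt(d)))
  A <- g_dropout(A, dropout, training)
  g_add(g_matmul(A, V), H)
}

#' Reduce gene features to one channel with kernel-size-1 convolutions
#'
#' Two successive kernel-size-1 convolutions (per-gene affine maps) with a
#' ReLU between, ending in a single output channel; equivalent to
#' `relu(H W1 + b1) W2 + b2`.
#'
#' @param H n x F feature matrix.
#' @param W1 F x hidden weight; `b1` its 1 x hidden bias.
#' @param W2 hidden x 1 weight; `b2` its 1 x 1 bias.
#' @return n x 1 matrix.
#' @export
conv1d_reduce <- function(H, W1, b1, W2, b2) {
  g_add(g_matmul(g_relu(g_add(g_matmul(H, W1), b1)), W2), b2)
}

# Flattened kernel layout for conv2d_fuse: index (c-1)*9 + (di-1)*3 + dj for
# channel c, vertical tap di (1..3 = rows above/at/below) and horizontal tap
# dj (1..3). The spatial input is n x 1, so after zero padding only the
# centre column dj = 2 overlaps data; the dj = 1, 3 taps multiply zeros.
conv2d_center_index <- function(nch) {
  # one index per (channel, vertical tap) pair, vertical tap varying fastest,
  # matching the column order of the shifted feature matrix in conv2d_fuse
  as.integer(vapply(seq_len(nch), function(c)
    (c - 1L) * 9L + (1:3 - 1L) * 3L + 2L, integer(3L)))
}

#' Fuse per-network gene scalars with a 3x3 2D convolution
#'
#' The per-network n x 1 features are stacked into a `nch x n x 1` image
#' (one channel per network), zero-padded by one on both spatial dimensions,
#' and convolved with a single `nch x 3 x 3` kernel producing one output
#' channel of spatial size n x 1.
#'
#' @param h_list List of `nch` n x 1 matrices (one per enabled network).
#' @param kernel Either a numeric array of dim `c(nch, 3, 3)` or a flattened
#'   `(nch*9) x 1` parameter (column-major taps, see source) as used in
#'   training.
#' @param bias Scalar (or 1 x 1) bias.
#' @return n x 1 fused feature matrix.
#' @export
conv2d_fuse <- function(h_list, kernel, bias) {
  nch <- length(h_list)
  if (nch < 1L || nrow(ad_value(h_list[[1L]])) < 1L)
    stop("conv2d_fuse needs at least one channel with at least one gene")
  feats <- vector("list", 3L * nch)
  pos <- 0L
  for (c in seq_len(nch)) {
    for (di in 1:3) {
      pos <- pos + 1L
      # output row i reads input row i + (di - 2): di=1 row above, di=3 below
      feats[[pos]] <- g_rowshift(h_list[[c]], 2L - di)
    }
  }
  Feat <- do.call(g_cbind, feats)
  if (is_ad(kernel)) {
    w <- ad_subset_rows(kernel, conv2d_center_index(nch))
  } else {
    if (is.array(kernel) && length(dim(kernel)) == 3L) {
      kflat <- numeric(nch * 9L)
      for (c in seq_len(nch)) for (di in 1:3) for (dj in 1:3)
        kflat[(c - 1L) * 9L + (di - 1L) * 3L + dj] <- kernel[c, di, dj]
    } else kflat <- as.numeric(kernel)
    if (length(kflat) != nch * 9L) stop("kernel must have nch*9 entries")
    w <- matrix(kflat[conv2d_center_index(nch)], ncol = 1L)
  }
  b <- if (is_ad(bias)) bias else matrix(as.numeric(bias)[1L], 1L, 1L)
  g_add(g_matmul(Feat, w), b)
}

#' Three-layer perceptron on the original gene features
#'
#' `Linear3(relu(Linear2(relu(Linear1(X)))))`, output width 1.
#'
#' @param X n x F1 original gene features.
#' @param W1,b1,W2,b2,W3,b3 Layer weights and (row-vector) biases.
#' @return n x 1 matrix.
#' @export
mlp_branch <- function(X, W1, b1, W2, b2, W3, b3) {
  h1 <- g_relu(g_add(g_matmul(X, W1), b1))
  h2 <- g_relu(g_add(g_matmul(h1, W2), b2))
  g_add(g_matmul(h2, W3), b3)
}
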