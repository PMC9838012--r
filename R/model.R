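# Model assembly: parameter initialization, the full forward pass over the
# enabled network branches, and unsupervised pre-training on the gene-miRNA
# network.

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

zeros_row <- function(k) matrix(0, 1L, k)

# Channel order of the enabled networks is fixed as (gene-gene,
# gene-outlying, gene-miRNA); the 2D convolution is not permutation
# invariant, so the order is part of the model definition.
enabled_networks <- function(config) {
  c("pp", "po", "pr")[c(config$use_gene_gene, config$use_outlying,
                        config$use_mirna)]
}

#' Initialize all learnable parameters of the model
#'
#' Glorot-uniform weights and zero biases, drawn from the current RNG stream
#' (callers fix the seed). Only parameters of enabled branches are created.
#'
#' @param config A [run_config()].
#' @param F1 Gene attribute width.
#' @param F2 Outlying-gene attribute width.
#' @param F3 miRNA attribute width.
#' @return Named list of parameter matrices.
#' @export
init_model_params <- function(config, F1, F2, F3) {
  dims <- c(F1, config$hidden_dims)
  L <- length(config$hidden_dims)
  hL <- config$hidden_dims[L]
  p <- list()
  for (k in seq_len(L)) {
    p[[paste0("theta_", k)]] <- glorot(dims[k], dims[k + 1L])
    p[[paste0("W1_", k)]] <- glorot(dims[k], dims[k + 1L])
    p[[paste0("b1_", k)]] <- zeros_row(dims[k + 1L])
  }
  if (config$use_outlying) {
    p$lift_O_W <- glorot(F2, F1)
    p$lift_O_b <- zeros_row(F1)
    if (config$use_bilinear) {
      p$bil_W <- glorot(F1, hL)
      p$bil_b <- zeros_row(hL)
    }
  }
  if (config$use_mirna && !config$use_pretrain) {
    p$lift_R_W <- glorot(F3, F1)
    p$lift_R_b <- zeros_row(F1)
  }
  if (config$use_attention) {
    p$att_WQ <- glorot(hL, hL)
    p$att_WK <- glorot(hL, hL)
    p$att_WV <- glorot(hL, hL)
  }
  for (net in enabled_networks(config)) {
    p[[paste0("c1_", net, "_W1")]] <- glorot(hL, config$conv1d_hidden)
    p[[paste0("c1_", net, "_b1")]] <- zeros_row(config$conv1d_hidden)
    p[[paste0("c1_", net, "_W2")]] <- glorot(config$conv1d_hidden, 1L)
    p[[paste0("c1_", net, "_b2")]] <- zeros_row(1L)
  }
  nch <- length(enabled_networks(config))
  p$c2_K <- matrix(stats::runif(nch * 9L, -sqrt(6 / (nch * 9L + 1L)),
                                sqrt(6 / (nch * 9L + 1L))), ncol = 1L)
  p$c2_b <- matrix(0, 1L, 1L)
  m <- config$mlp_hidden
  p$mlp_W1 <- glorot(F1, m[1L]); p$mlp_b1 <- zeros_row(m[1L])
  p$mlp_W2 <- glorot(m[1L], m[2L]); p$mlp_b2 <- zeros_row(m[2L])
  p$mlp_W3 <- glorot(m[2L], 1L); p$mlp_b3 <- zeros_row(1L)
  p
}

wrap_params <- function(params) lapply(params, ad_param)

collect_grads <- function(pnodes) lapply(pnodes, function(p) p$grad)

hgcn_layer_params <- function(params, L) {
  lapply(seq_len(L), function(k) list(
    theta = params[[paste0("theta_", k)]],
    W1 = params[[paste0("W1_", k)]],
    b1 = params[[paste0("b1_", k)]]
  ))
}

#' Full forward pass of the model
#'
#' Runs every enabled branch: parameter-sharing HGCN stacks on the three
#' networks (with the bilinear layer mixed into the gene-outlying branch and
#' the shared self-attention layer on each branch's gene features), the
#' per-branch kernel-1 convolutions, the 3x3 fusion convolution, and the MLP
#' on the original gene features.
#'
#' @param params Named parameter list (plain matrices, or `ad` nodes during
#'   training).
#' @param inputs List with the normalized adjacencies `P_PP`, `P_PO`, `P_PR`,
#'   the raw incidence `A_PO`, and feature matrices `X_P`, `X_O`, `X_P_pre`,
#'   `X_R_pre` (widths F1 except `X_O`).
#' @param config A [run_config()].
#' @param training TRUE enables dropout.
#' @return List with `H_att`, `H_1D` (named per network), `H_2D`, `H_mlp`,
#'   `H_syn`; `ad` nodes when called on a tape, plain matrices otherwise.
#' @export
forward_model <- function(params, inputs, config, training = FALSE) {
  L <- length(config$hidden_dims)
  layers <- hgcn_layer_params(params, L)
  nets <- enabled_networks(config)
  H_gene <- list()

  if (config$use_gene_gene) {
    H_gene$pp <- hgcn_stack(inputs$P_PP, inputs$X_P, inputs$X_P, layers,
                            symmetric = TRUE, dropout = config$dropout_default,
                            training = training)$gene
  }
  if (config$use_outlying) {
    X_O_lift <- g_add(g_matmul(inputs$X_O, params$lift_O_W), params$lift_O_b)
    H_po <- hgcn_stack(inputs$P_PO, inputs$X_P, X_O_lift, layers,
                       dropout = config$dropout_default,
                       training = training)$gene
    if (config$use_bilinear) {
      H_ba <- bilinear_aggregate(inputs$A_PO, inputs$X_P, X_O_lift,
                                 params$bil_W, params$bil_b)
      H_po <- mix_bilinear(H_po, H_ba, config$alpha)
    }
    H_gene$po <- H_po
  }
  if (config$use_mirna) {
    X_R_in <- if (config$use_pretrain) inputs$X_R_pre else
      g_add(g_matmul(inputs$X_R, params$lift_R_W), params$lift_R_b)
    H_gene$pr <- hgcn_stack(inputs$P_PR, inputs$X_P_pre, X_R_in, layers,
                            dropout = config$dropout_default,
                            training = training)$gene
  }

  H_att <- if (config$use_attention) {
    lapply(H_gene, function(H) self_attention(
      H, params$att_WQ, params$att_WK, params$att_WV,
      dropout = config$dropout_attention, training = training))
  } else H_gene

  H_1D <- lapply(stats::setNames(nets, nets), function(net) conv1d_reduce(
    H_att[[net]],
    params[[paste0("c1_", net, "_W1")]], params[[paste0("c1_", net, "_b1")]],
    params[[paste0("c1_", net, "_W2")]], params[[paste0("c1_", net, "_b2")]]))

  H_2D <- conv2d_fuse(unname(H_1D[nets]), params$c2_K, params$c2_b)
  H_mlp <- mlp_branch(inputs$X_P, params$mlp_W1, params$mlp_b1,
                      params$mlp_W2, params$mlp_b2,
                      params$mlp_W3, params$mlp_b3)
  H_syn <- g_add(H_mlp, H_2D)

  list(H_att = H_att, H_1D = H_1D, H_2D = H_2D, H_mlp = H_mlp, H_syn = H_syn)
}

#' Pre-train gene and miRNA features on the gene-miRNA network
#'
#' A standalone two-layer HGCN on the bipartite gene-miRNA network, trained
#' to reconstruct the adjacency by inner-product link prediction with 1:1
#' negative sampling (binary cross-entropy, Adam). The final-layer features
#' of both sides are lifted back to the gene attribute width F1 and returned
#' as `X_P_pre` and `X_R_pre`. With `epochs = 0` the untrained forward pass
#' is returned. Deterministic for a fixed seed.
#'
#' @param A_PR Gene-miRNA adjacency (n x t), nonempty.
#' @param X_P Gene attributes (n x F1).
#' @param X_R miRNA attributes (t x F3).
#' @param hidden_dims Per-layer widths of the pre-training HGCN.
#' @param epochs Training epochs (default 100).
#' @param lr,weight_decay Adam settings.
#' @param seed Integer seed.
#' @return List with `X_P_pre` (n x F1), `X_R_pre` (t x F1), and
#'   `link_scores(pairs)`, a function mapping a 2-column matrix of
#'   (gene, miRNA) index pairs to reconstruction scores in (0, 1).
#' @export
pretrain_gene_mirna <- function(A_PR, X_P, X_R, hidden_dims = c(64L, 32L),
                                epochs = 100L, lr = 0.002,
                                weight_decay = 5e-4, seed = 0L) {
  if (Matrix::nnzero(A_PR) == 0L) stop("gene-miRNA network is empty")
  withr::with_seed(seed, {
    F1 <- ncol(X_P); F3 <- ncol(X_R)
    n <- nrow(A_PR); t_ <- ncol(A_PR)
    P_PR <- normalize_adjacency(A_PR)
    dims <- c(F1, hidden_dims)
    L <- length(hidden_dims)
    hL <- hidden_dims[L]
    params <- list(lift_R_W = glorot(F3, F1), lift_R_b = zeros_row(F1),
                   out_P_W = glorot(hL, F1), out_P_b = zeros_row(F1),
                   out_R_W = glorot(hL, F1), out_R_b = zeros_row(F1))
    for (k in seq_len(L)) {
      params[[paste0("theta_", k)]] <- glorot(dims[k], dims[k + 1L])
      params[[paste0("W1_", k)]] <- glorot(dims[k], dims[k + 1L])
      params[[paste0("b1_", k)]] <- zeros_row(dims[k + 1L])
    }

    fwd <- function(pars, training) {
      X_R_lift <- g_add(g_matmul(X_R, pars$lift_R_W), pars$lift_R_b)
      hs <- hgcn_stack(P_PR, X_P, X_R_lift, hgcn_layer_params(pars, L),
                       dropout = if (training) 0.5 else 0, training = training)
      list(
        X_P_pre = g_add(g_matmul(hs$gene, pars$out_P_W), pars$out_P_b),
        X_R_pre = g_add(g_matmul(hs$other, pars$out_R_W), pars$out_R_b)
      )
    }

    edges <- Matrix::which(A_PR != 0, arr.ind = TRUE)
    n_edge <- nrow(edges)
    opt <- adam_init(params, lr = lr, weight_decay = weight_decay)
    ones_f <- matrix(1, F1, 1L)

    for (ep in seq_len(epochs)) {
      neg <- sample_bipartite_negatives(A_PR, n_edge)
      pairs <- rbind(edges, neg)
      y <- c(rep(1, n_edge), rep(0, n_edge))
      tape_start()
      pn <- wrap_params(params)
      out <- fwd(pn, training = TRUE)
      dots <- ad_matmul(ad_mul(ad_subset_rows(out$X_P_pre, pairs[, 1L]),
                               ad_subset_rows(out$X_R_pre, pairs[, 2L])),
                        ones_f)
      loss <- ad_bce(ad_clamp(ad_sigmoid(dots), 1e-7, 1 - 1e-7), y)
      if (!is.finite(loss$value[1L]))
        stop("non-finite pre-training loss at epoch ", ep)
      ad_backward(loss)
      st <- adam_step(opt, params, collect_grads(pn))
      opt <- st$opt; params <- st$params
    }
    .ad$tape <- NULL

    out <- fwd(params, training = FALSE)
    XPp <- ad_value(out$X_P_pre)
    XRp <- ad_value(out$X_R_pre)
    list(
      X_P_pre = XPp,
      X_R_pre = XRp,
      link_scores = function(pairs) {
        stats::plogis(rowSums(XPp[pairs[, 1L], , drop = FALSE] *
                              XRp[pairs[, 2L], , drop = FALSE]))
      }
    )
  })
}

# Uniform sample of `k` non-edges (i, j) of a bipartite adjacency.
sample_bipartite_negatives <- function(A, k) {
  n <- nrow(A); t_ <- ncol(A)
  if (n * t_ - Matrix::nnzero(A) < k)
    stop("graph too dense to sample the requested number of non-edges")
  out <- matrix(0L, 0L, 2L)
  while (nrow(out) < k) {
    need <- k - nrow(out)
    i <- sample.int(n, 2L * need, replace = TRUE)
    j <- sample.int(t_, 2L * need, replace = TRUE)
    keep <- A[cbind(i, j)] == 0
    out <- rbind(out, cbind(i[keep], j[keep]))
  }
  out[seq_len(k), , drop = FALSE]
}
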