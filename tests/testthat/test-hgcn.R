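test_that("hgcn_layer reduces to known closed forms", {
  set.seed(20)
  X <- rand_mat(5, 4)
  theta <- rand_mat(4, 3); W1 <- rand_mat(4, 3); b1 <- matrix(0, 1, 3)
  # zero adjacency and zero bias: both aggregates vanish
  out <- hgcn_layer(matrix(0, 5, 5), X, X, theta, W1, b1)
  expect_equal(out, matrix(0, 5, 3), ignore_attr = TRUE)
  # identity theta, zero W1, identity activation: plain propagation P X
  P <- normalize_adjacency(rand_symmetric(5, 0.5))
  out <- hgcn_layer(P, X, X, diag(4), matrix(0, 4, 4), matrix(0, 1, 4),
                    activation = "identity")
  expect_equal(out, as.matrix(P %*% X), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hgcn_layer matches the per-node loop oracle on random graphs", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:7, 1); m <- sample(3:6, 1); fi <- 4; fo <- 3
    P <- as.matrix(normalize_adjacency(rand_binary(n, m, 0.4)))
    Xs <- rand_mat(n, fi); Xn <- rand_mat(m, fi)
    theta <- rand_mat(fi, fo); W1 <- rand_mat(fi, fo); b1 <- rand_mat(1, fo)
    expect_lt(max(abs(hgcn_layer(P, Xs, Xn, theta, W1, b1) -
                      hgcn_layer_oracle(P, Xs, Xn, theta, W1, b1))), 1e-6)
  }
})

test_that("hgcn_stack composes layers with the stated widths", {
  set.seed(22)
  n <- 6; m <- 5
  P <- normalize_adjacency(Matrix::Matrix(rand_binary(n, m, 0.4), sparse = TRUE))
  Xg <- rand_mat(n, 4); Xo <- rand_mat(m, 4)
  ly1 <- list(theta = rand_mat(4, 3), W1 = rand_mat(4, 3), b1 = rand_mat(1, 3))
  # L = 1 equals a single layer call, both directions
  st <- hgcn_stack(P, Xg, Xo, list(ly1))
  expect_equal(st$gene, hgcn_layer(P, Xg, Xo, ly1$theta, ly1$W1, ly1$b1))
  expect_equal(st$other, hgcn_layer(Matrix::t(P), Xo, Xg, ly1$theta, ly1$W1, ly1$b1))
  # two layers: widths follow hidden_dims; output has the layer-2 width
  ly2 <- list(theta = rand_mat(3, 2), W1 = rand_mat(3, 2), b1 = rand_mat(1, 2))
  st2 <- hgcn_stack(P, Xg, Xo, list(ly1, ly2))
  expect_equal(dim(st2$gene), c(n, 2))
  expect_equal(dim(st2$other), c(m, 2))
  # no dropout: repeated evaluation is bit-identical
  expect_identical(st2$gene, hgcn_stack(P, Xg, Xo, list(ly1, ly2))$gene)
})

test_that("bilinear aggregation matches pair enumeration and its guards", {
  set.seed(23)
  # single neighbour: output is exactly s_self * s_nbr
  A <- matrix(c(1, 0), 1, 2)
  Xs <- rand_mat(1, 3); Xn <- rand_mat(2, 3)
  W <- rand_mat(3, 2); b <- rand_mat(1, 2)
  s <- function(x) as.numeric(x %*% W + b)
  expect_equal(as.numeric(bilinear_aggregate(A, Xs, Xn, W, b)),
               s(Xs[1, ]) * s(Xn[1, ]), tolerance = 1e-10)
  # isolated gene: b_P = 0 guard gives a zero row
  expect_equal(as.numeric(bilinear_aggregate(matrix(0, 1, 2), Xs, Xn, W, b)),
               c(0, 0))
  # star of 6 neighbours and random instances: fast identity == double loop
  for (rep in 1:5) {
    n <- sample(3:6, 1); m <- 6
    A <- rand_binary(n, m, 0.5)
    Xs <- rand_mat(n, 4); Xn <- rand_mat(m, 4)
    W <- rand_mat(4, 3); b <- rand_mat(1, 3)
    expect_lt(max(abs(bilinear_aggregate(A, Xs, Xn, W, b) -
                      bilinear_oracle(A, Xs, Xn, W, b))), 1e-6)
  }
})

test_that("bilinear mixing is the stated convex combination", {
  set.seed(24)
  H <- rand_mat(4, 3); B <- rand_mat(4, 3)
  expect_equal(mix_bilinear(H, B, 0), H)
  expect_equal(mix_bilinear(H, B, 1), B)
  expect_equal(mix_bilinear(H, B, 0.2), 0.8 * H + 0.2 * B)
  expect_error(mix_bilinear(H, B, 1.2), "alpha")
})

test_that("self-attention matches the loop oracle and its special cases", {
  set.seed(25)
  # n = 1 with identity values: softmax weight 1, residual doubles the row
  H <- rand_mat(1, 3)
  expect_equal(self_attention(H, diag(3), diag(3), diag(3)), 2 * H)
  # zero queries/keys: uniform averaging of V plus residual, exactly
  H <- rand_mat(5, 3); WV <- rand_mat(3, 3)
  out <- self_attention(H, matrix(0, 3, 3), matrix(0, 3, 3), WV)
  V <- H %*% WV
  expect_equal(out, matrix(colMeans(V), 5, 3, byrow = TRUE) + H)
  # random instances against the scalar-loop oracle; rows of the attention
  # matrix sum to one by construction of the oracle comparison
  for (rep in 1:5) {
    H <- rand_mat(sample(3:6, 1), 4)
    WQ <- rand_mat(4, 4); WK <- rand_mat(4, 4); WV <- rand_mat(4, 4)
    expect_lt(max(abs(self_attention(H, WQ, WK, WV) -
                      attention_oracle(H, WQ, WK, WV))), 1e-6)
  }
})

test_that("softmax rows of the attention weights sum to one", {
  ns <- asNamespace("drivergcn")
  set.seed(26)
  S <- ns$g_softmax_rows(rand_mat(7, 7))
  expect_equal(rowSums(S), rep(1, 7), tolerance = 1e-6)
})

test_that("parameter sharing ties all network branches to one tensor", {
  d <- tiny_dataset()
  cfg <- tiny_config()
  inputs <- prepare_model_inputs(d, cfg)
  withr::with_seed(1, {
    params <- init_model_params(cfg, d$attrs$F1, d$attrs$F2, d$attrs$F3)
  })
  out1 <- forward_model(params, inputs, cfg)
  params2 <- params
  params2$theta_1 <- params2$theta_1 * 1.1
  out2 <- forward_model(params2, inputs, cfg)
  # perturbing the shared layer-1 weight moves every branch's features
  for (net in c("pp", "po", "pr"))
    expect_gt(max(abs(out1$H_att[[net]] - out2$H_att[[net]])), 0)
})

test_that("layer outputs stay finite across random trials", {
  set.seed(27)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    H <- rand_mat(n, 3, sd = 5)
    out <- self_attention(H, rand_mat(3, 3), rand_mat(3, 3), rand_mat(3, 3))
    P <- normalize_adjacency(rand_symmetric(n, 0.5))
    out2 <- hgcn_layer(P, H, H, rand_mat(3, 2), rand_mat(3, 2), rand_mat(1, 2))
    expect_true(all(is.finite(out)) && all(is.finite(out2)))
  }
})

test_that("gene-miRNA pre-training reconstructs a structured bipartite graph", {
  set.seed(28)
  n <- 30; t_ <- 10
  blockA <- outer(rep(c(TRUE, FALSE), c(15, 15)), rep(c(TRUE, FALSE), c(5, 5)), "&")
  blockB <- outer(rep(c(FALSE, TRUE), c(15, 15)), rep(c(FALSE, TRUE), c(5, 5)), "&")
  p <- ifelse(blockA | blockB, 0.6, 0.05)
  A_PR <- Matrix::Matrix((matrix(runif(n * t_), n, t_) < p) * 1, sparse = TRUE)
  X_P <- rand_mat(n, 8); X_R <- rand_mat(t_, 5)
  pre <- pretrain_gene_mirna(A_PR, X_P, X_R, hidden_dims = c(16L, 8L),
                             epochs = 100L, seed = 2)
  expect_equal(dim(pre$X_P_pre), c(n, 8))
  expect_equal(dim(pre$X_R_pre), c(t_, 8))
  edges <- Matrix::which(A_PR != 0, arr.ind = TRUE)
  non <- Matrix::which(A_PR == 0, arr.ind = TRUE)
  set.seed(3)
  non <- non[sample(nrow(non), nrow(edges)), ]
  sc <- pre$link_scores(rbind(edges, non))
  y <- rep(c(1, 0), each = nrow(edges))
  expect_gte(evaluate_scores(sc, y)["auc"], 0.8)
})

test_that("pre-training with zero epochs returns the untrained lift", {
  set.seed(29)
  A <- Matrix::Matrix(rand_binary(8, 5, 0.4), sparse = TRUE)
  p1 <- pretrain_gene_mirna(A, rand_mat(8, 6), rand_mat(5, 4),
                            hidden_dims = c(4L, 3L), epochs = 0L, seed = 9)
  set.seed(30)  # pre-training reseeds internally; stream position irrelevant
  p2 <- pretrain_gene_mirna(A, rand_mat(8, 6), rand_mat(5, 4),
                            hidden_dims = c(4L, 3L), epochs = 0L, seed = 9)
  expect_true(all(is.finite(p1$X_P_pre)))
  expect_equal(dim(p1$X_P_pre), c(8, 6))
})

test_that("disabling pre-training passes original features through", {
  d <- tiny_dataset()
  cfg <- tiny_config(use_pretrain = FALSE)
  inputs <- prepare_model_inputs(d, cfg)
  expect_identical(inputs$X_P_pre, d$attrs$X_P)
  expect_null(inputs$X_R_pre)
  cfg2 <- tiny_config()
  inputs2 <- prepare_model_inputs(d, cfg2)
  expect_false(identical(inputs2$X_P_pre, d$attrs$X_P))
  expect_equal(ncol(inputs2$X_R_pre), d$attrs$F1)
})
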