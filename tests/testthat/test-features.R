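test_that("biological features have the per-context layout and [0,1] range", {
  set.seed(8)
  n <- 30
  make <- function(C) suppressMessages(gene_biological_features(
    matrix(runif(n * C), n, C), matrix(runif(n * C), n, C),
    matrix(runif(n * C), n, C)))
  expect_equal(ncol(make(16)), 48)  # pan-cancer layout
  expect_equal(ncol(make(1)), 3)   # single-cancer layout
  X <- make(4)
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(unname(apply(X, 2, min)), rep(0, 12))
  expect_equal(unname(apply(X, 2, max)), rep(1, 12))
})

test_that("min-max normalization is the forced affine map", {
  expect_equal(as.numeric(minmax_normalize(matrix(c(0.2, 0.4, 0.6), 3))),
               c(0, 0.5, 1))
  expect_message(out <- minmax_normalize(matrix(2, 3, 1)), "constant")
  expect_equal(as.numeric(out), c(0, 0, 0))
})

test_that("z-scores use the population sd and drive outlying detection", {
  # row (10, 10, 10, 30): mean 15, population sd sqrt(75), z_last = 15/sqrt(75)
  x <- matrix(c(10, 10, 10, 30), 1, 4)
  det <- detect_outlying_genes(list(ctx = x), threshold = 1.7)
  expect_equal(det$z$ctx[1, 4], 15 / sqrt(75))
  expect_true(det$outlying[1])
  # with four samples |z| is capped at sqrt(3), so threshold 2 cannot fire
  expect_false(detect_outlying_genes(list(ctx = x), threshold = 2)$outlying[1])

  # constant rows never become outlying
  cst <- matrix(5, 2, 6)
  det2 <- detect_outlying_genes(list(ctx = cst), threshold = 0.1)
  expect_equal(det2$z$ctx, matrix(0, 2, 6), ignore_attr = TRUE)
  expect_false(any(det2$outlying))

  # infinite threshold empties the outlying set; detection is monotone in it
  set.seed(9)
  e <- list(a = rand_mat(40, 12), b = rand_mat(40, 12))
  expect_false(any(detect_outlying_genes(e, threshold = Inf)$outlying))
  low <- detect_outlying_genes(e, threshold = 1.5)$outlying
  high <- detect_outlying_genes(e, threshold = 2.5)$outlying
  expect_true(all(which(high) %in% which(low)))
})

test_that("outlying-gene features are mean z and exceedance frequency", {
  z <- matrix(c(0.5, 2.5, -2.5, 0.1, 0.2, 0.3, 0.1, 0.8), 1)
  out <- outlying_gene_features(list(ctx = z), threshold = 2)
  expect_equal(unname(out[1, "zmean_1"]), mean(z))
  expect_equal(unname(out[1, "freq_1"]), 2 / 8)  # outlying in 2 of 8 samples
  zz <- replicate(16, matrix(rnorm(10), 5, 2), simplify = FALSE)
  expect_equal(ncol(outlying_gene_features(zz)), 32)  # pan-cancer
  expect_equal(ncol(outlying_gene_features(zz[1])), 2)  # single-cancer
})

test_that("GIP kernel matches its closed form and brute-force oracle", {
  # hand case: profiles (1,0) and (0,1): gamma = 1, K12 = exp(-2)
  K <- gip_kernel(rbind(c(1, 0), c(0, 1)))
  expect_equal(K[1, 2], exp(-2), tolerance = 1e-9)
  expect_equal(diag(K), c(1, 1))

  expect_equal(gip_kernel(rbind(c(1, 1), c(1, 1)))[1, 2], 1)  # identical rows

  set.seed(10)
  Pm <- rand_binary(20, 8, 0.4)
  K <- gip_kernel(Pm)
  expect_lt(max(abs(K - gip_oracle(Pm))), 1e-10)
  expect_identical(K, t(K))
  expect_true(all(K > 0 & K <= 1))

  expect_warning(K0 <- gip_kernel(matrix(0, 3, 4)), "identity")
  expect_equal(K0, diag(3))
})

test_that("topological embeddings are deterministic and structure aware", {
  set.seed(12)
  # two 8-cliques joined by one edge, plus an isolated node
  n <- 17
  A <- matrix(0, n, n)
  A[1:8, 1:8] <- 1; A[9:16, 9:16] <- 1
  diag(A) <- 0
  A[1, 9] <- A[9, 1] <- 1
  e1 <- suppressMessages(gene_topological_features(A, dim = 8, seed = 3))
  e2 <- suppressMessages(gene_topological_features(A, dim = 8, seed = 3))
  expect_identical(e1, e2)  # same seed, bit-identical
  expect_equal(ncol(e1), 8)
  expect_equal(unname(e1[17, ]), rep(0, 8))  # isolated node

  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- mean(c(cos(e1[2, ], e1[3, ]), cos(e1[4, ], e1[5, ]),
                   cos(e1[10, ], e1[11, ]), cos(e1[12, ], e1[13, ])))
  between <- mean(c(cos(e1[2, ], e1[10, ]), cos(e1[3, ], e1[12, ]),
                    cos(e1[5, ], e1[14, ]), cos(e1[6, ], e1[15, ])))
  expect_gt(within, between)
})

test_that("miRNA features stack z-scores, expression, similarities, degree", {
  set.seed(13)
  t_ <- 10
  mkctx <- function(C) replicate(C, rand_mat(t_, 6), simplify = FALSE)
  K <- gip_kernel(rand_binary(t_, 12, 0.3))
  A_PR <- Matrix::Matrix(rand_binary(9, t_, 0.4), sparse = TRUE)
  X16 <- mirna_features(mkctx(16), mkctx(16), K, A_PR, sim_dim = 16)
  expect_equal(ncol(X16), 49)  # pan-cancer: 16 + 16 + 16 + 1
  X1 <- mirna_features(mkctx(1), mkctx(1), K, A_PR, sim_dim = 1)
  expect_equal(ncol(X1), 4)    # single-cancer layout
  expect_equal(unname(X16[, "degree"]), unname(Matrix::colSums(A_PR)))
  # degree feature counts connected genes
  expect_equal(unname(X16[3, "degree"]), sum(A_PR[, 3]))
})
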