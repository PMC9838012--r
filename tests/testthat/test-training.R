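test_that("node BCE hits its analytic values and the loop oracle", {
  expect_lt(node_bce(c(1, 0), c(1, 0)), 1e-6)            # perfect fit
  expect_equal(node_bce(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-9)
  set.seed(50)
  p <- runif(30); y <- rbinom(30, 1, 0.5)
  expect_equal(node_bce(p, y), bce_oracle(p, y), tolerance = 1e-10)
  expect_error(node_bce(numeric(0), numeric(0)), "empty")
})

test_that("link reconstruction is a lazy symmetric sigmoid inner product", {
  H <- matrix(c(0, 1, log(3)), 3, 1)
  expect_equal(link_reconstruction(H, cbind(1, 2)), 0.5)       # zero feature
  expect_equal(link_reconstruction(matrix(c(1, log(3)), 2, 1), cbind(1, 2)),
               plogis(log(3)))                                  # = 0.75
  set.seed(51)
  H <- rand_mat(6, 1)
  pairs <- cbind(sample(6, 10, TRUE), sample(6, 10, TRUE))
  expect_equal(link_reconstruction(H, pairs),
               link_reconstruction(H, pairs[, 2:1]))            # symmetry
})

test_that("link BCE uses the edge-count divisor", {
  # constant 0.5 scores with |Neg| = |E|: each sum contributes |E| log 2
  expect_equal(link_bce(rep(0.5, 7), rep(0.5, 7)), 2 * log(2), tolerance = 1e-9)
  expect_lt(link_bce(rep(1, 5), rep(0, 5)), 1e-5)  # perfect reconstruction
  set.seed(52)
  pe <- runif(20); pn <- runif(20)
  oracle <- -(sum(log(pmax(pe, 1e-7))) + sum(log(pmax(1 - pn, 1e-7)))) / 20
  expect_equal(link_bce(pe, pn), oracle, tolerance = 1e-10)
})

test_that("the total loss is the stated weighted sum", {
  expect_equal(total_loss(1, 2, 3, 0.1, 0.01), 1.23)
  expect_equal(total_loss(5, 2, 3, 0, 0), 5)
  cfg <- run_config()
  expect_equal(cfg$omega1, 0.1)
  expect_equal(cfg$omega2, 0.01)
  expect_equal(cfg$alpha, 0.2)
})

test_that("negative sampling never returns edges or self-pairs", {
  set.seed(53)
  A <- Matrix::Matrix(rand_symmetric(12, 0.3), sparse = TRUE)
  for (rep in 1:20) {
    neg <- sample_gene_negatives(A, 15)
    expect_true(all(neg[, 1] < neg[, 2]))
    expect_true(all(A[neg] == 0))
  }
  dense <- Matrix::Matrix(1 - diag(5), sparse = TRUE)
  expect_error(sample_gene_negatives(dense, 3), "dense")
})

test_that("AUC and AUPRC match pair enumeration", {
  expect_equal(unname(evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))),
               c(1, 1))
  # (0.9, 0.8, 0.3) with labels (1, 0, 1): one of two pos-neg pairs correct
  expect_equal(unname(evaluate_scores(c(0.9, 0.8, 0.3), c(1, 0, 1))["auc"]),
               0.5)
  # ties get half credit
  expect_equal(unname(evaluate_scores(c(0.5, 0.5), c(1, 0))["auc"]), 0.5)
  # random scores concentrate near 0.5
  set.seed(54)
  aucs <- replicate(20, evaluate_scores(runif(400), rbinom(400, 1, 0.3))["auc"])
  expect_lt(max(abs(aucs - 0.5)), 0.1)
  expect_error(evaluate_scores(runif(5), rep(1, 5)), "both classes")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(56)
  for (rep in 1:5) {
    s <- runif(80)
    y <- rbinom(80, 1, 0.4)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(unname(evaluate_scores(s, y)["auc"]), ref, tolerance = 1e-12)
  }
})

test_that("average precision agrees with an explicit running-precision loop", {
  set.seed(55)
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  ap <- evaluate_scores(s, y)["auprc"]
  ord <- order(-s)
  yo <- y[ord]; hits <- 0; acc <- 0
  for (k in seq_along(yo)) {
    if (yo[k] == 1) { hits <- hits + 1; acc <- acc + hits / k }
  }
  expect_equal(unname(ap), acc / sum(y), tolerance = 1e-12)
})

test_that("training runs end to end, improves, and is seed-deterministic", {
  d <- tiny_dataset()
  cfg <- tiny_config(epochs = 30L)
  fit <- train_model(d, cfg)
  expect_true(all(is.finite(fit$loss_history)))
  expect_lt(fit$loss_history[30, "total"], fit$loss_history[1, "total"])
  fit2 <- train_model(d, cfg)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$scores, fit2$scores)
  expect_error(train_model(d, cfg, train_genes = d$labels$positives),
               "positive and one negative")
})

test_that("cross-validation partitions, stratifies, and covers all genes", {
  d <- tiny_dataset()
  cfg <- tiny_config(epochs = 3L)
  cv <- suppressWarnings(cross_validate(d, cfg))
  labelled <- c(d$labels$positives, d$labels$negatives)
  # every labelled gene in exactly one test fold, scored exactly once
  expect_setequal(names(cv$fold_of), labelled)
  expect_false(anyNA(cv$oof_scores))
  expect_setequal(names(cv$oof_scores), labelled)
  # stratification: per-fold positive count within 1 of the balanced share
  pos_per_fold <- table(cv$fold_of[d$labels$positives])
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
})

test_that("ablation variants change the combiner arity as specified", {
  cfg <- tiny_config()
  expect_error(apply_ablation(cfg, "bogus"), "genes_only")
  arity <- function(v) length(drivergcn:::enabled_networks(apply_ablation(cfg, v))) + 2L
  expect_equal(arity("full"), 5L)
  expect_equal(arity("genes_only"), 3L)
  expect_equal(arity("gene_mirna"), 4L)
  no_att <- apply_ablation(cfg, "no_attention")
  expect_false(no_att$use_attention)
  no_lr <- apply_ablation(cfg, "no_lr")
  expect_equal(no_lr$combiner, "sigmoid_sum")
  # excluding the gene-gene network drops the link loss term
  d <- tiny_dataset()
  fit <- suppressWarnings(train_model(d, apply_ablation(tiny_config(epochs = 2L),
                                                        "outlying_mirna")))
  expect_true(all(is.na(fit$loss_history[, "link"])))
  expect_null(fit$link_audit)
})

test_that("attention bypass leaves branch features untouched", {
  d <- tiny_dataset()
  cfg <- apply_ablation(tiny_config(), "no_attention")
  inputs <- prepare_model_inputs(d, cfg)
  params <- withr::with_seed(2, init_model_params(cfg, d$attrs$F1,
                                                  d$attrs$F2, d$attrs$F3))
  out <- forward_model(params, inputs, cfg)
  expect_null(params$att_WQ)
  # H_att is the HGCN output itself under the bypass
  expect_equal(dim(out$H_att$pp), c(d$bundle$n, cfg$hidden_dims[2]))
})
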