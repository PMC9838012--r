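# Losses, negative sampling, the optimization loop, cross-validation,
# metrics and ablation orchestration.

BCE_EPS <- 1e-7

#' Binary cross-entropy over labelled genes
#'
#' `-(1/n) * sum(y*log(p) + (1-y)*log(1-p))` with scores clamped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param scores Predicted probabilities for the labelled genes.
#' @param labels 0/1 vector of the same length.
#' @return Scalar loss.
#' @export
node_bce <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty label set")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  p <- pmin(pmax(scores, BCE_EPS), 1 - BCE_EPS)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# Tape version of the same mean BCE; `p` is an ad node already clamped.
ad_bce <- function(p, y) {
  k <- length(y)
  ymat <- matrix(y, ncol = 1L)
  term <- ad_add(ad_mul(ad_log(p), ymat),
                 ad_mul(ad_log(ad_sub(matrix(1, k, 1L), p)), 1 - ymat))
  ad_scale(ad_sum(term), -1 / k)
}

#' Link reconstruction scores from gene features
#'
#' `a_hat[i, j] = sigmoid(<h_i, h_j>)` evaluated lazily for the requested
#' pairs only; the n x n reconstructed adjacency is never materialized.
#'
#' @param H Gene feature matrix (n x k; the model uses the n x 1 gene-gene
#'   branch output).
#' @param pairs Two-column integer matrix of gene index pairs.
#' @return Vector of reconstruction scores in (0, 1).
#' @export
link_reconstruction <- function(H, pairs) {
  H <- as.matrix(H)
  stats::plogis(rowSums(H[pairs[, 1L], , drop = FALSE] *
                        H[pairs[, 2L], , drop = FALSE]))
}

#' Link prediction binary cross-entropy
#'
#' `-(1/|E|) * (sum_E log a_hat + sum_Neg log(1 - a_hat))`; the divisor is
#' the edge count, so with `|Neg| = |E|` and all scores 0.5 the loss is
#' `2 log 2`.
#'
#' @param a_hat_edges Reconstruction scores on the observed edges E.
#' @param a_hat_neg Reconstruction scores on the sampled non-edges.
#' @return Scalar loss.
#' @export
link_bce <- function(a_hat_edges, a_hat_neg) {
  pe <- pmin(pmax(a_hat_edges, BCE_EPS), 1 - BCE_EPS)
  pn <- pmin(pmax(a_hat_neg, BCE_EPS), 1 - BCE_EPS)
  -(sum(log(pe)) + sum(log(1 - pn))) / length(a_hat_edges)
}

#' Weighted multi-task loss
#'
#' `L_total = L_n + omega1 * L_n1 + omega2 * L_r`.
#'
#' @param l_n Node loss on the synthesis feature.
#' @param l_n1 Node loss on the fused (2D-convolution) feature.
#' @param l_r Link reconstruction loss.
#' @param omega1,omega2 Loss weights (defaults 0.1 and 0.01).
#' @return Scalar total loss.
#' @export
total_loss <- function(l_n, l_n1, l_r, omega1 = 0.1, omega2 = 0.01) {
  l_n + omega1 * l_n1 + omega2 * l_r
}

#' Sample non-edges of a symmetric gene-gene network
#'
#' Uniform unordered pairs (i < j) with `A[i, j] == 0`; self-pairs and
#' existing edges are never returned.
#'
#' @param A Symmetric \{0,1\} adjacency.
#' @param k Number of non-edges to draw.
#' @return k x 2 integer matrix.
#' @export
sample_gene_negatives <- function(A, k) {
  n <- nrow(A)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs - Matrix::nnzero(A) / 2 < k)
    stop("graph too dense to sample the requested number of non-edges")
  out <- matrix(0L, 0L, 2L)
  while (nrow(out) < k) {
    need <- k - nrow(out)
    i <- sample.int(n, 2L * need, replace = TRUE)
    j <- sample.int(n, 2L * need, replace = TRUE)
    keep <- i < j & A[cbind(i, j)] == 0
    out <- rbind(out, cbind(i[keep], j[keep]))
  }
  out[seq_len(k), , drop = FALSE]
}

#' AUC and area under the precision-recall curve
#'
#' AUC is the Mann-Whitney rank statistic over all positive-negative pairs
#' with 0.5 credit for ties; AUPRC is average precision (step-wise summation
#' without interpolation).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 vector of the same length; both classes must be present.
#' @return Named vector `c(auc = ..., auprc = ...)`.
#' @export
evaluate_scores <- function(scores, labels) {
  pos <- labels == 1
  if (!any(pos) || all(pos)) stop("evaluation needs both classes")
  r <- rank(scores)  # average ranks give 0.5 credit to ties
  np <- sum(pos); nn <- sum(!pos)
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-scores)
  yo <- labels[ord]
  prec <- cumsum(yo) / seq_along(yo)
  auprc <- sum(prec * yo) / np
  c(auc = auc, auprc = auprc)
}

#' Bundle networks, attributes and labels into a model-ready dataset
#'
#' @param bundle A [network_bundle()].
#' @param attrs An [attribute_set()].
#' @param labels A [labeled_gene_set()].
#' @return An object of class `driver_dataset`.
#' @export
driver_dataset <- function(bundle, attrs, labels) {
  stopifnot(inherits(bundle, "network_bundle"),
            inherits(attrs, "attribute_set"),
            inherits(labels, "labeled_gene_set"))
  if (nrow(attrs$X_P) != bundle$n || labels$index$n != bundle$n)
    stop("gene dimensions of networks, attributes and labels disagree")
  structure(list(bundle = bundle, attrs = attrs, labels = labels),
            class = "driver_dataset")
}

#' Prepare the constant model inputs (including pre-training)
#'
#' Runs the gene-miRNA pre-training when enabled and assembles the input
#' list consumed by [forward_model()]. Called once per dataset; the result
#' can be shared across cross-validation folds since pre-training uses no
#' labels.
#'
#' @param dataset A [driver_dataset()].
#' @param config A [run_config()].
#' @return Input list for [forward_model()].
#' @export
prepare_model_inputs <- function(dataset, config) {
  b <- dataset$bundle
  a <- dataset$attrs
  inputs <- list(P_PP = b$P_PP, P_PO = b$P_PO, P_PR = b$P_PR, A_PO = b$A_PO,
                 X_P = a$X_P, X_O = a$X_O, X_R = a$X_R,
                 X_P_pre = a$X_P, X_R_pre = NULL)
  if (config$use_mirna && config$use_pretrain) {
    pre <- pretrain_gene_mirna(
      b$A_PR, a$X_P, a$X_R,
      hidden_dims = pmin(config$hidden_dims, 64L),
      epochs = config$pretrain_epochs,
      lr = config$learning_rate, weight_decay = config$weight_decay,
      seed = config$seed + 7L)
    inputs$X_P_pre <- pre$X_P_pre
    inputs$X_R_pre <- pre$X_R_pre
    inputs$pretrain <- pre
  }
  inputs
}

#' Train the full model
#'
#' Full-graph forward pass per epoch through all enabled branches, Adam on
#' the weighted multi-task loss (node BCE on the synthesis feature, node BCE
#' on the fused feature, link reconstruction BCE on the gene-gene network
#' with per-epoch 1:1 negative resampling). Losses use only the labelled
#' training genes; unlabeled genes participate in the graphs only. After
#' training, the five feature columns are computed in evaluation mode and
#' the combiner is fitted on the training genes. Deterministic for a fixed
#' `config$seed`.
#'
#' @param dataset A [driver_dataset()].
#' @param config A [run_config()].
#' @param train_genes Character vector of labelled genes to train on
#'   (default: all labelled genes).
#' @param inputs Optional precomputed [prepare_model_inputs()] result.
#' @return An object of class `driver_fit` with elements `params`, `config`,
#'   `features` (n x (branches + 2) matrix), `scores` (per-gene driver
#'   probabilities), `lr` (combiner weights, or NULL), `loss_history`,
#'   `link_audit` (held-out link AUC, or NULL).
#' @export
train_model <- function(dataset, config, train_genes = NULL, inputs = NULL) {
  validate_run_config(config)
  withr::with_seed(config$seed, {
    if (is.null(inputs)) inputs <- prepare_model_inputs(dataset, config)
    labels <- dataset$labels
    y <- label_vector(labels)
    if (is.null(train_genes)) train_genes <- c(labels$positives, labels$negatives)
    train_idx <- sort(match(train_genes, labels$index$ids))
    if (anyNA(train_idx)) stop("train_genes must be indexed genes")
    y_train <- y[train_idx]
    if (anyNA(y_train)) stop("train_genes must all be labelled")
    if (!any(y_train == 1) || !any(y_train == 0))
      stop("training needs at least one positive and one negative gene")

    params <- init_model_params(config, dataset$attrs$F1, dataset$attrs$F2,
                                dataset$attrs$F3)
    opt <- adam_init(params, lr = config$learning_rate,
                     weight_decay = config$weight_decay)

    use_link <- config$use_gene_gene
    edges <- if (use_link) upper_edges(dataset$bundle$A_PP) else NULL
    holdout <- NULL
    if (use_link && config$link_holdout > 0 && nrow(edges) > 1L) {
      n_hold <- max(1L, floor(config$link_holdout * nrow(edges)))
      hold_id <- sample.int(nrow(edges), n_hold)
      holdout <- edges[hold_id, , drop = FALSE]
      edges <- edges[-hold_id, , drop = FALSE]
    }

    loss_history <- matrix(NA_real_, config$epochs, 4L,
                           dimnames = list(NULL, c("total", "node", "node1", "link")))
    for (ep in seq_len(config$epochs)) {
      tape_start()
      pn <- wrap_params(params)
      out <- forward_model(pn, inputs, config, training = TRUE)
      p_syn <- ad_clamp(ad_sigmoid(ad_subset_rows(out$H_syn, train_idx)),
                        BCE_EPS, 1 - BCE_EPS)
      l_n <- ad_bce(p_syn, y_train)
      p_2d <- ad_clamp(ad_sigmoid(ad_subset_rows(out$H_2D, train_idx)),
                       BCE_EPS, 1 - BCE_EPS)
      l_n1 <- ad_bce(p_2d, y_train)
      loss <- ad_add(l_n, ad_scale(l_n1, config$omega1))
      l_r_val <- NA_real_
      if (use_link && nrow(edges) > 0L) {
        neg <- sample_gene_negatives(dataset$bundle$A_PP, nrow(edges))
        pairs <- rbind(edges, neg)
        hp <- out$H_1D$pp
        dots <- ad_mul(ad_subset_rows(hp, pairs[, 1L]),
                       ad_subset_rows(hp, pairs[, 2L]))
        p_link <- ad_clamp(ad_sigmoid(dots), BCE_EPS, 1 - BCE_EPS)
        # divisor |E| (not |E| + |Neg|): twice the mean BCE of the 2|E| terms
        l_r <- ad_scale(ad_bce(p_link, c(rep(1, nrow(edges)), rep(0, nrow(neg)))), 2)
        loss <- ad_add(loss, ad_scale(l_r, config$omega2))
        l_r_val <- l_r$value[1L]
      }
      lv <- loss$value[1L]
      if (!is.finite(lv)) stop("non-finite loss at epoch ", ep)
      loss_history[ep, ] <- c(lv, l_n$value[1L], l_n1$value[1L], l_r_val)
      ad_backward(loss)
      st <- adam_step(opt, params, collect_grads(pn))
      opt <- st$opt
      params <- st$params
    }
    .ad$tape <- NULL

    out <- forward_model(params, inputs, config, training = FALSE)
    nets <- enabled_networks(config)
    feats <- cbind(
      do.call(cbind, lapply(out$H_1D[nets], ad_value)),
      ad_value(out$H_2D), ad_value(out$H_mlp)
    )
    colnames(feats) <- c(paste0("H_1D_", nets), "H_2D", "H_mlp")
    rownames(feats) <- labels$index$ids

    lr_fit <- NULL
    scores <- if (config$combiner == "lr") {
      lr_fit <- lr_combine(feats, y_train, train_idx, lambda = config$lr_lambda)
      lr_fit$scores
    } else {
      stats::plogis(as.numeric(ad_value(out$H_syn)))
    }
    names(scores) <- labels$index$ids

    link_audit <- NULL
    if (!is.null(holdout)) {
      neg <- sample_gene_negatives(dataset$bundle$A_PP, nrow(holdout))
      hp <- ad_value(out$H_1D$pp)
      s_pos <- link_reconstruction(hp, holdout)
      s_neg <- link_reconstruction(hp, neg)
      link_audit <- list(
        auc = unname(evaluate_scores(c(s_pos, s_neg),
                                     c(rep(1, length(s_pos)),
                                       rep(0, length(s_neg))))["auc"]),
        n_holdout = nrow(holdout))
    }

    structure(list(params = params, config = config, features = feats,
                   scores = scores, lr = lr_fit, loss_history = loss_history,
                   link_audit = link_audit, train_idx = train_idx),
              class = "driver_fit")
  })
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("<driver_fit: %d genes, %d feature columns, final loss %.4f>\n",
              length(x$scores), ncol(x$features),
              x$loss_history[nrow(x$loss_history), "total"]))
  invisible(x)
}

#' Logistic-regression combiner over the learned feature columns
#'
#' Ridge-penalised logistic regression (weak L2 by default) fitted on the
#' training genes only, then applied to every gene. The coefficients report
#' the contribution of each feature column.
#'
#' @param features n x k feature matrix.
#' @param y_train 0/1 labels of the training genes.
#' @param train_idx Row indices of the training genes.
#' @param lambda L2 penalty.
#' @return List with `weights`, `intercept`, `scores` (length n).
#' @export
lr_combine <- function(features, y_train, train_idx, lambda = 1e-4) {
  if (length(unique(y_train)) < 2L)
    stop("combiner training fold contains a single class")
  fit <- glmnet::glmnet(features[train_idx, , drop = FALSE], y_train,
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  co <- as.numeric(stats::coef(fit))
  list(weights = stats::setNames(co[-1L], colnames(features)),
       intercept = co[1L],
       scores = as.numeric(stats::predict(fit, features, type = "response")))
}

#' Evaluate the combiner at given weights
#'
#' `score = sigmoid(features %*% weights + epsilon)`.
#'
#' @param features n x k feature matrix.
#' @param weights Length-k weight vector.
#' @param epsilon Intercept.
#' @return Score vector in (0, 1).
#' @export
lr_predict <- function(features, weights, epsilon = 0) {
  stats::plogis(as.numeric(as.matrix(features) %*% weights + epsilon))
}

# Stratified fold assignment over labelled genes; returns integer folds in
# 1..k named by gene id.
stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    assign_one <- function(ids) {
      ids <- sample(ids)
      stats::setNames(rep_len(seq_len(k), length(ids)), ids)
    }
    folds <- c(assign_one(labels$positives), assign_one(labels$negatives))
    if (min(table(folds)) < 1L) stop("a fold is empty; use fewer folds")
    folds
  })
}

#' Stratified cross-validation
#'
#' Splits the labelled genes into stratified folds; for every fold the model
#' is trained on the remaining folds (unlabeled genes stay in the graphs but
#' never enter a loss), the combiner is fitted on the training genes, and
#' the held-out fold is scored. Pre-training and feature preparation are
#' shared across folds (they use no labels).
#'
#' @param dataset A [driver_dataset()].
#' @param config A [run_config()]; `config$cv_folds` and `config$seed` drive
#'   the split.
#' @return An object of class `cv_result`: per-fold `auc`/`auprc`, their
#'   means and standard deviations, per-gene out-of-fold scores, and the
#'   mean held-out link AUC when `config$link_holdout > 0`.
#' @export
cross_validate <- function(dataset, config) {
  k <- config$cv_folds
  if (k < 2L) stop("cv_folds must be at least 2")
  labels <- dataset$labels
  fold_of <- stratified_folds(labels, k, config$seed)
  if (min(table(fold_of[labels$positives])) < 1L)
    stop("a fold has no positives; use fewer folds")
  inputs <- prepare_model_inputs(dataset, config)
  y <- label_vector(labels)
  labelled <- names(fold_of)

  oof <- rep(NA_real_, labels$index$n)
  names(oof) <- labels$index$ids
  folds <- data.frame(fold = seq_len(k), auc = NA_real_, auprc = NA_real_,
                      n_test = NA_integer_)
  link_aucs <- c()
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    test_genes <- labelled[fold_of == f]
    train_genes <- labelled[fold_of != f]
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train_model(dataset, cfg_f, train_genes = train_genes,
                       inputs = inputs)
    ti <- match(test_genes, labels$index$ids)
    oof[ti] <- fit$scores[ti]
    ev <- evaluate_scores(fit$scores[ti], y[ti])
    folds$auc[f] <- ev["auc"]
    folds$auprc[f] <- ev["auprc"]
    folds$n_test[f] <- length(ti)
    if (!is.null(fit$link_audit)) link_aucs <- c(link_aucs, fit$link_audit$auc)
    fits[[f]] <- fit
  }
  structure(list(
    folds = folds,
    auc_mean = mean(folds$auc), auc_sd = stats::sd(folds$auc),
    auprc_mean = mean(folds$auprc), auprc_sd = stats::sd(folds$auprc),
    oof_scores = oof[labelled],
    fold_of = fold_of,
    link_auc = if (length(link_aucs)) mean(link_aucs) else NULL,
    prevalence = mean(y[match(labelled, labels$index$ids)]),
    fits = fits
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds | AUC %.4f +/- %.4f | AUPRC %.4f +/- %.4f%s>\n",
              nrow(x$folds), x$auc_mean, x$auc_sd, x$auprc_mean, x$auprc_sd,
              if (!is.null(x$link_auc))
                sprintf(" | link AUC %.4f", x$link_auc) else ""))
  invisible(x)
}

#' Ablation variants
#'
#' Named configuration switches matching the model's ablation study: single
#' and dual network subsets, removal of pre-training, of the bilinear layer,
#' of self-attention, and of the logistic-regression combiner. When the
#' gene-gene network is excluded the link reconstruction loss is dropped.
#'
#' @return Character vector of valid variant names.
#' @export
ablation_variants <- function() {
  c("full", "genes_only", "outlying_only", "mirna_only",
    "gene_outlying", "gene_mirna", "outlying_mirna",
    "no_pretrain", "no_bilinear", "no_attention", "no_lr")
}

#' Apply an ablation variant to a configuration
#'
#' @param config A [run_config()].
#' @param variant One of [ablation_variants()].
#' @return The modified `run_config`.
#' @export
apply_ablation <- function(config, variant) {
  if (!variant %in% ablation_variants())
    stop(sprintf("unknown variant '%s'; valid: %s", variant,
                 paste(ablation_variants(), collapse = ", ")))
  sw <- switch(variant,
    full = list(),
    genes_only = list(use_outlying = FALSE, use_mirna = FALSE),
    outlying_only = list(use_gene_gene = FALSE, use_mirna = FALSE),
    mirna_only = list(use_gene_gene = FALSE, use_outlying = FALSE),
    gene_outlying = list(use_mirna = FALSE),
    gene_mirna = list(use_outlying = FALSE),
    outlying_mirna = list(use_gene_gene = FALSE),
    no_pretrain = list(use_pretrain = FALSE),
    no_bilinear = list(use_bilinear = FALSE),
    no_attention = list(use_attention = FALSE),
    no_lr = list(combiner = "sigmoid_sum")
  )
  for (nm in names(sw)) config[[nm]] <- sw[[nm]]
  validate_run_config(config)
  config
}

#' Run one ablation variant end to end
#'
#' @param dataset A [driver_dataset()].
#' @param config Base [run_config()].
#' @param variant One of [ablation_variants()].
#' @return The [cross_validate()] result, with the variant name and the
#'   combiner feature arity attached.
#' @export
ablate <- function(dataset, config, variant) {
  cfg <- apply_ablation(config, variant)
  res <- cross_validate(dataset, cfg)
  res$variant <- variant
  res$n_lr_features <- length(enabled_networks(cfg)) + 2L
  res
}
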