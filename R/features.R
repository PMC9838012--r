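# Assembly of initial node attributes: per-context biological rates for
# genes, random-walk topological embeddings, outlying-expression summaries,
# the Gaussian Interaction Profile kernel and miRNA attributes.

#' Min-max normalize the columns of a matrix to the unit interval
#'
#' A constant column (max equals min) is mapped to all zeros with a message,
#' since the affine rescaling is undefined there.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with every column in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  flat <- hi == lo
  if (any(flat))
    message(sprintf("minmax_normalize: %d constant column(s) set to 0", sum(flat)))
  rng <- ifelse(flat, 1, hi - lo)
  out <- sweep(sweep(x, 2L, lo, "-"), 2L, rng, "/")
  out[, flat] <- 0
  out
}

#' Biological gene features from per-context omics rates
#'
#' Concatenates, in this order, the per-context mutation rates, differential
#' methylation rates and differential expression rates, then min-max
#' normalizes each column. With C cancer contexts the result has 3C columns
#' (48 for the 16-context pan-cancer layout, 3 for a single cancer type).
#'
#' @param mutation,methylation,expression Numeric genes x contexts matrices
#'   with identical dimensions and matching column (context) order.
#' @return A genes x 3C matrix with columns in `[0, 1]`.
#' @export
gene_biological_features <- function(mutation, methylation, expression) {
  mutation <- as.matrix(mutation)
  methylation <- as.matrix(methylation)
  expression <- as.matrix(expression)
  if (!all(dim(mutation) == dim(methylation)) ||
      !all(dim(mutation) == dim(expression)))
    stop("the three omics rate matrices must have identical dimensions")
  out <- minmax_normalize(cbind(mutation, methylation, expression))
  C <- ncol(mutation)
  colnames(out) <- c(paste0("mut_", seq_len(C)), paste0("meth_", seq_len(C)),
                     paste0("expr_", seq_len(C)))
  rownames(out) <- rownames(mutation)
  out
}

#' Topological gene features via random-walk embedding
#'
#' Runs uniform random walks (the p = q = 1 special case of biased
#' second-order walks) on the gene-gene network and trains a skip-gram model
#' with negative sampling on the walk corpus. Deterministic for a fixed seed;
#' isolated genes receive an all-zero row.
#'
#' @param A_PP Symmetric \{0,1\} gene-gene adjacency.
#' @param dim Embedding width (default 16).
#' @param seed Integer seed.
#' @param walk_length,walks_per_node,window,negative,epochs,lr Walk corpus and
#'   skip-gram settings.
#' @return A genes x `dim` numeric matrix.
#' @export
gene_topological_features <- function(A_PP, dim = 16L, seed = 0L,
                                      walk_length = 80L, walks_per_node = 10L,
                                      window = 10L, negative = 5L,
                                      epochs = 3L, lr = 0.025) {
  if (nrow(A_PP) != ncol(A_PP)) stop("A_PP must be square")
  A <- methods::as(A_PP, "generalMatrix")
  adj <- lapply(seq_len(nrow(A)), function(v) which(A[v, ] != 0))
  iso <- sum(lengths(adj) == 0L)
  if (iso > 0L)
    message(sprintf("gene_topological_features: %d isolated node(s) get zero embeddings", iso))
  emb <- node2vec_embed_cpp(adj, as.integer(dim), as.integer(walk_length),
                            as.integer(walks_per_node), as.integer(window),
                            as.integer(negative), as.integer(epochs),
                            lr, as.integer(seed))
  colnames(emb) <- paste0("topo_", seq_len(dim))
  rownames(emb) <- rownames(A_PP)
  emb
}

#' Detect outlying genes from per-context expression
#'
#' For each cancer context, expression is z-scored per gene across that
#' context's tumor samples (population standard deviation). A gene is
#' outlying when `|z| > threshold` in at least one sample of any context. A
#' zero-variance gene in a context has z defined as 0 there and can never be
#' outlying in that context.
#'
#' @param expression Named list, one genes x samples numeric matrix per
#'   context. All matrices must share the same genes in the same order.
#' @param threshold Absolute z-score cutoff (default 2).
#' @return A list with elements `z` (list of z-score matrices, one per
#'   context), `outlying` (logical per gene), `threshold`.
#' @export
detect_outlying_genes <- function(expression, threshold = 2) {
  if (!length(expression)) stop("expression must contain at least one context")
  z <- lapply(expression, function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop("each context needs at least 2 samples")
    mu <- rowMeans(x)
    sd_pop <- sqrt(pmax(rowMeans(x * x) - mu * mu, 0))
    zx <- (x - mu) / ifelse(sd_pop == 0, 1, sd_pop)
    zx[sd_pop == 0, ] <- 0
    zx
  })
  outlying <- Reduce(`|`, lapply(z, function(zx) {
    apply(abs(zx) > threshold, 1L, any)
  }))
  list(z = z, outlying = outlying, threshold = threshold)
}

#' Outlying-gene attributes: mean z-score and outlying frequency per context
#'
#' For each context, the mean z-score over all of that context's samples and
#' the fraction of samples with `|z| > threshold`. With C contexts the result
#' has 2C columns (32 for the pan-cancer layout, 2 for a single cancer type),
#' ordered mean z-scores first, then frequencies.
#'
#' @param zscores List of genes x samples z-score matrices, one per context
#'   (as produced by [detect_outlying_genes()], restricted to outlying genes).
#' @param threshold Absolute z-score cutoff used for the frequencies.
#' @return A m x 2C numeric matrix.
#' @export
outlying_gene_features <- function(zscores, threshold = 2) {
  meanz <- do.call(cbind, lapply(zscores, rowMeans))
  freq <- do.call(cbind, lapply(zscores, function(zx) {
    rowMeans(abs(zx) > threshold)
  }))
  C <- length(zscores)
  out <- cbind(meanz, freq)
  colnames(out) <- c(paste0("zmean_", seq_len(C)), paste0("freq_", seq_len(C)))
  out
}

#' Gaussian Interaction Profile kernel
#'
#' RBF similarity between binary association profiles with a data-scaled
#' bandwidth: `K[i, j] = exp(-gamma * ||x_i - x_j||^2)` with
#' `gamma = gamma_prime / mean_i(||x_i||^2)`. Symmetric with unit diagonal,
#' entries in (0, 1]. When every profile is all-zero the bandwidth is
#' undefined and the identity matrix is returned with a warning.
#'
#' @param profiles t x D binary profile matrix (e.g. miRNA-disease
#'   associations).
#' @param gamma_prime Positive bandwidth numerator (default 1).
#' @return A t x t similarity matrix.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  sq <- rowSums(profiles^2)
  if (all(sq == 0)) {
    warning("all profiles are zero; GIP bandwidth undefined, returning identity")
    return(diag(nrow(profiles)))
  }
  gamma <- gamma_prime / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2 <- pmax(d2, 0)
  K <- exp(-gamma * d2)
  diag(K) <- 1
  K
}

# Reduce a t x t similarity matrix to `dim` columns. "svd" projects onto the
# top right singular vectors (deterministic up to sign, fixed by making the
# largest-magnitude loading positive); "projection" applies a fixed seeded
# Gaussian linear map.
reduce_similarity <- function(K, dim, method = c("svd", "projection"), seed = 0L) {
  method <- match.arg(method)
  t_ <- nrow(K)
  k <- min(dim, t_)
  if (method == "svd") {
    sv <- svd(K, nu = 0L, nv = k)
    V <- sv$v
    for (j in seq_len(k)) {
      if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    }
    out <- K %*% V
  } else {
    W <- withr::with_seed(seed, matrix(stats::rnorm(t_ * k, sd = 1 / sqrt(t_)), t_, k))
    out <- K %*% W
  }
  if (k < dim) out <- cbind(out, matrix(0, t_, dim - k))
  out
}

#' miRNA attributes
#'
#' Per context: the mean expression z-score and the mean differential
#' expression across the context's samples; then `sim_dim` similarity
#' features obtained by linearly reducing the GIP kernel matrix; then the
#' miRNA degree (number of associated genes). Pan-cancer layout with C = 16
#' and `sim_dim = 16` gives 16 + 16 + 16 + 1 = 49 columns; a single cancer
#' type with `sim_dim = 1` gives 4.
#'
#' @param zscores Named list per context of t x samples z-score matrices.
#' @param diffexpr Named list per context of t x samples differential
#'   expression matrices.
#' @param gip t x t GIP similarity matrix from [gip_kernel()].
#' @param A_PR Gene-miRNA adjacency (n x t); column sums give degrees.
#' @param sim_dim Width of the similarity block (16 pan-cancer, 1 single).
#' @param sim_method `"svd"` (deterministic spectral reduction, default) or
#'   `"projection"` (fixed seeded Gaussian map).
#' @param seed Seed for `sim_method = "projection"`.
#' @return A t x (2C + sim_dim + 1) numeric matrix.
#' @export
mirna_features <- function(zscores, diffexpr, gip, A_PR, sim_dim = 16L,
                           sim_method = c("svd", "projection"), seed = 0L) {
  sim_method <- match.arg(sim_method)
  meanz <- do.call(cbind, lapply(zscores, rowMeans))
  meand <- do.call(cbind, lapply(diffexpr, rowMeans))
  sims <- reduce_similarity(gip, sim_dim, sim_method, seed)
  degree <- Matrix::colSums(A_PR)
  C <- length(zscores)
  out <- cbind(meanz, meand, sims, degree)
  colnames(out) <- c(paste0("zmean_", seq_len(C)), paste0("dmean_", seq_len(C)),
                     paste0("sim_", seq_len(sim_dim)), "degree")
  out
}

#' Bundle initial attribute matrices
#'
#' @param X_P Gene attributes (n x F1), biological + topological columns.
#' @param X_O Outlying-gene attributes (m x F2); lifted to F1 inside the
#'   model by a trainable affine map.
#' @param X_R miRNA attributes (t x F3); likewise lifted to F1.
#' @return An object of class `attribute_set`.
#' @export
attribute_set <- function(X_P, X_O, X_R) {
  structure(list(
    X_P = as.matrix(X_P), X_O = as.matrix(X_O), X_R = as.matrix(X_R),
    F1 = ncol(X_P), F2 = ncol(X_O), F3 = ncol(X_R)
  ), class = "attribute_set")
}

#' @export
print.attribute_set <- function(x, ...) {
  cat(sprintf("<attribute_set: X_P %dx%d, X_O %dx%d, X_R %dx%d>\n",
              nrow(x$X_P), x$F1, nrow(x$X_O), x$F2, nrow(x$X_R), x$F3))
  invisible(x)
}
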