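# Typed containers and on-disk formats: node indices, edge lists, attribute
# tables, label lists, score tables and run configuration.

#' Create a node index
#'
#' An ordered registry of unique node identifiers (genes, outlying genes or
#' miRNAs). The order of `ids` is the single source of truth for the row and
#' column order of every matrix in the pipeline.
#'
#' @param ids Character vector of unique node identifiers.
#' @param type Node role, one of `"gene"`, `"outlying"`, `"mirna"`.
#' @return An object of class `node_index` with fields `ids`, `n`, `type`.
#' @export
node_index <- function(ids, type = c("gene", "outlying", "mirna")) {
  type <- match.arg(type)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("node ids must be unique")
  if (length(ids) == 0L) stop("node index must contain at least one id")
  structure(list(ids = ids, n = length(ids), type = type),
            class = "node_index")
}

#' @export
print.node_index <- function(x, ...) {
  cat(sprintf("<node_index: %d %s nodes>\n", x$n, x$type))
  invisible(x)
}

index_lookup <- function(index, ids, what = "node") {
  pos <- match(ids, index$ids)
  if (anyNA(pos)) {
    bad <- ids[which(is.na(pos))[1L]]
    stop(sprintf("unknown %s id '%s' (not in the %s index)",
                 what, bad, index$type))
  }
  pos
}

#' Read a two-column edge list into a binary adjacency matrix
#'
#' Edges are tab-separated `from<TAB>to` pairs (an optional third weight
#' column is ignored). Duplicate edges collapse to a single 1. For
#' `kind = "symmetric"` the matrix is symmetrised and self-loops are dropped
#' with a warning.
#'
#' @param path Path to the edge-list file.
#' @param kind `"symmetric"` (square, e.g. gene-gene) or `"bipartite"`.
#' @param row_index,col_index [node_index] objects resolving the two columns.
#'   For `kind = "symmetric"`, `col_index` defaults to `row_index`.
#' @return A sparse `Matrix::dgCMatrix` with entries in \{0, 1\}.
#' @export
read_edge_list <- function(path, kind = c("symmetric", "bipartite"),
                           row_index, col_index = row_index) {
  kind <- match.arg(kind)
  if (length(readLines(path, n = 1L)) == 0L)
    stop(sprintf("edge list '%s' is empty", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "")
  i <- tryCatch(index_lookup(row_index, raw[[1L]]),
                error = function(e) stop(sprintf("%s in '%s'",
                                                 conditionMessage(e), path)))
  j <- tryCatch(index_lookup(col_index, raw[[2L]]),
                error = function(e) stop(sprintf("%s in '%s'",
                                                 conditionMessage(e), path)))
  edges_to_adjacency(i, j, row_index$n, col_index$n, symmetric = kind == "symmetric")
}

# Shared constructor for binary adjacencies from index pairs.
edges_to_adjacency <- function(i, j, nrow, ncol, symmetric = FALSE) {
  if (symmetric) {
    loops <- i == j
    if (any(loops)) {
      warning(sprintf("dropping %d self-loop(s) from symmetric edge list",
                      sum(loops)))
      i <- i[!loops]; j <- j[!loops]
    }
    ii <- c(i, j); jj <- c(j, i)
  } else {
    ii <- i; jj <- j
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nrow, ncol))
  A@x[] <- 1  # collapse duplicates
  methods::as(A, "generalMatrix")
}

#' Read a node attribute table
#'
#' Tab-separated with a header row; the first column holds node ids. Rows are
#' reordered to match `index`; a node missing from the table is an error (no
#' silent imputation).
#'
#' @param path Path to the TSV file.
#' @param index A [node_index].
#' @return A numeric matrix with `index$n` rows in index order.
#' @export
read_attribute_table <- function(path, index) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  ids <- tab[[1L]]
  num <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value in '%s' at row %d, column '%s'",
                 path, bad[1L], colnames(num)[bad[2L]]))
  }
  pos <- match(index$ids, ids)
  if (anyNA(pos)) {
    stop(sprintf("attribute table '%s' is missing node '%s'",
                 path, index$ids[which(is.na(pos))[1L]]))
  }
  out <- num[pos, , drop = FALSE]
  rownames(out) <- index$ids
  out
}

#' Write a node attribute table
#'
#' Inverse of [read_attribute_table()]: id column plus named numeric columns.
#'
#' @param x Numeric matrix with row names (node ids) and column names.
#' @param path Output path.
#' @export
write_attribute_table <- function(x, path) {
  if (is.null(rownames(x))) stop("attribute matrix must have row names")
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene scores
#'
#' Tab-separated `gene_id<TAB>score[<TAB>label]`, sorted by descending score
#' with ties broken by gene id (ascending, stable).
#'
#' @param path Output path.
#' @param gene_ids Character vector.
#' @param scores Numeric scores in `[0, 1]`, one per gene.
#' @param labels Optional per-gene labels (NA for unlabeled).
#' @export
write_scores <- function(path, gene_ids, scores, labels = NULL) {
  if (length(gene_ids) != length(scores))
    stop("gene_ids and scores differ in length")
  if (!is.null(labels) && length(labels) != length(scores))
    stop("labels and scores differ in length")
  ord <- order(-scores, gene_ids)
  df <- data.frame(gene_id = gene_ids[ord], score = scores[ord])
  if (!is.null(labels)) df$label <- labels[ord]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene scores written by [write_scores()]
#' @param path Path to the score table.
#' @return A data.frame with columns `gene_id`, `score` and optionally `label`.
#' @export
read_scores <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, colClasses = NA)
}

#' Construct a labelled gene set
#'
#' Partitions the gene universe into known drivers (positives), confident
#' non-drivers (negatives) and unlabeled genes. Unlabeled genes participate in
#' the networks but never in losses or evaluation.
#'
#' @param positives,negatives Character vectors of gene ids.
#' @param index Gene [node_index]; genes in neither set are unlabeled.
#' @return An object of class `labeled_gene_set`.
#' @export
labeled_gene_set <- function(positives, negatives, index) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(intersect(positives, negatives)))
    stop("a gene cannot be both positive and negative")
  index_lookup(index, positives, "positive gene")
  index_lookup(index, negatives, "negative gene")
  structure(list(
    positives = positives,
    negatives = negatives,
    unlabeled = setdiff(index$ids, c(positives, negatives)),
    index = index
  ), class = "labeled_gene_set")
}

#' @export
print.labeled_gene_set <- function(x, ...) {
  cat(sprintf("<labeled_gene_set: %d positive, %d negative, %d unlabeled>\n",
              length(x$positives), length(x$negatives), length(x$unlabeled)))
  invisible(x)
}

#' Read gene labels
#'
#' TSV `gene_id<TAB>{0,1}` without header; genes absent from the file are
#' unlabeled.
#'
#' @param path Path to the label file.
#' @param index Gene [node_index].
#' @return A [labeled_gene_set].
#' @export
read_labels <- function(path, index) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer"))
  if (!all(tab[[2L]] %in% c(0L, 1L))) stop("labels must be 0 or 1")
  labeled_gene_set(tab[[1L]][tab[[2L]] == 1L], tab[[1L]][tab[[2L]] == 0L], index)
}

#' Write gene labels (inverse of [read_labels()])
#' @param labels A [labeled_gene_set].
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(
    gene_id = c(labels$positives, labels$negatives),
    y = c(rep(1L, length(labels$positives)), rep(0L, length(labels$negatives)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Permute the labels of a labelled gene set
#'
#' Reassigns the positive/negative labels uniformly at random among the same
#' labelled genes (the unlabeled set is unchanged). Used as a null control:
#' any signal recovered from permuted labels is leakage.
#'
#' @param labels A [labeled_gene_set()].
#' @param seed Integer seed.
#' @return A [labeled_gene_set()] with shuffled label assignments.
#' @export
permute_labels <- function(labels, seed) {
  withr::with_seed(seed, {
    pool <- sample(c(labels$positives, labels$negatives))
    npos <- length(labels$positives)
    labeled_gene_set(pool[seq_len(npos)], pool[-seq_len(npos)], labels$index)
  })
}

# 0/1 vector over the full index for labelled genes, NA for unlabeled.
label_vector <- function(labels) {
  y <- rep(NA_integer_, labels$index$n)
  y[match(labels$positives, labels$index$ids)] <- 1L
  y[match(labels$negatives, labels$index$ids)] <- 0L
  y
}

#' Model and training configuration
#'
#' Defaults follow the pan-cancer setting of the method: two graph
#' convolution layers of 256 and 128 filters, bilinear mixing weight
#' `alpha = 0.2`, auxiliary loss weights `omega1 = 0.1` and `omega2 = 0.01`,
#' Adam with learning rate 0.002 and weight decay 5e-4, 1065 epochs, dropout
#' 0.5 everywhere except 0.2 inside self-attention.
#'
#' @param hidden_dims Integer vector of per-layer widths (length = layer count).
#' @param alpha Bilinear mixing weight in `[0, 1]`.
#' @param omega1,omega2 Weights of the fused-feature node loss and of the link
#'   reconstruction loss.
#' @param dropout_default,dropout_attention Dropout rates in `[0, 1)`.
#' @param learning_rate,weight_decay,epochs Adam settings.
#' @param pretrain_epochs Epochs of gene-miRNA pre-training.
#' @param conv1d_hidden Hidden channel count of the 1D-convolution modules.
#' @param mlp_hidden Hidden widths of the MLP branch on original features.
#' @param lr_lambda L2 penalty of the logistic-regression combiner.
#' @param link_holdout Fraction of gene-gene edges excluded from the link loss
#'   and kept aside to audit link reconstruction (0 = use all edges).
#' @param cv_folds Cross-validation fold count.
#' @param seed Integer seed controlling all randomness of a run.
#' @param use_gene_gene,use_outlying,use_mirna Network ablation switches.
#' @param use_attention,use_bilinear,use_pretrain Module ablation switches.
#' @param combiner `"lr"` (logistic-regression combiner) or `"sigmoid_sum"`
#'   (score directly from the synthesis feature).
#' @return An object of class `run_config`.
#' @export
run_config <- function(hidden_dims = c(256L, 128L),
                       alpha = 0.2,
                       omega1 = 0.1,
                       omega2 = 0.01,
                       dropout_default = 0.5,
                       dropout_attention = 0.2,
                       learning_rate = 0.002,
                       weight_decay = 5e-4,
                       epochs = 1065L,
                       pretrain_epochs = 100L,
                       conv1d_hidden = 32L,
                       mlp_hidden = c(256L, 64L),
                       lr_lambda = 1e-4,
                       link_holdout = 0,
                       cv_folds = 10L,
                       seed = 0L,
                       use_gene_gene = TRUE,
                       use_outlying = TRUE,
                       use_mirna = TRUE,
                       use_attention = TRUE,
                       use_bilinear = TRUE,
                       use_pretrain = TRUE,
                       combiner = c("lr", "sigmoid_sum")) {
  combiner <- match.arg(combiner)
  cfg <- list(
    hidden_dims = as.integer(hidden_dims), alpha = alpha,
    omega1 = omega1, omega2 = omega2,
    dropout_default = dropout_default, dropout_attention = dropout_attention,
    learning_rate = learning_rate, weight_decay = weight_decay,
    epochs = as.integer(epochs), pretrain_epochs = as.integer(pretrain_epochs),
    conv1d_hidden = as.integer(conv1d_hidden),
    mlp_hidden = as.integer(mlp_hidden), lr_lambda = lr_lambda,
    link_holdout = link_holdout, cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    use_gene_gene = use_gene_gene, use_outlying = use_outlying,
    use_mirna = use_mirna, use_attention = use_attention,
    use_bilinear = use_bilinear, use_pretrain = use_pretrain,
    combiner = combiner
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(length(cfg$hidden_dims) >= 1L, all(cfg$hidden_dims >= 1L))
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must lie in [0, 1]")
  if (cfg$omega1 < 0 || cfg$omega2 < 0) stop("omega1 and omega2 must be >= 0")
  for (d in c(cfg$dropout_default, cfg$dropout_attention))
    if (d < 0 || d >= 1) stop("dropout rates must lie in [0, 1)")
  if (cfg$link_holdout < 0 || cfg$link_holdout >= 1)
    stop("link_holdout must lie in [0, 1)")
  if (!any(cfg$use_gene_gene, cfg$use_outlying, cfg$use_mirna))
    stop("at least one network must be enabled")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  layers: %s | alpha %.3g | omega1 %.3g | omega2 %.3g\n",
              paste(x$hidden_dims, collapse = "-"), x$alpha, x$omega1, x$omega2))
  cat(sprintf("  adam: lr %.4g wd %.4g epochs %d | dropout %.2g (attn %.2g)\n",
              x$learning_rate, x$weight_decay, x$epochs,
              x$dropout_default, x$dropout_attention))
  cat(sprintf("  networks: PP=%s PO=%s PR=%s | attention=%s bilinear=%s pretrain=%s | combiner=%s\n",
              x$use_gene_gene, x$use_outlying, x$use_mirna,
              x$use_attention, x$use_bilinear, x$use_pretrain, x$combiner))
  invisible(x)
}

#' Read / write a run configuration as a YAML key:value file
#'
#' Only keys present in the file override [run_config()] defaults.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config` to serialise.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
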