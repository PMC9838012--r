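# Construction of the three relationship networks and their normalized forms.

#' Build the gene-gene adjacency from PPI edges
#'
#' Expects edges already filtered by interaction score upstream. Accepts
#' either a two-column matrix/data.frame of gene ids or a path readable by
#' [read_edge_list()].
#'
#' @param edges Two-column object of gene id pairs, or a file path.
#' @param gene_index Gene [node_index].
#' @return Symmetric sparse \{0,1\} matrix `A_PP` (n x n).
#' @export
build_gene_gene <- function(edges, gene_index) {
  if (is.character(edges) && length(edges) == 1L)
    return(read_edge_list(edges, "symmetric", gene_index))
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(gene_index$n, gene_index$n)))
  i <- index_lookup(gene_index, edges[, 1L])
  j <- index_lookup(gene_index, edges[, 2L])
  edges_to_adjacency(i, j, gene_index$n, gene_index$n, symmetric = TRUE)
}

#' Build the gene-outlying-gene adjacency
#'
#' A gene connects to an outlying gene when the gene is mutated in at least
#' one sample AND the pair is linked in the PPI network:
#' `A_PO[g, o] = mutated[g] & ppi_link[g, o]`.
#'
#' @param ppi_links Sparse or dense \{0,1\} incidence (n genes x m outlying
#'   genes) of PPI links between genes and outlying genes.
#' @param mutated_mask Logical/0-1 vector of length n; TRUE when the gene
#'   carries a mutation in at least one sample.
#' @return Sparse \{0,1\} matrix `A_PO` (n x m).
#' @export
build_gene_outlying <- function(ppi_links, mutated_mask) {
  mutated_mask <- as.numeric(mutated_mask != 0)
  if (length(mutated_mask) != nrow(ppi_links))
    stop("mutated_mask length must equal the gene dimension of ppi_links")
  A <- Matrix::Diagonal(x = mutated_mask) %*% ppi_links
  A <- methods::as(Matrix::drop0(A), "generalMatrix")
  A@x[] <- 1
  A
}

#' Build the gene-miRNA adjacency from target associations
#'
#' Associations whose gene or miRNA is not in the given indices are skipped
#' with a warning (closed node universes); duplicates collapse to 1.
#'
#' @param target_edges Two-column object `(gene_id, mirna_id)`, or a file path.
#' @param gene_index,mirna_index Node indices.
#' @return Sparse \{0,1\} matrix `A_PR` (n x t).
#' @export
build_gene_mirna <- function(target_edges, gene_index, mirna_index) {
  if (is.character(target_edges) && length(target_edges) == 1L)
    return(read_edge_list(target_edges, "bipartite", gene_index, mirna_index))
  target_edges <- as.matrix(target_edges)
  i <- match(target_edges[, 1L], gene_index$ids)
  j <- match(target_edges[, 2L], mirna_index$ids)
  keep <- !is.na(i) & !is.na(j)
  if (any(!keep))
    warning(sprintf("skipping %d association(s) with unindexed nodes",
                    sum(!keep)))
  if (!any(keep))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(gene_index$n, mirna_index$n)))
  edges_to_adjacency(i[keep], j[keep], gene_index$n, mirna_index$n)
}

#' Degree normalization of an adjacency matrix
#'
#' `P[i, j] = A[i, j] / sqrt((rowdeg_i + 1) * (coldeg_j + 1))`, where degrees
#' are row and column sums of `A`. The +1 shift makes the normalization
#' well defined for isolated nodes; no self-loop edges are inserted. The
#' transposition identity `normalize(t(A)) == t(normalize(A))` holds exactly.
#'
#' @param A Nonnegative (sparse or dense) adjacency matrix.
#' @return Sparse normalized matrix `P` of the same shape.
#' @export
normalize_adjacency <- function(A) {
  dr <- 1 / sqrt(Matrix::rowSums(A) + 1)
  dc <- 1 / sqrt(Matrix::colSums(A) + 1)
  P <- Matrix::Diagonal(x = dr) %*% A %*% Matrix::Diagonal(x = dc)
  methods::as(P, "generalMatrix")
}

#' Bundle the three networks with their normalized forms
#'
#' @param A_PP Symmetric gene-gene adjacency (n x n).
#' @param A_PO Gene-outlying-gene adjacency (n x m).
#' @param A_PR Gene-miRNA adjacency (n x t).
#' @return An object of class `network_bundle` with the three adjacencies and
#'   their normalized forms `P_PP`, `P_PO`, `P_PR` (gene-side rows). The
#'   other-side normalized matrices are the transposes `t(P_PO)`, `t(P_PR)`.
#' @export
network_bundle <- function(A_PP, A_PO, A_PR) {
  if (nrow(A_PP) != ncol(A_PP)) stop("A_PP must be square")
  if (!Matrix::isSymmetric(methods::as(A_PP, "generalMatrix")))
    stop("A_PP must be symmetric")
  n <- nrow(A_PP)
  if (nrow(A_PO) != n || nrow(A_PR) != n)
    stop("A_PO and A_PR must have one row per gene")
  structure(list(
    A_PP = A_PP, A_PO = A_PO, A_PR = A_PR,
    P_PP = normalize_adjacency(A_PP),
    P_PO = normalize_adjacency(A_PO),
    P_PR = normalize_adjacency(A_PR),
    n = n, m = ncol(A_PO), t = ncol(A_PR)
  ), class = "network_bundle")
}

#' @export
print.network_bundle <- function(x, ...) {
  cat(sprintf(paste0("<network_bundle: %d genes, %d outlying genes, %d miRNAs;",
                     " |E_PP|=%d, |E_PO|=%d, |E_PR|=%d>\n"),
              x$n, x$m, x$t,
              Matrix::nnzero(x$A_PP) / 2L, Matrix::nnzero(x$A_PO),
              Matrix::nnzero(x$A_PR)))
  invisible(x)
}

# Undirected edge list (i < j) of a symmetric sparse adjacency.
upper_edges <- function(A) {
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  idx
}
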