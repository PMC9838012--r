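# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every graph layer in this package is an explicit composition of the
# primitives below; gradients for the full multi-network model are obtained
# by one backward sweep over the tape. Values are base-R matrices; sparse
# adjacencies enter only as constants of `ad_spmm()`.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

# Start a fresh tape. Each training step builds one tape and discards it.
tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

tape_active <- function() {
  if (is.null(.ad$tape)) stop("no active autodiff tape; call tape_start() first")
  .ad$tape
}

is_ad <- function(x) inherits(x, "ad")

ad_value <- function(x) if (is_ad(x)) x$value else x

# Create a tape node. `backfn(grad)` must return one gradient per parent
# (NULL for parents that are plain constants).
ad_node <- function(value, parents = list(), backfn = NULL) {
  t <- tape_active()
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backfn <- backfn
  n$grad <- NULL
  t$n <- t$n + 1L
  if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[t$n]] <- n
  class(n) <- "ad"
  n
}

# Leaf node for a learnable parameter (grad collected after backward).
ad_param <- function(x) ad_node(as.matrix(x))

ad_matmul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A %*% B, list(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

# Sparse-constant times dense node: P is a (possibly sparse) fixed matrix.
ad_spmm <- function(P, b) {
  B <- ad_value(b)
  ad_node(as.matrix(P %*% B), list(b), function(g) {
    list(as.matrix(Matrix::crossprod(P, g)))
  })
}

# Addition; `b` may be a 1 x k row vector (bias broadcast over rows).
ad_add <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  if (is.matrix(B) && nrow(B) == 1L && nrow(A) > 1L) {
    val <- sweep(A, 2L, as.numeric(B), "+")
    ad_node(val, list(a, b), function(g) {
      list(g, matrix(colSums(g), nrow = 1L))
    })
  } else {
    ad_node(A + B, list(a, b), function(g) list(g, g))
  }
}

ad_sub <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A - B, list(a, b), function(g) list(g, -g))
}

# Elementwise product; either side may be a plain constant.
ad_mul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A * B, list(a, b), function(g) list(g * B, g * A))
}

ad_scale <- function(a, s) {
  A <- ad_value(a)
  ad_node(A * s, list(a), function(g) list(g * s))
}

ad_relu <- function(a) {
  A <- ad_value(a)
  ad_node(pmax(A, 0), list(a), function(g) list(g * (A > 0)))
}

ad_sigmoid <- function(a) {
  S <- stats::plogis(ad_value(a))
  ad_node(S, list(a), function(g) list(g * S * (1 - S)))
}

ad_log <- function(a) {
  A <- ad_value(a)
  ad_node(log(A), list(a), function(g) list(g / A))
}

# Clamp to [lo, hi]; gradient is passed only where the value was not clipped.
ad_clamp <- function(a, lo, hi) {
  A <- ad_value(a)
  ad_node(pmin(pmax(A, lo), hi), list(a), function(g) {
    list(g * (A >= lo & A <= hi))
  })
}

# Row-wise softmax with the usual stabilised forward and exact backward.
ad_softmax_rows <- function(a) {
  A <- ad_value(a)
  E <- exp(A - apply(A, 1L, max))
  S <- E / rowSums(E)
  ad_node(S, list(a), function(g) {
    list(S * (g - rowSums(g * S)))
  })
}

ad_transpose <- function(a) {
  ad_node(t(ad_value(a)), list(a), function(g) list(t(g)))
}

ad_sum <- function(a) {
  A <- ad_value(a)
  ad_node(matrix(sum(A), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(A), ncol(A)))
  })
}

ad_mean <- function(a) {
  A <- ad_value(a)
  ad_node(matrix(mean(A), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / length(A), nrow(A), ncol(A)))
  })
}

# Row subset; `idx` may repeat, gradients are summed back per source row.
ad_subset_rows <- function(a, idx) {
  A <- ad_value(a)
  ad_node(A[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# Shift rows by `s` (positive = down), zero fill; adjoint is the reverse shift.
ad_rowshift <- function(a, s) {
  shift <- function(M, k) {
    n <- nrow(M)
    out <- matrix(0, n, ncol(M))
    if (k == 0L) return(M)
    if (abs(k) >= n) return(out)
    if (k > 0L) out[(k + 1L):n, ] <- M[1L:(n - k), , drop = FALSE]
    else out[1L:(n + k), ] <- M[(1L - k):n, , drop = FALSE]
    out
  }
  A <- ad_value(a)
  ad_node(shift(A, s), list(a), function(g) list(shift(g, -s)))
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_value)
  widths <- vapply(vals, ncol, 1L)
  ad_node(do.call(cbind, vals), args, function(g) {
    stops <- cumsum(widths)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    lapply(seq_along(args), function(j) g[, starts[j]:stops[j], drop = FALSE])
  })
}

# Backward sweep from a scalar loss node; gradients accumulate in-place.
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  t <- tape_active()
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (is_ad(p) && !is.null(gs[[j]])) {
        p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
      }
    }
  }
  invisible(loss)
}

# --- Adam ------------------------------------------------------------------

# State for Adam over a named list of parameter matrices. `weight_decay` is
# classic L2 (added to the gradient), matching the optimiser the model
# defaults were tuned with.
adam_init <- function(params, lr = 0.002, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, wd = weight_decay,
    t = 0L,
    m = lapply(params, function(p) array(0, dim(as.matrix(p)))),
    v = lapply(params, function(p) array(0, dim(as.matrix(p))))
  )
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    if (opt$wd > 0) g <- g + opt$wd * params[[k]]
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g * g
    params[[k]] <- params[[k]] -
      opt$lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}
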