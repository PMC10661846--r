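# Tape-based reverse-mode automatic differentiation over dense matrices.
#
# Every op creates a node (an environment holding the value, the parent
# nodes and a backward closure) and appends it to the active tape. Calling
# ag_backward() on a scalar loss walks the tape in reverse creation order
# and accumulates gradients into each node's $grad. Parameter matrices are
# wrapped with ag_param() at the start of a forward pass; their gradients
# are read back after the backward sweep.
#
# The op set is exactly what the dual-graph network needs: affine maps,
# SiLU/sigmoid, column binding, row gather/scatter, segment (per-graph or
# per-atom) sums and softmax, row scaling, and the two losses (L1 on the
# sigmoid output, binary cross-entropy on the logit).

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_start <- function() {
  .ag$tape <- new.env(parent = emptyenv())
  .ag$tape$nodes <- vector("list", 256)
  .ag$tape$n <- 0L
  invisible(.ag$tape)
}

ag_tape_stop <- function() { .ag$tape <- NULL; invisible(NULL) }

.ag_node <- function(val, parents = list(), backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  tape <- .ag$tape
  if (!is.null(tape) && !is.null(backfn)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- node
  }
  node
}

.ag_acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

ag_const <- function(x) .ag_node(as.matrix(x))

ag_param <- function(x) {
  node <- .ag_node(as.matrix(x))
  node$is_param <- TRUE
  node
}

ag_matmul <- function(a, b) {
  .ag_node(a$val %*% b$val, list(a, b), function(node) {
    g <- node$grad
    .ag_acc(a, tcrossprod(g, b$val))
    .ag_acc(b, crossprod(a$val, g))
  })
}

# x: n x d, bias: 1 x d (broadcast over rows)
ag_add_bias <- function(x, bias) {
  v <- x$val
  .ag_node(v + rep(as.vector(bias$val), each = nrow(v)), list(x, bias),
           function(node) {
    g <- node$grad
    .ag_acc(x, g)
    .ag_acc(bias, matrix(colSums(g), 1))
  })
}

ag_add <- function(a, b) {
  .ag_node(a$val + b$val, list(a, b), function(node) {
    .ag_acc(a, node$grad); .ag_acc(b, node$grad)
  })
}

ag_silu <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  .ag_node(x$val * s, list(x), function(node) {
    .ag_acc(x, node$grad * (s * (1 + x$val * (1 - s))))
  })
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  .ag_node(s, list(x), function(node) {
    .ag_acc(x, node$grad * s * (1 - s))
  })
}

ag_cbind <- function(...) {
  xs <- list(...)
  widths <- vapply(xs, function(x) ncol(x$val), integer(1))
  .ag_node(do.call(cbind, lapply(xs, `[[`, "val")), xs, function(node) {
    g <- node$grad
    off <- 0L
    for (k in seq_along(xs)) {
      .ag_acc(xs[[k]], g[, off + seq_len(widths[k]), drop = FALSE])
      off <- off + widths[k]
    }
  })
}

# Gather rows: out[r, ] = x[idx[r], ]. Backward scatter-adds.
ag_rows <- function(x, idx) {
  idx <- as.integer(idx)
  .ag_node(x$val[idx, , drop = FALSE], list(x), function(node) {
    g <- node$grad
    acc <- rowsum(g, group = idx)
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    gx[as.integer(rownames(acc)), ] <- acc
    .ag_acc(x, gx)
  })
}

# Segment sum: out[s, ] = sum over rows r with idx[r] == s; groups 1..ngroups
# (empty groups yield zero rows).
ag_segment_sum <- function(x, idx, ngroups) {
  idx <- as.integer(idx)
  out <- matrix(0, ngroups, ncol(x$val))
  if (nrow(x$val) > 0) {
    v <- rowsum(x$val, group = idx)
    out[as.integer(rownames(v)), ] <- v
  }
  .ag_node(out, list(x), function(node) {
    .ag_acc(x, node$grad[idx, , drop = FALSE])
  })
}

# Column-wise softmax within segments defined by idx (values 1..ngroups).
ag_segment_softmax <- function(x, idx, ngroups) {
  idx <- as.integer(idx)
  v <- x$val
  mx <- apply(v, 2, function(col) tapply(col, idx, max)[as.character(idx)])
  e <- exp(v - mx)
  denom <- apply(e, 2, function(col) tapply(col, idx, sum)[as.character(idx)])
  p <- e / denom
  .ag_node(p, list(x), function(node) {
    g <- node$grad
    pg <- p * g
    s <- apply(pg, 2, function(col) tapply(col, idx, sum)[as.character(idx)])
    .ag_acc(x, pg - p * s)
  })
}

# Select columns of x.
ag_cols <- function(x, idx) {
  idx <- as.integer(idx)
  .ag_node(x$val[, idx, drop = FALSE], list(x), function(node) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    gx[, idx] <- node$grad
    .ag_acc(x, gx)
  })
}

# Scale each row of v (n x d) by scalar s (n x 1).
ag_scale_rows <- function(v, s) {
  .ag_node(v$val * as.vector(s$val), list(v, s), function(node) {
    g <- node$grad
    .ag_acc(v, g * as.vector(s$val))
    .ag_acc(s, matrix(rowSums(g * v$val), ncol = 1))
  })
}

# Mean absolute error between pred (n x 1) and a constant target.
ag_l1_loss <- function(pred, target) {
  d <- pred$val - as.matrix(target)
  .ag_node(matrix(mean(abs(d))), list(pred), function(node) {
    .ag_acc(pred, node$grad[1] * sign(d) / length(d))
  })
}

# Binary cross-entropy on logits z (n x 1) with 0/1 targets:
# mean(softplus(z) - y * z); gradient is (sigmoid(z) - y) / n.
ag_bce_logits <- function(z, target) {
  y <- as.matrix(target)
  zp <- z$val
  softplus <- ifelse(zp > 30, zp, log1p(exp(pmin(zp, 30))))
  .ag_node(matrix(mean(softplus - y * zp)), list(z), function(node) {
    s <- 1 / (1 + exp(-zp))
    .ag_acc(z, node$grad[1] * (s - y) / length(y))
  })
}

ag_backward <- function(loss) {
  if (length(loss$val) != 1) stop("backward() needs a scalar loss")
  tape <- .ag$tape
  if (is.null(tape)) stop("no active tape")
  loss$grad <- matrix(1)
  for (k in rev(seq_len(tape$n))) {
    node <- tape$nodes[[k]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node)
  }
  invisible(NULL)
}

# 2-layer MLP block: silu(x W1 + b1) W2 + b2, optionally a final activation.
ag_mlp <- function(x, p, prefix, final = c("linear", "silu")) {
  final <- match.arg(final)
  h <- ag_silu(ag_add_bias(ag_matmul(x, p[[paste0(prefix, "_W1")]]),
                           p[[paste0(prefix, "_b1")]]))
  out <- ag_add_bias(ag_matmul(h, p[[paste0(prefix, "_W2")]]),
                     p[[paste0(prefix, "_b2")]])
  if (final == "silu") ag_silu(out) else out
}

# ---- optimizer ------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
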