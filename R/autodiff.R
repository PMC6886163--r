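# Minimal reverse-mode automatic differentiation on R matrices.
#
# Every value on the tape is a numeric matrix (vectors are n x 1). Nodes are
# environments recording a value, an accumulated gradient, parent nodes and a
# backward closure. Operations append nodes in creation order, so the reverse
# of that order is a valid topological order for backpropagation -- no DFS
# (and no recursion-depth limit) is needed.

# The tape is a linked list threaded through the nodes themselves (each node
# keeps a `prev` pointer to the previously created node), so pushes are O(1)
# and backward walks creation order in reverse without materialising a list.
.tape <- new.env(parent = emptyenv())
.tape$active <- FALSE
.tape$last <- NULL

tape_start <- function() {
  .tape$active <- TRUE
  .tape$last <- NULL
  invisible(NULL)
}

tape_stop <- function() {
  .tape$active <- FALSE
  .tape$last <- NULL
  invisible(NULL)
}

is_node <- function(x) inherits(x, "ad_node")

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

new_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- as_mat(value)
  e$grad <- NULL
  e$backward <- backward
  class(e) <- "ad_node"
  if (.tape$active && !is.null(backward)) {
    e$prev <- .tape$last
    .tape$last <- e
  }
  e
}

#' @noRd
nd_value <- function(x) if (is_node(x)) x$value else as_mat(x)

# Leaf wrapping: parameters are leaves whose gradients we read after backward.
nd_leaf <- function(value) {
  e <- new_node(value)
  e$is_leaf <- TRUE
  e
}

accum_grad <- function(node, g) {
  gr <- node$grad
  node$grad <- if (is.null(gr)) g else gr + g
  invisible(NULL)
}

# Backpropagate from a scalar node through the active tape.
nd_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  accum_grad(loss, matrix(1, 1L, 1L))
  nd <- .tape$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad)) nd$backward(nd$grad)
    nd <- nd$prev
  }
  invisible(NULL)
}

# ---- elementwise and linear-algebra ops ----------------------------------

# Addition with scalar (1x1) broadcasting on either side.
nd_add <- function(a, b) {
  av <- nd_value(a); bv <- nd_value(b)
  broadcast_a <- length(av) == 1L && length(bv) > 1L
  broadcast_b <- length(bv) == 1L && length(av) > 1L
  val <- if (broadcast_a) av[1L] + bv else if (broadcast_b) av + bv[1L] else av + bv
  new_node(val, list(a, b), function(g) {
    if (is_node(a)) accum_grad(a, if (broadcast_a) sum(g) else g)
    if (is_node(b)) accum_grad(b, if (broadcast_b) sum(g) else g)
  })
}

nd_sub <- function(a, b) nd_add(a, nd_scale(b, -1))

nd_scale <- function(a, k) {
  av <- nd_value(a)
  new_node(av * k, list(a), function(g) {
    if (is_node(a)) accum_grad(a, g * k)
  })
}

nd_mul <- function(a, b) {
  av <- nd_value(a); bv <- nd_value(b)
  broadcast_a <- length(av) == 1L && length(bv) > 1L
  broadcast_b <- length(bv) == 1L && length(av) > 1L
  val <- if (broadcast_a) av[1L] * bv else if (broadcast_b) av * bv[1L] else av * bv
  new_node(val, list(a, b), function(g) {
    if (is_node(a)) {
      accum_grad(a, if (broadcast_a) sum(g * bv) else if (broadcast_b) g * bv[1L] else g * bv)
    }
    if (is_node(b)) {
      accum_grad(b, if (broadcast_b) sum(g * av) else if (broadcast_a) g * av[1L] else g * av)
    }
  })
}

nd_matmul <- function(a, b) {
  av <- nd_value(a); bv <- nd_value(b)
  new_node(av %*% bv, list(a, b), function(g) {
    if (is_node(a)) accum_grad(a, g %*% t(bv))
    if (is_node(b)) accum_grad(b, t(av) %*% g)
  })
}

# Column-vector dot product -> 1x1.
nd_dot <- function(a, b) nd_matmul(nd_t(a), b)

nd_t <- function(a) {
  av <- nd_value(a)
  new_node(t(av), list(a), function(g) {
    if (is_node(a)) accum_grad(a, t(g))
  })
}

# Add a column vector to every column of a matrix (bias broadcast).
nd_add_col <- function(a, bias) {
  av <- nd_value(a); bv <- nd_value(bias)
  stopifnot(nrow(av) == nrow(bv), ncol(bv) == 1L)
  new_node(av + as.vector(bv), list(a, bias), function(g) {
    if (is_node(a)) accum_grad(a, g)
    if (is_node(bias)) accum_grad(bias, matrix(rowSums(g), ncol = 1L))
  })
}

# Add a row vector to every row of a matrix.
nd_add_row <- function(a, bias) {
  av <- nd_value(a); bv <- nd_value(bias)
  stopifnot(ncol(av) == length(bv))
  new_node(sweep(av, 2L, as.vector(bv), "+"), list(a, bias), function(g) {
    if (is_node(a)) accum_grad(a, g)
    if (is_node(bias)) accum_grad(bias, matrix(colSums(g), nrow(bv), ncol(bv)))
  })
}

nd_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-nd_value(a)))
  new_node(s, list(a), function(g) {
    if (is_node(a)) accum_grad(a, g * s * (1 - s))
  })
}

nd_tanh <- function(a) {
  v <- tanh(nd_value(a))
  new_node(v, list(a), function(g) {
    if (is_node(a)) accum_grad(a, g * (1 - v^2))
  })
}

nd_relu <- function(a) {
  av <- nd_value(a)
  mask <- av > 0
  new_node(av * mask, list(a), function(g) {
    if (is_node(a)) accum_grad(a, g * mask)
  })
}

nd_log <- function(a) {
  av <- nd_value(a)
  new_node(log(av), list(a), function(g) {
    if (is_node(a)) accum_grad(a, g / av)
  })
}

nd_sum <- function(a) {
  av <- nd_value(a)
  new_node(sum(av), list(a), function(g) {
    if (is_node(a)) accum_grad(a, matrix(g[1L], nrow(av), ncol(av)))
  })
}

nd_mean <- function(a) nd_scale(nd_sum(a), 1 / length(nd_value(a)))

# Max-subtracted softmax over a column vector.
nd_softmax <- function(a) {
  av <- nd_value(a)
  z <- exp(av - max(av))
  p <- z / sum(z)
  new_node(p, list(a), function(g) {
    if (is_node(a)) accum_grad(a, p * (g - sum(p * g)))
  })
}

# Stack column vectors as rows of a matrix (n_vec x len).
nd_rbind <- function(vecs) {
  vals <- lapply(vecs, nd_value)
  val <- do.call(rbind, lapply(vals, function(v) as.vector(v)))
  new_node(val, vecs, function(g) {
    for (i in seq_along(vecs)) {
      if (is_node(vecs[[i]])) accum_grad(vecs[[i]], matrix(g[i, ], ncol = 1L))
    }
  })
}

# Concatenate column vectors vertically.
nd_vcat <- function(...) {
  vecs <- list(...)
  vals <- lapply(vecs, nd_value)
  lens <- vapply(vals, length, integer(1L))
  val <- matrix(unlist(lapply(vals, as.vector)), ncol = 1L)
  new_node(val, vecs, function(g) {
    off <- 0L
    for (i in seq_along(vecs)) {
      if (is_node(vecs[[i]])) {
        accum_grad(vecs[[i]], matrix(g[(off + 1L):(off + lens[i]), 1L], ncol = 1L))
      }
      off <- off + lens[i]
    }
  })
}

# Concatenate matrices by column (filter-axis concatenation after conv).
nd_cbind <- function(mats) {
  vals <- lapply(mats, nd_value)
  ncols <- vapply(vals, ncol, integer(1L))
  val <- do.call(cbind, vals)
  new_node(val, mats, function(g) {
    off <- 0L
    for (i in seq_along(mats)) {
      if (is_node(mats[[i]])) {
        accum_grad(mats[[i]], g[, (off + 1L):(off + ncols[i]), drop = FALSE])
      }
      off <- off + ncols[i]
    }
  })
}

# Extract row i of a matrix as a column vector.
nd_row <- function(a, i) {
  av <- nd_value(a)
  new_node(matrix(av[i, ], ncol = 1L), list(a), function(g) {
    if (is_node(a)) {
      ga <- matrix(0, nrow(av), ncol(av))
      ga[i, ] <- as.vector(g)
      accum_grad(a, ga)
    }
  })
}

nd_reshape_vec <- function(a) {
  av <- nd_value(a)
  new_node(matrix(as.vector(av), ncol = 1L), list(a), function(g) {
    if (is_node(a)) accum_grad(a, matrix(as.vector(g), nrow(av), ncol(av)))
  })
}

# ---- convolution / pooling via gathered windows ---------------------------
#
# Feature maps are stored positions x filters. `idx` is an n_out x K matrix of
# 1-based row indices into the input (rows n_in + 1 .. address an appended pad
# row). Within a fixed tap k the indices are distinct (stride >= 1), so
# scatter-add per tap is safe.

gather_pad <- function(v, idx_col, pad_value = 0) {
  n_in <- nrow(v)
  pad <- idx_col > n_in
  if (!any(pad)) return(v[idx_col, , drop = FALSE])
  idx_col[pad] <- 1L
  out <- v[idx_col, , drop = FALSE]
  out[pad, ] <- pad_value
  out
}

# im2col: input (n_in x c_in) -> (n_out x K*c_in), tap-major column order.
nd_im2col <- function(a, idx) {
  av <- nd_value(a)
  K <- ncol(idx)
  c_in <- ncol(av)
  blocks <- lapply(seq_len(K), function(k) gather_pad(av, idx[, k], 0))
  val <- do.call(cbind, blocks)
  n_in <- nrow(av)
  new_node(val, list(a), function(g) {
    if (is_node(a)) {
      ga <- matrix(0, n_in, c_in)
      for (k in seq_len(K)) {
        gk <- g[, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
        m <- idx[, k]
        keep <- m <= n_in
        if (any(keep)) ga[m[keep], ] <- ga[m[keep], , drop = FALSE] + gk[keep, , drop = FALSE]
      }
      accum_grad(a, ga)
    }
  })
}

# Max pool over gathered taps; padding behaves as -Inf.
nd_maxpool <- function(a, idx) {
  av <- nd_value(a)
  K <- ncol(idx)
  n_in <- nrow(av)
  M <- gather_pad(av, idx[, 1L], -Inf)
  arg <- matrix(1L, nrow(M), ncol(M))
  if (K > 1L) {
    for (k in 2L:K) {
      blk <- gather_pad(av, idx[, k], -Inf)
      upd <- blk > M
      M[upd] <- blk[upd]
      arg[upd] <- k
    }
  }
  new_node(M, list(a), function(g) {
    if (is_node(a)) {
      ga <- matrix(0, n_in, ncol(av))
      for (k in seq_len(K)) {
        sel <- arg == k
        if (!any(sel)) next
        gk <- g * sel
        m <- idx[, k]
        keep <- m <= n_in
        if (any(keep)) ga[m[keep], ] <- ga[m[keep], , drop = FALSE] + gk[keep, , drop = FALSE]
      }
      accum_grad(a, ga)
    }
  })
}

# Average pool; pads count toward the divisor (framework default).
nd_avgpool <- function(a, idx) {
  av <- nd_value(a)
  K <- ncol(idx)
  n_in <- nrow(av)
  acc <- gather_pad(av, idx[, 1L], 0)
  if (K > 1L) for (k in 2L:K) acc <- acc + gather_pad(av, idx[, k], 0)
  val <- acc / K
  new_node(val, list(a), function(g) {
    if (is_node(a)) {
      ga <- matrix(0, n_in, ncol(av))
      gk <- g / K
      for (k in seq_len(K)) {
        m <- idx[, k]
        keep <- m <= n_in
        if (any(keep)) ga[m[keep], ] <- ga[m[keep], , drop = FALSE] + gk[keep, , drop = FALSE]
      }
      accum_grad(a, ga)
    }
  })
}

# Clip values to [lo, hi]; gradient is zero where the clip is active.
nd_clip <- function(a, lo, hi) {
  av <- nd_value(a)
  mask <- av >= lo & av <= hi
  new_node(pmin(pmax(av, lo), hi), list(a), function(g) {
    if (is_node(a)) accum_grad(a, g * mask)
  })
}

# Inverted dropout: scales kept units by 1/(1-rate); mask drawn from the
# session RNG so runs are reproducible under a fixed seed.
nd_dropout <- function(a, rate) {
  if (rate <= 0) return(a)
  av <- nd_value(a)
  mask <- matrix(stats::rbinom(length(av), 1L, 1 - rate), nrow(av), ncol(av)) / (1 - rate)
  new_node(av * mask, list(a), function(g) {
    if (is_node(a)) accum_grad(a, g * mask)
  })
}
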