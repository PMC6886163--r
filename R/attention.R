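# Channel-wise and time-wise attention, and the bidirectional GRU backbone.
#
# Public single-pair operations (fusional_rate, attention_energy, ...) work on
# plain numeric vectors and mirror the vectorised tape implementations used
# during training; tests assert their equivalence.

#' Channel-attention parameters
#'
#' @param p Feature dimension of the multi-view vectors.
#' @return List with weight vectors `W_rg`, `W_rc`, `W_ec` (length `p`) and
#'   scalar biases `b_rc`, `b_ec`, Glorot-initialised from the current RNG.
#' @export
channel_attention_params <- function(p) {
  list(W_rg = glorot_uniform(p, 1L, p, 1L),
       W_rc = glorot_uniform(p, 1L, p, 1L),
       b_rc = matrix(0, 1L, 1L),
       W_ec = glorot_uniform(p, 1L, p, 1L),
       b_ec = matrix(0, 1L, 1L))
}

#' Time-attention parameters
#'
#' @param q Per-direction GRU hidden size; hidden states have length `2q`.
#' @return List with weight vectors `W_rt`, `W_ri`, `W_et` (length `2q`) and
#'   scalar biases `b_rt`, `b_et`.
#' @export
time_attention_params <- function(q) {
  list(W_rt = glorot_uniform(2L * q, 1L, 2L * q, 1L),
       W_ri = glorot_uniform(2L * q, 1L, 2L * q, 1L),
       b_rt = matrix(0, 1L, 1L),
       W_et = glorot_uniform(2L * q, 1L, 2L * q, 1L),
       b_et = matrix(0, 1L, 1L))
}

#' Fusional rate between global- and channel-view features
#'
#' `r = sigmoid(W_rg . s + W_rc . d + b_rc)`: a learned gate in `[0, 1]`
#' deciding how much channel-view information enters the attention energy.
#'
#' @param s Global-view feature vector (length p).
#' @param d Channel-view feature vector (length p).
#' @param params [channel_attention_params()].
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' p <- channel_attention_params(4)
#' fusional_rate(rnorm(4), rnorm(4), p)
fusional_rate <- function(s, d, params) {
  s <- as.vector(s); d <- as.vector(d)
  if (length(s) != length(params$W_rg) || length(d) != length(params$W_rc)) {
    stop("dimension mismatch in fusional_rate", call. = FALSE)
  }
  plogis(sum(params$W_rg * s) + sum(params$W_rc * d) + as.vector(params$b_rc))
}

#' Attention energy of one channel
#'
#' `e = W_ec . ((1 - r) * s + r * d) + b_ec`: the unnormalised contribution
#' score of a channel, computed on the elementwise convex blend of its two
#' views.
#'
#' @param s,d Global- and channel-view feature vectors.
#' @param r Fusional rate in `[0, 1]`.
#' @param params [channel_attention_params()].
#' @return Scalar energy.
#' @export
attention_energy <- function(s, d, r, params) {
  if (r < 0 || r > 1) stop("fusional rate outside [0, 1]", call. = FALSE)
  blend <- (1 - r) * as.vector(s) + r * as.vector(d)
  sum(params$W_ec * blend) + as.vector(params$b_ec)
}

#' Softmax-normalised channel contribution scores
#'
#' @param energies Numeric vector of C finite energies.
#' @return Simplex vector of length C (max-subtracted softmax).
#' @export
channel_scores <- function(energies) {
  if (any(!is.finite(energies))) stop("non-finite attention energy", call. = FALSE)
  z <- exp(energies - max(energies))
  z / sum(z)
}

#' Fuse the multi-view features of one epoch
#'
#' `x = s (+) sum_c alpha_c d_c`: the global view concatenated with the
#' score-weighted channel-view aggregate, giving a length-`2p` fused vector.
#'
#' @param s Global-view vector (length p).
#' @param d_list List of C channel-view vectors.
#' @param alpha Simplex weight vector of length C.
#' @return Numeric vector of length `2p`.
#' @export
channel_fuse <- function(s, d_list, alpha) {
  if (abs(sum(alpha) - 1) > 1e-6 || any(alpha < -1e-6)) {
    stop("alpha is not on the probability simplex", call. = FALSE)
  }
  agg <- Reduce(`+`, Map(function(a, d) a * as.vector(d), alpha, d_list))
  c(as.vector(s), agg)
}

# Vectorised channel attention on the tape. D is a node/matrix (C x p), s a
# column vector; exploits W.((1-r)s + r d) = (1-r)(W.s) + r(W.d).
channel_attention_forward <- function(s, D, prm) {
  ws <- nd_dot(prm$W_rg, s)                              # 1x1
  rd <- nd_matmul(D, prm$W_rc)                           # C x 1
  r <- nd_sigmoid(nd_add(nd_add(rd, ws), prm$b_rc))      # C x 1
  es <- nd_dot(prm$W_ec, s)                              # 1x1
  ed <- nd_matmul(D, prm$W_ec)                           # C x 1
  one_minus_r <- nd_scale(nd_add(nd_scale(r, -1), 1), 1) # 1 - r
  e <- nd_add(nd_add(nd_mul(one_minus_r, es), nd_mul(r, ed)), prm$b_ec)
  alpha <- nd_softmax(e)                                 # C x 1
  agg <- nd_matmul(nd_t(D), alpha)                       # p x 1
  list(alpha = alpha, fused = nd_vcat(s, agg), rate = r)
}

# ---- bidirectional GRU ----------------------------------------------------

gru_layer_params <- function(input_dim, q) {
  gate <- function() list(
    W = glorot_uniform(q, input_dim, input_dim, q),
    U = glorot_uniform(q, q, q, q),
    b = matrix(0, q, 1L))
  list(z = gate(), r = gate(), n = gate())
}

#' Parameters of the 2-layer bidirectional GRU
#'
#' Independent forward and backward stacks, two layers each; layer 1 consumes
#' the fused vectors (length `2p`), layer 2 the concatenated bidirectional
#' output of layer 1 (length `2q`).
#'
#' @param input_dim Input dimension of layer 1.
#' @param q Per-direction hidden size.
#' @return Nested parameter list.
#' @export
bgru_params <- function(input_dim, q) {
  list(
    layer1 = list(fwd = gru_layer_params(input_dim, q),
                  bwd = gru_layer_params(input_dim, q)),
    layer2 = list(fwd = gru_layer_params(2L * q, q),
                  bwd = gru_layer_params(2L * q, q)),
    q = as.integer(q)
  )
}

# One GRU step; x and h are column vectors/nodes.
gru_cell <- function(x, h, prm) {
  z <- nd_sigmoid(nd_add(nd_add(nd_matmul(prm$z$W, x), nd_matmul(prm$z$U, h)), prm$z$b))
  r <- nd_sigmoid(nd_add(nd_add(nd_matmul(prm$r$W, x), nd_matmul(prm$r$U, h)), prm$r$b))
  n <- nd_tanh(nd_add(nd_add(nd_matmul(prm$n$W, x), nd_mul(r, nd_matmul(prm$n$U, h))), prm$n$b))
  # h' = (1 - z) * n + z * h
  nd_add(nd_mul(nd_sub(ones_like(z), z), n), nd_mul(z, h))
}

ones_like <- function(x) matrix(1, nrow(nd_value(x)), 1L)

gru_direction <- function(x_seq, prm, q, reverse = FALSE) {
  T_len <- length(x_seq)
  order_idx <- if (reverse) rev(seq_len(T_len)) else seq_len(T_len)
  h <- matrix(0, q, 1L)
  out <- vector("list", T_len)
  for (t in order_idx) {
    h <- gru_cell(x_seq[[t]], h, prm)
    out[[t]] <- h
  }
  out
}

#' Bidirectional GRU forward pass
#'
#' Runs the 2-layer bidirectional GRU over a fused-vector sequence; at each
#' timestep the hidden state is the concatenation of the forward and backward
#' per-direction states of the top layer (length `2q`).
#'
#' @param x_seq List of T input column vectors (plain or tape nodes).
#' @param params [bgru_params()].
#' @return List of T hidden vectors of length `2q` (plain numeric when the
#'   inputs are plain).
#' @export
bgru_forward <- function(x_seq, params) {
  if (length(x_seq) < 1L) stop("empty input sequence", call. = FALSE)
  plain <- !any(vapply(x_seq, is_node, logical(1L)))
  x_seq <- lapply(x_seq, as_mat_or_node)
  q <- params$q
  for (layer in list(params$layer1, params$layer2)) {
    fw <- gru_direction(x_seq, layer$fwd, q, reverse = FALSE)
    bw <- gru_direction(x_seq, layer$bwd, q, reverse = TRUE)
    x_seq <- Map(function(f, b) nd_vcat(f, b), fw, bw)
  }
  if (plain) lapply(x_seq, function(h) as.vector(nd_value(h))) else x_seq
}

# ---- time-wise attention --------------------------------------------------

#' Time-wise contribution scores for one query timestep
#'
#' For query `t` against every sequence position `i`:
#' `r_ti = sigmoid(W_rt . h_t + W_ri . h_i + b_rt)`,
#' `e_ti = W_et . ((1 - r_ti) * h_t + r_ti * h_i) + b_et`,
#' `beta_t = softmax(e_t, 1..T)`.
#'
#' @param h_seq List of T hidden vectors (length 2q each).
#' @param t Query index in `1..T`.
#' @param params [time_attention_params()].
#' @return Simplex vector of length T.
#' @export
time_scores <- function(h_seq, t, params) {
  T_len <- length(h_seq)
  if (t < 1L || t > T_len) stop("query index out of range", call. = FALSE)
  h_t <- as.vector(h_seq[[t]])
  e <- vapply(seq_len(T_len), function(i) {
    h_i <- as.vector(h_seq[[i]])
    r <- plogis(sum(params$W_rt * h_t) + sum(params$W_ri * h_i) + as.vector(params$b_rt))
    sum(params$W_et * ((1 - r) * h_t + r * h_i)) + as.vector(params$b_et)
  }, numeric(1L))
  channel_scores(e)
}

#' Temporal context vector
#'
#' `c_t = sum_i beta_ti h_i`: the score-weighted aggregation of the sequence
#' hidden states. `form = "literal"` instead evaluates the degenerate variant
#' that weights the query state itself, `sum_i beta_ti h_t`, which collapses
#' to `h_t` for any normalised `beta` — kept as a tested negative control for
#' the aggregation choice.
#'
#' @param h_seq List of T hidden vectors.
#' @param beta Simplex vector of length T.
#' @param t Query index (used only by the literal form).
#' @param form `"aggregate"` (default) or `"literal"`.
#' @return Numeric vector of length 2q.
#' @export
time_context <- function(h_seq, beta, t = 1L, form = c("aggregate", "literal")) {
  form <- match.arg(form)
  if (abs(sum(beta) - 1) > 1e-6 || any(beta < -1e-6)) {
    stop("beta is not on the probability simplex", call. = FALSE)
  }
  if (form == "literal") {
    h_t <- as.vector(h_seq[[t]])
    return(Reduce(`+`, lapply(beta, function(b) b * h_t)))
  }
  Reduce(`+`, Map(function(b, h) b * as.vector(h), beta, h_seq))
}

# Vectorised time attention on the tape: H is a T x 2q node/matrix.
time_attention_forward <- function(H, prm) {
  rH <- nd_matmul(H, prm$W_ri)            # T x 1: W_ri . h_i
  eH <- nd_matmul(H, prm$W_et)            # T x 1: W_et . h_i
  qH <- nd_matmul(H, prm$W_rt)            # T x 1: W_rt . h_t per query
  aH <- eH                                # W_et . h_t per query (same projection)
  T_len <- nrow(nd_value(H))
  lapply(seq_len(T_len), function(t) {
    r <- nd_sigmoid(nd_add(nd_add(rH, nd_row(qH, t)), prm$b_rt))        # T x 1
    one_minus_r <- nd_add(nd_scale(r, -1), 1)
    e <- nd_add(nd_add(nd_mul(one_minus_r, nd_row(aH, t)), nd_mul(r, eH)), prm$b_et)
    beta <- nd_softmax(e)
    ctx <- nd_matmul(nd_t(H), beta)       # 2q x 1
    list(beta = beta, context = ctx)
  })
}
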