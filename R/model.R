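#' Build the full hybrid-attention model
#'
#' Assembles every learnable component: the multi-view encoder (one 1-D
#' encoder per channel plus the 2-D global encoder), the channel-wise
#' attention, the 2-layer bidirectional GRU, the time-wise attention and the
#' classifier head. All parameters are initialised from the current RNG
#' stream, so `set.seed()` before building gives identical models.
#'
#' @param input_lens Per-channel input lengths (native-rate samples per
#'   30-s epoch in the time domain; flattened spectrogram length in the
#'   frequency domain).
#' @param montage_size Number of channels C.
#' @param p,q,r Feature, GRU (per direction) and head dimensions; the
#'   full-scale configuration uses 128 for all three.
#' @param n_classes Number of stage classes (5).
#' @param spec Encoder configuration, see [default_encoder_spec()].
#' @param activation Head nonlinearity.
#' @param share_channel_weights Share one channel-encoder parameter set.
#' @return A `sleepatt_model` list.
#' @export
#' @examples
#' set.seed(1)
#' m <- build_model(240, montage_size = 2, p = 16, q = 16, r = 16,
#'                  spec = toy_encoder_spec())
#' m$dims
build_model <- function(input_lens, montage_size, p = 128L, q = 128L, r = 128L,
                        n_classes = 5L, spec = default_encoder_spec(),
                        activation = "tanh", share_channel_weights = FALSE) {
  encoder <- build_encoder(input_lens, montage_size, p = p, spec = spec,
                           share_channel_weights = share_channel_weights)
  structure(list(
    encoder = encoder,
    chan_attn = channel_attention_params(p),
    gru = bgru_params(2L * p, q),
    time_attn = time_attention_params(q),
    head = head_params(q, r, n_classes, activation),
    dims = list(p = as.integer(p), q = as.integer(q), r = as.integer(r),
                n_classes = as.integer(n_classes), C = as.integer(montage_size))
  ), class = "sleepatt_model")
}

# ---- parameter flattening -------------------------------------------------

model_param_list <- function(model) {
  list(encoder = model$encoder$params, chan_attn = model$chan_attn,
       gru = model$gru, time_attn = model$time_attn, head = model$head)
}

#' Flatten all learnable tensors into a named list
#'
#' @param model A `sleepatt_model`.
#' @return Named list of numeric matrices with dotted keys such as
#'   `encoder.channel.1.stages.1.2.W` or `head.W_s`.
#' @export
flatten_params <- function(model) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.matrix(x) && is.numeric(x)) {
      out[[prefix]] <<- x
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste(prefix, key, sep = "."))
      }
    }
  }
  walk(model_param_list(model), "par")
  names(out) <- sub("^par\\.", "", names(out))
  out
}

assign_by_path <- function(x, path, value) {
  key <- path[1L]
  idx <- suppressWarnings(as.integer(key))
  k <- if (!is.na(idx) && (is.null(names(x)) || !(key %in% names(x)))) idx else key
  if (length(path) == 1L) x[[k]] <- value
  else x[[k]] <- assign_by_path(x[[k]], path[-1L], value)
  x
}

#' Write a flat parameter list back into a model
#'
#' @param model A `sleepatt_model`.
#' @param flat Named list as produced by [flatten_params()] (values may be
#'   plain matrices or tape leaves whose `$value` is taken).
#' @return The updated model.
#' @export
set_params <- function(model, flat) {
  parts <- model_param_list(model)
  for (nm in names(flat)) {
    v <- flat[[nm]]
    if (is_node(v)) v <- v$value
    parts <- assign_by_path(parts, strsplit(nm, ".", fixed = TRUE)[[1L]], v)
  }
  model$encoder$params <- parts$encoder
  model$chan_attn <- parts$chan_attn
  model$gru <- parts$gru
  model$time_attn <- parts$time_attn
  model$head <- parts$head
  model
}

# A model whose matrices are replaced by tape leaves; the leaves are also
# returned flat so gradients can be read after backward.
wrap_model_params <- function(model) {
  flat <- flatten_params(model)
  leaves <- lapply(flat, nd_leaf)
  model <- set_params_nodes(model, leaves)
  list(model = model, leaves = leaves)
}

set_params_nodes <- function(model, leaves) {
  parts <- model_param_list(model)
  for (nm in names(leaves)) {
    parts <- assign_by_path(parts, strsplit(nm, ".", fixed = TRUE)[[1L]], leaves[[nm]])
  }
  model$encoder$params <- parts$encoder
  model$chan_attn <- parts$chan_attn
  model$gru <- parts$gru
  model$time_attn <- parts$time_attn
  model$head <- parts$head
  model
}

# ---- full forward pass ----------------------------------------------------

# Forward one window (list of epochs) through the whole stack. Works on plain
# parameters (evaluation) or node-wrapped parameters (training); dropout is
# applied only when train = TRUE.
model_forward <- function(model, epochs, train = FALSE, dropout = 0.5) {
  enc <- model$encoder
  C <- enc$arch$montage_size
  fused <- vector("list", length(epochs))
  alpha <- vector("list", length(epochs))
  for (t in seq_along(epochs)) {
    ep <- epochs[[t]]
    d <- lapply(seq_len(C), function(c) {
      arch <- enc$arch$channel[[c]]
      prm <- channel_params(enc$params, c, enc$arch)
      encoder_head(conv_stack_forward(as_mat(ep$channels[[c]]), prm$stages, arch), prm$proj)
    })
    s <- {
      inp <- matrix(as.vector(t(ep$matrix)), ncol = 1L)
      encoder_head(conv_stack_forward(inp, enc$params$global$stages, enc$arch$global),
                   enc$params$global$proj)
    }
    D <- nd_rbind(d)
    ca <- channel_attention_forward(s, D, model$chan_attn)
    x_t <- ca$fused
    if (train && dropout > 0) x_t <- nd_dropout(x_t, dropout)
    fused[[t]] <- x_t
    alpha[[t]] <- ca$alpha
  }
  h_seq <- bgru_forward(fused, model$gru)
  H <- nd_rbind(h_seq)
  ta <- time_attention_forward(H, model$time_attn)
  probs <- vector("list", length(epochs))
  beta <- vector("list", length(epochs))
  act <- if (identical(model$head$activation, "relu")) nd_relu else nd_tanh
  for (t in seq_along(epochs)) {
    v <- nd_vcat(ta[[t]]$context, h_seq[[t]])
    h_hat <- act(nd_add(nd_matmul(model$head$W_h, v), model$head$b_h))
    if (train && dropout > 0) h_hat <- nd_dropout(h_hat, dropout)
    logits <- nd_add(nd_matmul(model$head$W_s, h_hat), model$head$b_s)
    probs[[t]] <- nd_softmax(logits)
    beta[[t]] <- ta[[t]]$beta
  }
  list(probs = probs, alpha = alpha, beta = beta, h = h_seq)
}

# Two-term cross-entropy loss node over one window.
window_loss_node <- function(probs, label_idx, n_classes, form = "two_term", eps = 1e-7) {
  terms <- vector("list", length(probs))
  for (t in seq_along(probs)) {
    y <- matrix(0, n_classes, 1L)
    y[label_idx[t], 1L] <- 1
    p <- nd_clip(probs[[t]], eps, 1 - eps)
    tt <- nd_dot(y, nd_log(p))
    if (form == "two_term") {
      tt <- nd_add(tt, nd_dot(1 - y, nd_log(nd_sub(matrix(1, n_classes, 1L), p))))
    }
    terms[[t]] <- tt
  }
  total <- terms[[1L]]
  if (length(terms) > 1L) for (t in 2L:length(terms)) total <- nd_add(total, terms[[t]])
  nd_scale(total, -1 / length(terms))
}

#' Evaluate the model on epoch sequences
#'
#' Runs the forward pass in evaluation mode (no dropout) over each sequence,
#' windowed like training, and returns one row per epoch with the five class
#' probabilities, the predicted and the true stage, plus the channel
#' attention weights in a nested list-column-free long table via
#' [attention_weights()].
#'
#' @param model A `sleepatt_model`.
#' @param sequences List of `epoch_sequence`s (see [preprocess_record()]).
#' @param window Epochs per attention window.
#' @return Tibble with columns `subject`, `t`, `stage`, `pred`,
#'   `p_wake, p_rem, p_s1, p_s2, p_s3`.
#' @export
predict_sequences <- function(model, sequences, window = 25L) {
  stages <- sleep_stages()[seq_len(model$dims$n_classes)]
  rows <- purrr::map_dfr(sequences, function(seqn) {
    wins <- make_windows(seqn$epochs, window)
    purrr::map_dfr(wins, function(w) {
      fw <- model_forward(model, w, train = FALSE)
      P <- do.call(rbind, lapply(fw$probs, function(p) as.vector(nd_value(p))))
      tibble::tibble(
        subject = seqn$subject_id,
        t = vapply(w, `[[`, integer(1L), "t_index"),
        stage = vapply(w, `[[`, character(1L), "label"),
        pred = stages[max.col(P, ties.method = "first")],
        p_wake = P[, 1L], p_rem = P[, 2L], p_s1 = P[, 3L],
        p_s2 = P[, 4L], p_s3 = P[, 5L]
      )
    })
  })
  rows
}

# Split one record's epochs into attention windows of at most `window`
# epochs (stride = window; the trailing remainder forms a shorter window).
make_windows <- function(epochs, window) {
  T_len <- length(epochs)
  starts <- seq(1L, T_len, by = window)
  lapply(starts, function(s) epochs[s:min(s + window - 1L, T_len)])
}

#' Channel- and time-attention diagnostics
#'
#' Recomputes the forward pass in evaluation mode and exports the attention
#' weights in tidy long form for interpretability plots: channel rows carry
#' the per-epoch channel scores alpha, time rows the per-query scores beta
#' over window positions.
#'
#' @param model A `sleepatt_model`.
#' @param sequence One `epoch_sequence`.
#' @param window Epochs per attention window.
#' @return Tibble with columns `subject`, `t`, `kind` (`"channel"`/`"time"`),
#'   `index` (channel number or attended window position), `weight`.
#' @export
attention_weights <- function(model, sequence, window = 25L) {
  wins <- make_windows(sequence$epochs, window)
  purrr::map_dfr(wins, function(w) {
    fw <- model_forward(model, w, train = FALSE)
    ts <- vapply(w, `[[`, integer(1L), "t_index")
    ch <- purrr::map_dfr(seq_along(w), function(t) {
      a <- as.vector(nd_value(fw$alpha[[t]]))
      tibble::tibble(subject = sequence$subject_id, t = ts[t], kind = "channel",
                     index = seq_along(a), weight = a)
    })
    tm <- purrr::map_dfr(seq_along(w), function(t) {
      b <- as.vector(nd_value(fw$beta[[t]]))
      tibble::tibble(subject = sequence$subject_id, t = ts[t], kind = "time",
                     index = seq_along(b), weight = b)
    })
    dplyr::bind_rows(ch, tm)
  })
}
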