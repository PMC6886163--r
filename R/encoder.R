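#' Build the multi-view encoder
#'
#' Instantiates one independent 1-D channel encoder per channel (parameters
#' are not shared unless `share_channel_weights = TRUE`) plus one 2-D global
#' encoder, each ending in a flatten and a learned ReLU projection to the
#' common feature dimension `p`. Gather indices for every convolution and
#' pooling stage are precomputed from the per-channel input lengths; a stage
#' whose output length would reach zero raises a configuration error at build
#' time, and so does a stage whose parallel branches would emit unequal
#' lengths.
#'
#' Initialisation is Glorot-style uniform (fan-in/fan-out scaled) from the
#' current RNG stream, so builds are reproducible under `set.seed()`.
#'
#' @param input_lens Integer vector of per-channel input lengths (recycled to
#'   the montage size).
#' @param montage_size Number of channels C.
#' @param p Output feature dimension of every encoder.
#' @param spec An `encoder_spec` (see [default_encoder_spec()]).
#' @param share_channel_weights Use one parameter set for all channel
#'   encoders instead of C independent sets.
#' @return An `encoder` list with `arch` (gather indices, shapes) and
#'   `params` (weight matrices).
#' @export
#' @examples
#' set.seed(1)
#' enc <- build_encoder(240, montage_size = 2, p = 16, spec = toy_encoder_spec())
#' length(enc$params$channel)
build_encoder <- function(input_lens, montage_size, p = 128L,
                          spec = default_encoder_spec(),
                          share_channel_weights = FALSE) {
  stopifnot(inherits(spec, "encoder_spec"), montage_size >= 1L, p >= 1L)
  input_lens <- as.integer(rep_len(input_lens, montage_size))

  plan_1d <- function(L) {
    stages <- list()
    filters_in <- 1L
    for (si in seq_along(spec$stages_1d)) {
      st <- spec$stages_1d[[si]]
      outs <- vapply(st$branches, function(b) conv_out_len(L, b$kernel, b$stride, b$padding),
                     integer(1L))
      if (length(unique(outs)) != 1L) {
        stop(sprintf("stage %d branches emit unequal lengths (%s) for input %d",
                     si, paste(outs, collapse = ", "), L), call. = FALSE)
      }
      idx <- lapply(st$branches, function(b) im2col_idx_1d(L, b$kernel, b$stride, b$padding))
      filters_out <- sum(vapply(st$branches, `[[`, integer(1L), "filters"))
      L_conv <- outs[1L]
      pool_idx <- im2col_idx_1d(L_conv, st$pool$size, st$pool$stride, st$pool$padding)
      stages[[si]] <- list(conv_idx = idx, pool_idx = pool_idx,
                           pool_mode = st$pool$mode, filters_in = filters_in,
                           filters_out = filters_out)
      filters_in <- filters_out
      L <- nrow(pool_idx)
    }
    list(stages = stages, flat_dim = L * filters_in)
  }

  plan_2d <- function(H, W) {
    stages <- list()
    filters_in <- 1L
    for (si in seq_along(spec$stages_2d)) {
      st <- spec$stages_2d[[si]]
      outs <- lapply(st$branches, function(b) {
        c(conv_out_len(H, b$kernel[1L], b$stride[1L], b$padding[1L]),
          conv_out_len(W, b$kernel[2L], b$stride[2L], b$padding[2L]))
      })
      if (length(unique(vapply(outs, paste, character(1L), collapse = "x"))) != 1L) {
        stop(sprintf("2-D stage %d branches emit unequal shapes", si), call. = FALSE)
      }
      idx <- lapply(st$branches, function(b) {
        im2col_idx_2d(H, W, b$kernel[1L], b$kernel[2L], b$stride[1L], b$stride[2L],
                      b$padding[1L], b$padding[2L])
      })
      H_c <- outs[[1L]][1L]; W_c <- outs[[1L]][2L]
      pk <- st$pool
      kh <- if (is.na(pk$size[1L])) H_c else pk$size[1L]
      sh <- if (is.na(pk$stride[1L])) kh else pk$stride[1L]
      pool_idx <- im2col_idx_2d(H_c, W_c, kh, pk$size[2L], sh, pk$stride[2L],
                                pk$padding[1L], pk$padding[2L])
      filters_out <- sum(vapply(st$branches, `[[`, integer(1L), "filters"))
      stages[[si]] <- list(conv_idx = idx, pool_idx = pool_idx,
                           pool_mode = pk$mode, filters_in = filters_in,
                           filters_out = filters_out)
      filters_in <- filters_out
      hw <- attr(pool_idx, "out_hw")
      H <- hw[1L]; W <- hw[2L]
    }
    list(stages = stages, flat_dim = H * W * filters_in)
  }

  init_conv_params <- function(stage_specs, plan) {
    lapply(seq_along(stage_specs), function(si) {
      st <- stage_specs[[si]]
      c_in <- plan$stages[[si]]$filters_in
      lapply(st$branches, function(b) {
        k_total <- prod(b$kernel)
        list(W = glorot_uniform(k_total * c_in, b$filters, k_total * c_in,
                                k_total * b$filters),
             b = matrix(0, 1L, b$filters))
      })
    })
  }

  init_proj <- function(flat_dim) {
    list(W = glorot_uniform(p, flat_dim, flat_dim, p), b = matrix(0, p, 1L))
  }

  arch_ch <- lapply(input_lens, plan_1d)
  arch_g <- plan_2d(montage_size, max(input_lens))

  n_param_sets <- if (share_channel_weights) 1L else montage_size
  # shared weights require identical per-channel flatten dims
  if (share_channel_weights && length(unique(vapply(arch_ch, `[[`, integer(1L), "flat_dim"))) != 1L) {
    stop("share_channel_weights requires equal per-channel input lengths", call. = FALSE)
  }
  params_ch <- lapply(seq_len(n_param_sets), function(i) {
    list(stages = init_conv_params(spec$stages_1d, arch_ch[[i]]),
         proj = init_proj(arch_ch[[i]]$flat_dim))
  })
  params_g <- list(stages = init_conv_params(spec$stages_2d, arch_g),
                   proj = init_proj(arch_g$flat_dim))

  structure(list(
    arch = list(channel = arch_ch, global = arch_g,
                montage_size = montage_size, input_lens = input_lens, p = as.integer(p),
                share_channel_weights = share_channel_weights),
    params = list(channel = params_ch, global = params_g)
  ), class = "encoder")
}

# Shared conv-stack forward used by both views; `x` is a (positions x c_in)
# matrix or node, `stage_params`/`stage_arch` the per-stage weights/indices.
conv_stack_forward <- function(x, stage_params, stage_arch) {
  for (si in seq_along(stage_arch$stages)) {
    st <- stage_arch$stages[[si]]
    branches <- lapply(seq_along(st$conv_idx), function(bi) {
      cols <- nd_im2col(x, st$conv_idx[[bi]])
      nd_relu(nd_add_row(nd_matmul(cols, stage_params[[si]][[bi]]$W),
                         stage_params[[si]][[bi]]$b))
    })
    x <- if (length(branches) == 1L) branches[[1L]] else nd_cbind(branches)
    x <- if (st$pool_mode == "max") nd_maxpool(x, st$pool_idx) else nd_avgpool(x, st$pool_idx)
  }
  x
}

encoder_head <- function(x, proj) {
  flat <- nd_reshape_vec(x)
  nd_relu(nd_add(nd_matmul(proj$W, flat), proj$b))
}

#' Encode one channel vector
#'
#' Runs the channel's 1-D multi-scale convolution stack (ReLU after every
#' convolution, max pooling after every stage, parallel branches concatenated
#' along the filter axis) followed by flatten + ReLU projection to length `p`.
#' Pure and deterministic given the parameters.
#'
#' @param x Numeric vector of the length the encoder was built for.
#' @param encoder An [build_encoder()] result (or equivalent params/arch).
#' @param channel 1-based channel index.
#' @return Numeric vector of length `p` (or an `ad_node` when called on the
#'   tape with node-wrapped parameters via the internal forward).
#' @export
encode_channel <- function(x, encoder, channel = 1L) {
  arch <- encoder$arch$channel[[channel]]
  prm <- channel_params(encoder$params, channel, encoder$arch)
  if (length(nd_value(x)) != encoder$arch$input_lens[channel]) {
    stop("input length does not match the length the encoder was built for", call. = FALSE)
  }
  out <- encoder_head(conv_stack_forward(as_mat_or_node(x), prm$stages, arch), prm$proj)
  if (is_node(x)) out else as.vector(nd_value(out))
}

channel_params <- function(params, channel, arch) {
  if (isTRUE(arch$share_channel_weights)) params$channel[[1L]] else params$channel[[channel]]
}

as_mat_or_node <- function(x) if (is_node(x)) x else as_mat(x)

#' Encode the aligned channel matrix
#'
#' Runs the 2-D multi-scale convolution stack over the C x L aligned epoch
#' matrix (average pooling after every stage; the final pool collapses the
#' channel-height axis) followed by flatten + ReLU projection to length `p`.
#'
#' @param X C x L numeric matrix (aligned epoch).
#' @param encoder An [build_encoder()] result.
#' @return Numeric vector of length `p`.
#' @export
encode_global <- function(X, encoder) {
  Xv <- nd_value(X)
  if (nrow(Xv) != encoder$arch$montage_size || ncol(Xv) != max(encoder$arch$input_lens)) {
    stop("aligned matrix shape does not match the encoder", call. = FALSE)
  }
  # row-major H x W grid -> (H*W) x 1 with one input filter
  inp <- if (is_node(X)) nd_reshape_rowmajor(X) else matrix(as.vector(t(Xv)), ncol = 1L)
  out <- encoder_head(conv_stack_forward(inp, encoder$params$global$stages,
                                         encoder$arch$global),
                      encoder$params$global$proj)
  if (is_node(X)) out else as.vector(nd_value(out))
}

nd_reshape_rowmajor <- function(a) {
  av <- nd_value(a)
  new_node(matrix(as.vector(t(av)), ncol = 1L), list(a), function(g) {
    if (is_node(a)) accum_grad(a, matrix(as.vector(g), ncol(av), nrow(av))|> t())
  })
}

#' Encode one epoch into multi-view features
#'
#' Applies [encode_channel()] to every native-rate channel vector and
#' [encode_global()] to the aligned matrix, packaging the C channel-view
#' vectors `d` and the global-view vector `s`.
#'
#' @param epoch An aligned epoch (see [preprocess_record()]).
#' @param encoder An [build_encoder()] result.
#' @return List with `d` (list of C length-`p` vectors), `s` (length-`p`
#'   vector), `t_index`.
#' @export
encode_epoch <- function(epoch, encoder) {
  C <- encoder$arch$montage_size
  if (length(epoch$channels) != C) stop("channel count does not match the encoder", call. = FALSE)
  d <- lapply(seq_len(C), function(c) encode_channel(epoch$channels[[c]], encoder, c))
  s <- encode_global(epoch$matrix, encoder)
  list(d = d, s = s, t_index = epoch$t_index)
}
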