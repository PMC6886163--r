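# Convolution stage specifications and gather-index builders.
#
# Feature maps are stored positions x filters; convolutions are evaluated as
# im2col gathers followed by a matrix multiply against a (K*c_in) x F kernel
# matrix (tap-major column order, matching nd_im2col).

conv_out_len <- function(L, k, stride, pad) {
  n <- (L + 2L * pad - k) %/% stride + 1L
  if (n < 1L) stop("convolution/pooling output length reached 0 (input too short for the stage spec)",
                   call. = FALSE)
  as.integer(n)
}

# 1-D gather index: n_out x k matrix of 1-based input rows; L+1 marks padding.
im2col_idx_1d <- function(L, k, stride, pad) {
  starts <- (seq_len(conv_out_len(L, k, stride, pad)) - 1L) * stride - pad  # 0-based
  idx <- outer(starts, 0L:(k - 1L), `+`)                                    # 0-based input pos
  idx[idx < 0L | idx >= L] <- L
  idx + 1L
}

# 2-D gather index over an H x W grid stored row-major ((h-1)*W + w).
im2col_idx_2d <- function(H, W, kh, kw, sh, sw, ph, pw) {
  H_out <- conv_out_len(H, kh, sh, ph)
  W_out <- conv_out_len(W, kw, sw, pw)
  hs <- (seq_len(H_out) - 1L) * sh - ph
  ws <- (seq_len(W_out) - 1L) * sw - pw
  n_out <- H_out * W_out
  idx <- matrix(0L, n_out, kh * kw)
  pos <- 1L
  for (dh in 0L:(kh - 1L)) {
    for (dw in 0L:(kw - 1L)) {
      hh <- rep(hs + dh, each = W_out)
      ww <- rep(ws + dw, times = H_out)
      valid <- hh >= 0L & hh < H & ww >= 0L & ww < W
      col <- ifelse(valid, hh * W + ww + 1L, H * W + 1L)
      idx[, pos] <- col
      pos <- pos + 1L
    }
  }
  attr(idx, "out_hw") <- c(H_out, W_out)
  idx
}

conv_branch <- function(kernel, filters, stride, padding) {
  list(kernel = as.integer(kernel), filters = as.integer(filters),
       stride = as.integer(stride), padding = as.integer(padding))
}

pool_spec <- function(size, stride, padding, mode = c("max", "avg")) {
  list(size = as.integer(size), stride = as.integer(stride),
       padding = as.integer(padding), mode = match.arg(mode))
}

conv_stage <- function(branches, pool) list(branches = branches, pool = pool)

#' Default multi-view encoder configuration
#'
#' The full-scale configuration of the multi-view convolutional module: three
#' stages of parallel multi-scale kernel branches for both the per-channel
#' 1-D encoders (max pooling) and the global 2-D encoder (average pooling).
#' Stage 1 runs four parallel branches with kernels 8/16/32/64 (8 filters
#' each, stride 2); stages 2-3 run kernel-3 and kernel-5 branches (16 filters
#' each). The stage-1 paddings of the kernel-32 and kernel-64 branches are set
#' to 15 and 31 (i.e. `(K-2)/2`) so that all four branches emit equal temporal
#' lengths and can be concatenated along the filter axis; the final 2-D
#' average pool collapses the channel-height axis to 1. A flatten plus learned
#' ReLU linear projection maps each encoder output to the common feature
#' dimension `p`.
#'
#' @return An `encoder_spec` list with `stages_1d` and `stages_2d`.
#' @export
default_encoder_spec <- function() {
  s1d <- list(
    conv_stage(list(conv_branch(8L, 8L, 2L, 3L),
                    conv_branch(16L, 8L, 2L, 7L),
                    conv_branch(32L, 8L, 2L, 15L),
                    conv_branch(64L, 8L, 2L, 31L)),
               pool_spec(6L, 4L, 1L, "max")),
    conv_stage(list(conv_branch(3L, 16L, 1L, 1L),
                    conv_branch(5L, 16L, 1L, 2L)),
               pool_spec(3L, 2L, 1L, "max")),
    conv_stage(list(conv_branch(3L, 16L, 1L, 1L),
                    conv_branch(5L, 16L, 1L, 2L)),
               pool_spec(3L, 2L, 1L, "max"))
  )
  # 2-D kernels are height x width; NA pool height means "current height"
  # (collapses the channel axis at the final stage).
  s2d <- list(
    conv_stage(list(conv_branch(c(1L, 8L), 8L, c(1L, 2L), c(0L, 3L)),
                    conv_branch(c(1L, 16L), 8L, c(1L, 2L), c(0L, 7L)),
                    conv_branch(c(1L, 32L), 8L, c(1L, 2L), c(0L, 15L)),
                    conv_branch(c(1L, 64L), 8L, c(1L, 2L), c(0L, 31L))),
               pool_spec(c(1L, 6L), c(1L, 4L), c(0L, 1L), "avg")),
    conv_stage(list(conv_branch(c(3L, 3L), 16L, c(1L, 1L), c(1L, 1L)),
                    conv_branch(c(5L, 5L), 16L, c(1L, 1L), c(2L, 2L))),
               pool_spec(c(1L, 3L), c(1L, 2L), c(0L, 1L), "avg")),
    conv_stage(list(conv_branch(c(3L, 3L), 16L, c(1L, 1L), c(1L, 1L)),
                    conv_branch(c(5L, 5L), 16L, c(1L, 1L), c(2L, 2L))),
               pool_spec(c(NA_integer_, 3L), c(NA_integer_, 2L), c(0L, 1L), "avg"))
  )
  structure(list(stages_1d = s1d, stages_2d = s2d), class = "encoder_spec")
}

#' Reduced encoder configuration for small experiments
#'
#' A two-stage, two-branch variant of [default_encoder_spec()] sized for toy
#' cohorts (short channels, few filters); identical in structure — parallel
#' multi-scale kernels, max pooling on the channel view, average pooling on
#' the global view with a final channel-axis collapse.
#'
#' @return An `encoder_spec`.
#' @export
toy_encoder_spec <- function() {
  s1d <- list(
    conv_stage(list(conv_branch(8L, 4L, 4L, 2L),
                    conv_branch(16L, 4L, 4L, 6L)),
               pool_spec(4L, 4L, 0L, "max")),
    conv_stage(list(conv_branch(3L, 8L, 1L, 1L)),
               pool_spec(2L, 2L, 0L, "max"))
  )
  s2d <- list(
    conv_stage(list(conv_branch(c(1L, 8L), 4L, c(1L, 4L), c(0L, 2L)),
                    conv_branch(c(1L, 16L), 4L, c(1L, 4L), c(0L, 6L))),
               pool_spec(c(1L, 4L), c(1L, 4L), c(0L, 0L), "avg")),
    conv_stage(list(conv_branch(c(3L, 3L), 8L, c(1L, 1L), c(1L, 1L))),
               pool_spec(c(NA_integer_, 2L), c(NA_integer_, 2L), c(0L, 0L), "avg"))
  )
  structure(list(stages_1d = s1d, stages_2d = s2d), class = "encoder_spec")
}

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}
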