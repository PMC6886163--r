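#' Segment a record into labelled 30-s epochs
#'
#' Each hypnogram entry yields one epoch; channel `c`'s vector is the
#' contiguous half-open slice `[t * rate_c * 30, (t+1) * rate_c * 30)`
#' (0-based slots internally, reported 1-based as `t_index`). Any unlabelled
#' tail beyond the hypnogram is dropped.
#'
#' @param record A `psg_record`.
#' @return List of epochs; each has `channels` (named list of native-rate
#'   vectors), `label`, `t_index`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 1, epochs_per_subject = 3, seed = 2)
#' ep <- segment_epochs(generate_record(cfg, 1))
#' length(ep)
segment_epochs <- function(record) {
  n_epochs <- length(record$hypnogram)
  if (n_epochs < 1L) stop("record has an empty hypnogram", call. = FALSE)
  per_slot <- record$rates * 30L
  need <- per_slot * n_epochs
  have <- lengths(record$signals)
  if (any(have < need)) {
    stop("signal shorter than the labelled span implies", call. = FALSE)
  }
  lapply(seq_len(n_epochs), function(t) {
    chans <- lapply(seq_along(record$signals), function(c) {
      n <- per_slot[c]
      record$signals[[c]][((t - 1L) * n + 1L):(t * n)]
    })
    names(chans) <- names(record$signals)
    list(channels = chans, label = record$hypnogram[t], t_index = t)
  })
}

#' Linearly interpolate one channel vector to a target length
#'
#' Samples sit at times `k / rate` (0-based `k`) within the 30-s slot; the
#' target grid is `j / target_rate`. Upsampling by an integer factor therefore
#' reproduces the original samples exactly at the matching grid points, and a
#' vector already at `target_len` passes through unchanged. Values beyond the
#' last original sample take its value (constant extension).
#'
#' @param x Numeric vector (one channel, one epoch).
#' @param target_len Target number of samples (>= 2).
#' @return Numeric vector of length `target_len`.
#' @export
interp_channel <- function(x, target_len) {
  n <- length(x)
  if (n == 0L) stop("empty channel vector", call. = FALSE)
  if (target_len < 2L) stop("target_len must be >= 2", call. = FALSE)
  if (n == target_len) return(x)
  if (n == 1L) return(rep(x, target_len))
  t_in <- (seq_len(n) - 1L) / n          # seconds-scaled grid: k / rate, rate = n / 30
  t_out <- (seq_len(target_len) - 1L) / target_len
  stats::approx(t_in, x, xout = t_out, rule = 2L)$y
}

#' Align a segmented epoch onto a common channel matrix
#'
#' All channels are linearly interpolated to `target_len` samples spanning the
#' same 30-s interval and stacked into a C x L matrix (rows in montage order).
#'
#' @param epoch One element of [segment_epochs()].
#' @param target_len Common length L; conventionally the highest channel rate
#'   times 30 so that no channel is downsampled.
#' @return The epoch with an added `matrix` (C x L) and `domain = "time"`.
#' @export
align_epoch <- function(epoch, target_len) {
  mat <- do.call(rbind, lapply(epoch$channels, interp_channel, target_len = target_len))
  rownames(mat) <- names(epoch$channels)
  epoch$matrix <- mat
  epoch$domain <- "time"
  epoch
}

#' Short-time Fourier features for one aligned epoch
#'
#' Per channel (already aligned to the common time-domain length), the
#' magnitude spectrogram over non-overlapping windows: window length
#' `window`, hop equal to the window, a Hann taper, one-sided spectrum
#' (`window/2 + 1` bins), no boundary padding. On a 3,840-sample epoch with
#' the default 128-sample window this yields 65 x 30 values per channel,
#' flattened bin-major (all frames of bin 1, then bin 2, ...) into that
#' channel's feature vector.
#'
#' @param epoch An aligned epoch (see [align_epoch()]).
#' @param window STFT window length in samples.
#' @param hop Hop size; defaults to `window` (non-overlapping).
#' @param log_magnitude Return `log1p` of the magnitudes instead of raw
#'   magnitudes.
#' @return The epoch with `channels` replaced by the per-channel feature
#'   vectors, `matrix` by the C x (bins*frames) feature matrix, and
#'   `domain = "frequency"`.
#' @export
stft_features <- function(epoch, window = 128L, hop = window, log_magnitude = FALSE) {
  if (is.null(epoch$matrix)) stop("epoch must be aligned first", call. = FALSE)
  L <- ncol(epoch$matrix)
  if (L < window) stop("epoch shorter than one STFT window", call. = FALSE)
  n_frames <- (L - window) %/% hop + 1L
  n_bins <- window %/% 2L + 1L
  taper <- hann_window(window)
  feats <- t(apply(epoch$matrix, 1L, function(x) {
    frames <- vapply(seq_len(n_frames), function(f) {
      x[((f - 1L) * hop + 1L):((f - 1L) * hop + window)] * taper
    }, numeric(window))
    spec <- Mod(stats::mvfft(frames))[seq_len(n_bins), , drop = FALSE]  # bins x frames
    if (log_magnitude) spec <- log1p(spec)
    as.vector(t(spec))                   # bin-major flattening
  }))
  rownames(feats) <- rownames(epoch$matrix)
  epoch$channels <- lapply(seq_len(nrow(feats)), function(c) feats[c, ])
  names(epoch$channels) <- rownames(feats)
  epoch$matrix <- feats
  epoch$domain <- "frequency"
  epoch$stft_shape <- c(bins = n_bins, frames = n_frames)
  epoch
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Preprocess a record into an epoch sequence
#'
#' Optionally z-scores each channel over the whole record (amplitudes of
#' mixed biosignal modalities differ by orders of magnitude), segments it into
#' labelled epochs, aligns all channels to the common length (highest rate
#' times 30 by default) and, for the frequency domain, replaces each epoch by
#' its STFT magnitude features.
#'
#' @param record A `psg_record`.
#' @param domain `"time"` or `"frequency"`.
#' @param target_len Common aligned length; default `max(rates) * 30`.
#' @param normalize Per-channel z-score over the record before segmentation.
#' @param stft_window,stft_hop,stft_log Passed to [stft_features()].
#' @return An `epoch_sequence`: list with `subject_id`, `domain`, `epochs`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 1, epochs_per_subject = 2, seed = 5,
#'                      montage = list(channel_spec("A", 32, "eeg"),
#'                                     channel_spec("B", 16, "emg")))
#' es <- preprocess_record(generate_record(cfg, 1))
#' dim(es$epochs[[1]]$matrix)
preprocess_record <- function(record, domain = c("time", "frequency"),
                              target_len = NULL, normalize = TRUE,
                              stft_window = 128L, stft_hop = stft_window,
                              stft_log = FALSE) {
  domain <- match.arg(domain)
  if (is.null(target_len)) target_len <- max(record$rates) * 30L
  if (normalize) {
    record$signals <- lapply(record$signals, function(x) {
      s <- stats::sd(x)
      if (s < 1e-12) x - mean(x) else (x - mean(x)) / s
    })
  }
  eps <- segment_epochs(record)
  eps <- lapply(eps, align_epoch, target_len = target_len)
  if (domain == "frequency") {
    eps <- lapply(eps, stft_features, window = stft_window, hop = stft_hop,
                  log_magnitude = stft_log)
  } else {
    # channel encoders consume the native-rate vectors; keep them as is
  }
  structure(list(subject_id = record$subject_id, domain = domain, epochs = eps),
            class = "epoch_sequence")
}

#' Preprocess a whole cohort
#'
#' @param cohort List of `psg_record`s (see [generate_cohort()]).
#' @param ... Passed to [preprocess_record()].
#' @return List of `epoch_sequence`s.
#' @export
preprocess_cohort <- function(cohort, ...) lapply(cohort, preprocess_record, ...)
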