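make_record <- function(signals, rates, hypnogram) {
  structure(list(subject_id = "T001", signals = signals, rates = rates,
                 kinds = rep("eeg", length(signals)), hypnogram = hypnogram),
            class = "psg_record")
}

test_that("segmentation yields one epoch per hypnogram entry with whole slices", {
  # 300-s record at 128 Hz -> 10 epochs of 128 * 30 = 3840 samples
  rec <- make_record(list(A = seq_len(128L * 300L)), 128L, rep("S2", 10L))
  eps <- segment_epochs(rec)
  expect_length(eps, 10L)
  expect_true(all(vapply(eps, function(e) length(e$channels$A), integer(1L)) == 3840L))
  expect_identical(eps[[3L]]$channels$A, seq.int(2L * 3840L + 1L, 3L * 3840L))
  expect_identical(vapply(eps, `[[`, integer(1L), "t_index"), 1:10)

  # exactly one 30-s slot
  one <- segment_epochs(make_record(list(A = rnorm(64L * 30L)), 64L, "WAKE"))
  expect_length(one, 1L)

  # a 29-s unlabelled tail is ignored
  tail_rec <- make_record(list(A = rnorm(64L * 30L * 2L + 64L * 29L)), 64L,
                          c("WAKE", "S1"))
  expect_length(segment_epochs(tail_rec), 2L)

  # signal shorter than the hypnogram implies is an inconsistency
  short <- make_record(list(A = rnorm(64L * 45L)), 64L, c("WAKE", "S1"))
  expect_error(segment_epochs(short), "shorter")
})

test_that("re-concatenating epoch slices reproduces the labelled span", {
  cfg <- toy_cohort_config(n_subjects = 1L, epochs_per_subject = 5L, seed = 3L)
  rec <- generate_record(cfg, 1L)
  eps <- segment_epochs(rec)
  for (c in seq_along(rec$signals)) {
    rebuilt <- unlist(lapply(eps, function(e) e$channels[[c]]), use.names = FALSE)
    expect_identical(rebuilt, rec$signals[[c]][seq_along(rebuilt)])
  }
})

test_that("linear interpolation reproduces coarse samples and preserves bounds", {
  x <- rnorm(1920L)
  up <- interp_channel(x, 3840L)
  expect_length(up, 3840L)
  # doubling the rate puts original samples at the even 0-based indices
  expect_equal(up[seq(1L, 3839L, by = 2L)], x, tolerance = 1e-12)
  expect_gte(min(up), min(x))
  expect_lte(max(up), max(x))
  # identity when already at target length
  expect_identical(interp_channel(x, 1920L), x)
  expect_error(interp_channel(numeric(0L), 10L), "empty")
})

test_that("alignment is idempotent and yields the printed time-domain size", {
  rec <- full_scale_record()
  ep <- segment_epochs(rec)[[1L]]
  al <- align_epoch(ep, 3840L)
  expect_identical(dim(al$matrix), c(14L, 3840L))
  expect_identical(length(al$matrix), 53760L)
  # aligning the aligned channels again changes nothing
  re <- align_epoch(list(channels = lapply(seq_len(14L), function(c) al$matrix[c, ]),
                         label = al$label, t_index = al$t_index), 3840L)
  expect_equal(unname(re$matrix), unname(al$matrix), tolerance = 0)
})

test_that("STFT features have the printed frequency-domain geometry", {
  rec <- full_scale_record()
  ep <- align_epoch(segment_epochs(rec)[[1L]], 3840L)
  fr <- stft_features(ep, window = 128L)
  expect_identical(unname(fr$stft_shape), c(65L, 30L))
  expect_identical(dim(fr$matrix), c(14L, 65L * 30L))
  expect_identical(length(fr$matrix), 27300L)
  expect_identical(fr$domain, "frequency")
})

test_that("STFT is linear at zero and localises a pure tone, matching a DFT oracle", {
  zero_ep <- list(channels = list(A = rep(0, 3840L)), label = "WAKE", t_index = 1L)
  zep <- align_epoch(zero_ep, 3840L)
  expect_true(all(stft_features(zep, 128L)$matrix == 0))

  # 8 Hz tone sampled at 128 Hz: 8 cycles per 128-sample window -> bin 8 (0-based)
  tt <- (0:3839) / 128
  tone <- sin(2 * pi * 8 * tt)
  ep <- align_epoch(list(channels = list(A = tone), label = "WAKE", t_index = 1L), 3840L)
  fr <- stft_features(ep, 128L)
  S <- matrix(fr$matrix[1L, ], nrow = 65L, byrow = TRUE)     # bins x frames
  expect_true(all(apply(S, 2L, which.max) == 9L))            # 1-based bin 9 = 0-based 8

  # direct DFT oracle on the first Hann-tapered frame
  taper <- sleepatt:::hann_window(128L)
  frame <- tone[1:128] * taper
  k <- 0:127
  dft <- vapply(0:64, function(b) Mod(sum(frame * exp(-2i * pi * b * k / 128))),
                numeric(1L))
  expect_equal(S[, 1L], dft, tolerance = 1e-10)

  expect_error(stft_features(align_epoch(list(channels = list(A = rnorm(64L)),
                                              label = "W", t_index = 1L), 64L),
                             window = 128L), "shorter")
})

test_that("preprocess_record assembles normalized aligned sequences", {
  cfg <- toy_cohort_config(n_subjects = 1L, epochs_per_subject = 3L, seed = 19L)
  rec <- generate_record(cfg, 1L)
  es <- preprocess_record(rec)
  expect_s3_class(es, "epoch_sequence")
  expect_length(es$epochs, 3L)
  expect_identical(dim(es$epochs[[1L]]$matrix), c(2L, 960L))
  expect_identical(vapply(es$epochs, `[[`, integer(1L), "t_index"), 1:3)
  # z-scoring acts per channel over the record
  z <- unlist(lapply(es$epochs, function(e) e$channels[[1L]]))
  expect_lt(abs(mean(z)), 1e-8)
  expect_equal(stats::sd(z), 1, tolerance = 1e-3)

  ef <- preprocess_record(rec, domain = "frequency")
  expect_identical(ef$domain, "frequency")
  expect_identical(unname(ef$epochs[[1L]]$stft_shape), c(65L, 7L))
})
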