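test_that("record geometry follows rate x 30 x epochs arithmetic", {
  cfg <- cohort_config(n_subjects = 1L, epochs_per_subject = 20L, seed = 5L)
  rec <- generate_record(cfg, 1L)
  expect_length(rec$signals, 14L)
  # EEG channels sample at 128 Hz: 128 * 30 * 20 epochs
  expect_identical(length(rec$signals[[1L]]), 128L * 30L * 20L)
  # EMG channel at 64 Hz
  emg <- which(rec$kinds == "emg")
  expect_identical(length(rec$signals[[emg]]), 64L * 30L * 20L)
  expect_length(rec$hypnogram, 20L)
  expect_true(all(rec$hypnogram %in% sleep_stages()))
})

test_that("generation is deterministic and order-independent", {
  cfg <- cohort_config(n_subjects = 3L, epochs_per_subject = 3L, seed = 9L,
                       montage = toy_montage())
  a <- generate_record(cfg, 2L)
  b <- generate_record(cfg, 2L)
  expect_identical(a, b)
  # subject 2 generated inside a cohort equals subject 2 generated alone
  cohort <- generate_cohort(cfg)
  expect_identical(cohort[[2L]], a)
  # different subjects differ
  expect_false(identical(cohort[[1L]]$signals, cohort[[3L]]$signals))
})

test_that("cohorts have unique ids and the expected epoch count", {
  cfg <- cohort_config(n_subjects = 5L, epochs_per_subject = 40L, seed = 2L,
                       montage = toy_montage())
  cohort <- generate_cohort(cfg)
  ids <- vapply(cohort, `[[`, character(1L), "subject_id")
  expect_length(unique(ids), 5L)
  expect_identical(sum(vapply(cohort, function(r) length(r$hypnogram), integer(1L))), 200L)
})

test_that("invalid configurations are rejected", {
  bad <- default_stage_transition()
  bad[1L, 1L] <- bad[1L, 1L] + 0.1
  expect_error(cohort_config(stage_transition = bad), "sum to 1")
  expect_error(cohort_config(n_subjects = 0L), "n_subjects")
  expect_error(cohort_config(montage = list()), "montage")
  expect_error(channel_spec("X", 0L), "positive")
  cfg <- cohort_config(n_subjects = 2L, seed = 1L, montage = toy_montage())
  expect_error(generate_record(cfg, 3L), "out of range")
  cfg0 <- cohort_config(n_subjects = 1L, montage = toy_montage())
  cfg0$epochs_per_subject <- 0L
  expect_error(generate_record(cfg0, 1L), "epochs_per_subject")
})

test_that("signals are finite and non-constant under noise", {
  cfg <- toy_cohort_config(n_subjects = 1L, epochs_per_subject = 5L, seed = 21L)
  rec <- generate_record(cfg, 1L)
  for (x in rec$signals) {
    expect_true(all(is.finite(x)))
    expect_gt(stats::sd(x), 0)
  }
})

test_that("noise-free one-hot band spectra are recovered by a periodogram oracle", {
  # one dominant band per stage; generated slot power in that band should be
  # ~ amp^2/2 with everything else at the background amplitude
  map <- toy_band_power_map()
  cfg <- cohort_config(n_subjects = 1L, epochs_per_subject = 12L, seed = 33L,
                       montage = toy_montage(),
                       stage_transition = matrix(0.2, 5L, 5L),
                       band_power_map = map, amp_sd = 0, noise_sd = 0)
  rec <- generate_record(cfg, 1L)
  hot <- c(WAKE = "alpha", REM = "beta", S1 = "theta", S2 = "theta", S3 = "delta")
  n <- 32L * 30L
  for (t in seq_along(rec$hypnogram)) {
    stage <- rec$hypnogram[t]
    x <- rec$signals[[1L]][((t - 1L) * n + 1L):(t * n)]
    bp <- slot_band_powers(x, 32L)
    # predicted band-power shares: each band holds one sinusoid of power A^2/2
    amps <- exp(map[stage, "eeg", ])
    share_ref <- amps^2 / sum(amps^2)
    share <- bp / sum(bp)
    expect_lt(abs(share[[hot[[stage]]]] - share_ref[[hot[[stage]]]]) /
                share_ref[[hot[[stage]]]], 0.05)
    expect_identical(names(which.max(bp)), hot[[stage]])
  }
})

test_that("hypnogram stage frequencies converge to the stationary distribution", {
  P <- default_stage_transition()
  pi0 <- stationary_distribution(P)
  withr::with_seed(77L, {
    hyp <- sleepatt:::simulate_hypnogram(P, 10000L)
  })
  freq <- table(factor(hyp, levels = sleep_stages())) / length(hyp)
  tv <- 0.5 * sum(abs(as.numeric(freq) - pi0))
  expect_lt(tv, 0.05)
})

test_that("well-separated cohorts are separable by a band-power oracle", {
  cfg <- toy_cohort_config(n_subjects = 2L, epochs_per_subject = 30L, seed = 55L)
  cohort <- generate_cohort(cfg)
  feats <- dplyr::bind_rows(lapply(cohort, band_power_features))
  # aggregate per epoch over channels, then nearest-centroid in log-power space
  ep <- dplyr::summarise(
    dplyr::group_by(feats, .data$subject, .data$t, .data$stage),
    dplyr::across(c("delta", "theta", "alpha", "beta"), ~ log1p(sum(.x))),
    .groups = "drop")
  X <- as.matrix(ep[, c("delta", "theta", "alpha", "beta")])
  train <- ep$subject == "S001"
  cent <- stats::aggregate(X[train, ], list(stage = ep$stage[train]), mean)
  d2 <- apply(X[!train, ], 1L, function(v) {
    which.min(colSums((t(as.matrix(cent[, -1L])) - v)^2))
  })
  acc <- mean(cent$stage[d2] == ep$stage[!train])
  expect_gt(acc, 0.9)
})

test_that("the JSON record container round-trips", {
  cfg <- toy_cohort_config(n_subjects = 1L, epochs_per_subject = 2L, seed = 8L)
  rec <- generate_record(cfg, 1L)
  path <- withr::local_tempfile(fileext = ".json")
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$signals, rec$signals, tolerance = 1e-12)
  expect_identical(back$hypnogram, rec$hypnogram)
  expect_identical(back$rates, rec$rates)
  expect_identical(back$subject_id, rec$subject_id)
})
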