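#' Sleep stage labels
#'
#' The five stage labels used throughout the package, in their fixed class
#' order: wakefulness, REM sleep, and the NREM stages S1, S2 and S3 (the
#' original S3 and S4 deep-sleep stages merged into a single S3 class, the
#' usual convention for R&K-scored corpora).
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' sleep_stages()
sleep_stages <- function() c("WAKE", "REM", "S1", "S2", "S3")

# Frequency bands (Hz) used by the generator and the band-power oracle.
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Describe one recording channel
#'
#' @param name Unique channel label.
#' @param rate Sampling rate in Hz (positive integer).
#' @param kind Channel modality, one of `"eeg"`, `"eog"`, `"emg"`, `"ecg"`,
#'   `"other"`.
#' @return A `channel_spec` list.
#' @export
#' @examples
#' channel_spec("C3A2", 128, "eeg")
channel_spec <- function(name, rate, kind = "other") {
  kind <- match.arg(kind, c("eeg", "eog", "emg", "ecg", "other"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  rate <- as.integer(rate)
  if (is.na(rate) || rate <= 0L) stop("channel rate must be a positive integer", call. = FALSE)
  structure(list(name = name, rate = rate, kind = kind), class = "channel_spec")
}

#' Default 14-channel montage
#'
#' A stand-in montage mirroring the heterogeneity of a typical 14-channel
#' overnight PSG recording (128 Hz EEG, 64 Hz EMG, plus EOG/ECG and other
#' lower-rate biosignals). The public corpora this emulates do not publish a
#' channel-by-channel montage, so this is a synthetic default, not a claim
#' about any real recorder.
#'
#' @return List of 14 [channel_spec()] objects: 6 EEG @128 Hz, 2 EOG @128 Hz,
#'   1 EMG @64 Hz, 1 ECG @128 Hz, 4 other @64 Hz.
#' @export
default_montage <- function() {
  c(
    lapply(1:6, function(i) channel_spec(paste0("EEG", i), 128L, "eeg")),
    lapply(1:2, function(i) channel_spec(paste0("EOG", i), 128L, "eog")),
    list(channel_spec("EMG1", 64L, "emg")),
    list(channel_spec("ECG1", 128L, "ecg")),
    lapply(1:4, function(i) channel_spec(paste0("AUX", i), 64L, "other"))
  )
}

#' Default stage-transition matrix
#'
#' Row-stochastic 5x5 matrix of per-30-s transition probabilities, loosely
#' following hypnogram dynamics: sticky stages, wake -> S1 entry, S1 -> S2
#' progression, S2 <-> S3 cycling and REM entered mostly from S2.
#'
#' @return 5x5 matrix with `sleep_stages()` dimnames; rows sum to 1.
#' @export
default_stage_transition <- function() {
  s <- sleep_stages()
  P <- matrix(c(
    # WAKE   REM    S1     S2     S3
    0.80,  0.02,  0.15,  0.02,  0.01,   # from WAKE
    0.05,  0.80,  0.05,  0.09,  0.01,   # from REM
    0.10,  0.05,  0.60,  0.23,  0.02,   # from S1
    0.02,  0.08,  0.05,  0.70,  0.15,   # from S2
    0.01,  0.02,  0.02,  0.20,  0.75    # from S3
  ), nrow = 5L, byrow = TRUE, dimnames = list(s, s))
  P
}

#' Default stage- and modality-conditioned band power map
#'
#' Mean log-amplitudes of the four sinusoidal band components (delta, theta,
#' alpha, beta) for each (stage, channel kind) pair. Values follow textbook
#' sleep physiology at a coarse level: alpha/beta-dominant wakefulness,
#' theta-dominant S1, delta-dominant deep sleep, mixed REM, and REM muscle
#' atonia on EMG. They are simulator defaults, not physiological claims.
#'
#' @return 3-d array `[stage, kind, band]` of mean log-amplitudes.
#' @export
default_band_power_map <- function() {
  stages <- sleep_stages()
  kinds <- c("eeg", "eog", "emg", "ecg", "other")
  bands <- names(eeg_bands())
  A <- array(-1, dim = c(5L, 5L, 4L), dimnames = list(stages, kinds, bands))
  # EEG / EOG spectra dominate the stage signature.
  for (k in c("eeg", "eog")) {
    A["WAKE", k, ] <- c(-1.0, -0.5, 1.2, 0.8)
    A["REM",  k, ] <- c(-0.5, 0.6, -0.2, 0.5)
    A["S1",   k, ] <- c(-0.2, 1.0, -0.5, -1.0)
    A["S2",   k, ] <- c(0.8, 0.5, -1.0, -1.0)
    A["S3",   k, ] <- c(1.8, -0.2, -1.5, -1.5)
  }
  # EMG tone: high awake, atonic in REM, graded in NREM.
  A["WAKE", "emg", ] <- c(-1.5, -1.0, 0.0, 1.2)
  A["REM",  "emg", ] <- c(-2.5, -2.0, -2.0, -1.5)
  A["S1",   "emg", ] <- c(-1.5, -1.0, -0.5, 0.4)
  A["S2",   "emg", ] <- c(-1.5, -1.2, -0.8, 0.0)
  A["S3",   "emg", ] <- c(-1.5, -1.4, -1.0, -0.4)
  # ECG and auxiliary channels: weak stage dependence.
  for (k in c("ecg", "other")) {
    A["WAKE", k, ] <- c(0.2, 0.0, 0.1, 0.2)
    A["REM",  k, ] <- c(0.1, 0.1, 0.0, 0.1)
    A["S1",   k, ] <- c(0.1, 0.0, 0.0, 0.0)
    A["S2",   k, ] <- c(0.0, 0.0, -0.1, -0.1)
    A["S3",   k, ] <- c(-0.1, -0.1, -0.2, -0.2)
  }
  A
}

#' Configure a synthetic PSG cohort
#'
#' Bundles every knob of the synthetic generator: cohort size, montage,
#' epochs per subject, the Markov stage-transition matrix, the
#' stage-conditioned band power map, the additive noise scale and the master
#' seed. Defaults emulate a 14-channel heterogeneous overnight montage with
#' five-stage hypnograms.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param montage List of [channel_spec()]s; names must be unique.
#' @param epochs_per_subject Number of labelled 30-s epochs per record (>= 1).
#' @param stage_transition 5x5 row-stochastic matrix over `sleep_stages()`.
#' @param band_power_map `[stage, kind, band]` array of mean log-amplitudes.
#' @param amp_sd Log-amplitude jitter of each band component around its map
#'   entry.
#' @param noise_sd Scale of the additive Gaussian noise.
#' @param seed Master integer seed; per-subject streams are derived from it.
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 2, epochs_per_subject = 4, seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort)
cohort_config <- function(n_subjects = 25L,
                          montage = default_montage(),
                          epochs_per_subject = 60L,
                          stage_transition = default_stage_transition(),
                          band_power_map = default_band_power_map(),
                          amp_sd = 0.1,
                          noise_sd = 0.2,
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  epochs_per_subject <- as.integer(epochs_per_subject)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(montage) < 1L) stop("montage must be non-empty", call. = FALSE)
  nm <- vapply(montage, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("channel names must be unique", call. = FALSE)
  if (!is.matrix(stage_transition) || any(dim(stage_transition) != 5L)) {
    stop("stage_transition must be a 5x5 matrix", call. = FALSE)
  }
  if (any(stage_transition < 0) || any(abs(rowSums(stage_transition) - 1) > 1e-9)) {
    stop("stage_transition rows must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(
    n_subjects = n_subjects, montage = montage,
    epochs_per_subject = epochs_per_subject,
    stage_transition = stage_transition,
    band_power_map = band_power_map,
    amp_sd = amp_sd, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Stable per-subject seed derived from (master seed, subject index); keeps
# cohorts order-independent and every derived seed inside 32-bit range.
subject_seed <- function(seed, subject_index) {
  as.integer((abs(as.numeric(seed)) %% 65021 * 31607 + subject_index * 7919 + 13) %%
               2147483647)
}

simulate_hypnogram <- function(P, n) {
  stages <- sleep_stages()
  # start from the stationary distribution so short records are balanced
  pi0 <- stationary_distribution(P)
  out <- character(n)
  cur <- sample.int(5L, 1L, prob = pi0)
  out[1L] <- stages[cur]
  if (n > 1L) for (t in 2L:n) {
    cur <- sample.int(5L, 1L, prob = P[cur, ])
    out[t] <- stages[cur]
  }
  out
}

#' Stationary distribution of a stage-transition matrix
#'
#' @param P Row-stochastic square matrix.
#' @return Probability vector (left eigenvector of `P` for eigenvalue 1).
#' @export
stationary_distribution <- function(P) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

# One 30-s slot of one channel: per band, a band-limited sinusoid with
# log-amplitude drawn around the (stage, kind) map entry, plus white noise.
simulate_slot <- function(stage, spec, cfg) {
  n <- spec$rate * 30L
  tt <- seq(0, 30, length.out = n + 1L)[-(n + 1L)]
  bands <- eeg_bands()
  x <- numeric(n)
  nyq <- spec$rate / 2
  for (b in seq_along(bands)) {
    lo <- bands[[b]][1L]; hi <- min(bands[[b]][2L], nyq * 0.95)
    if (hi <= lo) next
    f <- stats::runif(1L, lo, hi)
    phase <- stats::runif(1L, 0, 2 * pi)
    amp <- exp(stats::rnorm(1L, cfg$band_power_map[stage, spec$kind, b], cfg$amp_sd))
    x <- x + amp * sin(2 * pi * f * tt + phase)
  }
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  x
}

#' Generate one synthetic PSG record
#'
#' The hypnogram is a realisation of the configured Markov chain; each
#' channel's 30-s slot is a sum of four band-limited sinusoids whose
#' log-amplitudes are drawn around the (stage, channel-kind) entries of the
#' band power map, plus Gaussian noise. Deterministic for a fixed
#' `(seed, subject_index)` pair regardless of generation order.
#'
#' @param config A [cohort_config()].
#' @param subject_index 1-based subject index, `<= config$n_subjects`.
#' @return A `psg_record`: list with `subject_id`, `signals` (named list of
#'   numeric vectors), `rates`, `kinds` and `hypnogram`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 1, epochs_per_subject = 2, seed = 3)
#' rec <- generate_record(cfg, 1)
#' lengths(rec$signals)[1:2]
generate_record <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1L || subject_index > config$n_subjects) {
    stop("subject_index out of range", call. = FALSE)
  }
  if (config$epochs_per_subject < 1L) stop("epochs_per_subject must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed(config$seed, subject_index))
  hyp <- simulate_hypnogram(config$stage_transition, config$epochs_per_subject)
  signals <- lapply(config$montage, function(spec) {
    unlist(lapply(hyp, function(st) simulate_slot(st, spec, config)), use.names = FALSE)
  })
  names(signals) <- vapply(config$montage, `[[`, character(1L), "name")
  structure(list(
    subject_id = sprintf("S%03d", subject_index),
    signals = signals,
    rates = vapply(config$montage, `[[`, integer(1L), "rate"),
    kinds = vapply(config$montage, `[[`, character(1L), "kind"),
    hypnogram = hyp
  ), class = "psg_record")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return List of `config$n_subjects` [generate_record()] results with
#'   distinct subject ids.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(seq_len(config$n_subjects), function(i) generate_record(config, i))
}

#' Band powers of one 30-s slot
#'
#' Periodogram-based power in the delta/theta/alpha/beta bands; used by the
#' oracle classifier that certifies synthetic cohorts are separable.
#'
#' @param x Numeric vector (one slot of one channel).
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of band powers.
#' @export
slot_band_powers <- function(x, rate) {
  n <- length(x)
  # one-sided mean-square power: a sinusoid of amplitude A contributes A^2/2
  sp <- 2 * Mod(stats::fft(x))^2 / n^2
  freq <- (seq_len(n) - 1L) * rate / n
  half <- freq <= rate / 2
  vapply(eeg_bands(), function(b) {
    sum(sp[half & freq >= b[1L] & freq < b[2L]])
  }, numeric(1L))
}

#' Band-power feature table for a record
#'
#' One row per (epoch, channel) with the four band powers; the tidy input for
#' the oracle separability check and for exploratory plots.
#'
#' @param record A `psg_record`.
#' @return Tibble with columns `subject`, `t`, `channel`, `stage`,
#'   `delta`, `theta`, `alpha`, `beta`.
#' @export
band_power_features <- function(record) {
  n_epochs <- length(record$hypnogram)
  rows <- purrr::map_dfr(seq_len(n_epochs), function(t) {
    purrr::map_dfr(seq_along(record$signals), function(c) {
      n <- record$rates[c] * 30L
      x <- record$signals[[c]][((t - 1L) * n + 1L):(t * n)]
      bp <- slot_band_powers(x, record$rates[c])
      tibble::tibble(
        subject = record$subject_id, t = t,
        channel = names(record$signals)[c],
        stage = record$hypnogram[t],
        delta = bp[["delta"]], theta = bp[["theta"]],
        alpha = bp[["alpha"]], beta = bp[["beta"]]
      )
    })
  })
  rows
}

#' Write / read the plain-text record container
#'
#' One JSON file per record holding the per-channel sample vectors, their
#' rates and kinds, and the hypnogram. Round-trips exactly at full double
#' precision.
#'
#' @param record A `psg_record`.
#' @param path File path (`.json`).
#' @return `write_record()` returns `path` invisibly; `read_record()` returns
#'   the `psg_record`.
#' @export
write_record <- function(record, path) {
  obj <- list(
    subject_id = record$subject_id,
    rates = as.integer(record$rates),
    kinds = record$kinds,
    hypnogram = record$hypnogram,
    signals = record$signals
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    subject_id = obj$subject_id,
    signals = as.list(obj$signals),
    rates = as.integer(obj$rates),
    kinds = obj$kinds,
    hypnogram = obj$hypnogram
  ), class = "psg_record")
}
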