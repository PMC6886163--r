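default_run_config_list <- function() {
  list(
    seed = 1L,
    domain = "time",
    cohort = list(
      n_subjects = 25L,
      epochs_per_subject = 60L,
      montage = "default",           # "default" (14-channel) or "toy"
      amp_sd = 0.1,
      noise_sd = 0.2
    ),
    preprocessing = list(
      align = list(target_len = NULL),   # NULL: highest rate x 30
      stft = list(window = 128L, hop = NULL, log_magnitude = FALSE),
      normalize = list(per_channel = TRUE)
    ),
    model = list(
      p = 128L, q = 128L, r = 128L, n_classes = 5L,
      encoder = "default",           # "default" (full-scale) or "toy"
      activation = "tanh",
      share_channel_weights = FALSE
    ),
    training = list(
      epochs = 50L, batch = 8L, rho = 0.95, adadelta_eps = 1e-6,
      l2_coeff = 0.001, momentum = 0.95, dropout = 0.5,
      window = 25L, patience = 10L, loss_form = "two_term"
    ),
    cv = list(k = 5L, ratios = c(0.7, 0.1, 0.2))
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste(path, nm, sep = ".") else nm
    if (!nm %in% names(defaults)) stop(sprintf("unknown config key: %s", key), call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) stop(sprintf("config key %s must be a mapping", key), call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      defaults[nm] <- list(user[[nm]])   # [[<- would drop keys set to NULL
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills every unset key with its default (an empty file
#' yields the full-scale defaults: 14 channels, `p = q = r = 128`, five
#' stages, 5-fold 0.7:0.1:0.2 cross-validation) and validates dimensional
#' consistency. Unknown keys and invalid dimensions raise errors naming the
#' offending key.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
#' @examples
#' cfg <- load_config(NULL)
#' cfg$model$p
load_config <- function(path = NULL) {
  cfg <- default_run_config_list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user) > 0L) cfg <- merge_config(cfg, user)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  pos_int <- function(x, key) {
    if (is.null(x) || length(x) != 1L || is.na(x) || x < 1L) {
      stop(sprintf("config key %s must be a positive integer", key), call. = FALSE)
    }
    as.integer(x)
  }
  cfg$model$p <- pos_int(cfg$model$p, "model.p")
  cfg$model$q <- pos_int(cfg$model$q, "model.q")
  cfg$model$r <- pos_int(cfg$model$r, "model.r")
  cfg$model$n_classes <- pos_int(cfg$model$n_classes, "model.n_classes")
  cfg$cohort$n_subjects <- pos_int(cfg$cohort$n_subjects, "cohort.n_subjects")
  cfg$cohort$epochs_per_subject <- pos_int(cfg$cohort$epochs_per_subject,
                                           "cohort.epochs_per_subject")
  cfg$training$window <- pos_int(cfg$training$window, "training.window")
  cfg$training$epochs <- pos_int(cfg$training$epochs, "training.epochs")
  cfg$cv$k <- pos_int(cfg$cv$k, "cv.k")
  if (!cfg$domain %in% c("time", "frequency")) {
    stop("config key domain must be 'time' or 'frequency'", call. = FALSE)
  }
  if (!cfg$cohort$montage %in% c("default", "toy")) {
    stop("config key cohort.montage must be 'default' or 'toy'", call. = FALSE)
  }
  if (!cfg$model$encoder %in% c("default", "toy")) {
    stop("config key model.encoder must be 'default' or 'toy'", call. = FALSE)
  }
  if (cfg$cv$k > cfg$cohort$n_subjects) {
    stop("config key cv.k exceeds cohort.n_subjects", call. = FALSE)
  }
  if (cfg$model$n_classes != 5L) {
    stop("config key model.n_classes must be 5 (the five sleep stages)", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Save a resolved configuration
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_montage <- function(cfg) {
  if (cfg$cohort$montage == "toy") toy_montage() else default_montage()
}

config_encoder_spec <- function(cfg) {
  if (cfg$model$encoder == "toy") toy_encoder_spec() else default_encoder_spec()
}

#' Reduced two-channel montage for toy experiments
#'
#' One 32 Hz EEG-like and one 32 Hz EMG-like channel; small enough that the
#' full stack trains in seconds while keeping the heterogeneous-modality
#' structure.
#'
#' @return List of two [channel_spec()]s.
#' @export
toy_montage <- function() {
  list(channel_spec("EEG1", 32L, "eeg"), channel_spec("EMG1", 32L, "emg"))
}

#' Strongly separated band-power map for toy cohorts
#'
#' Each stage is dominated by a single band with a stage-specific amplitude
#' level (well above the background of the remaining bands), so a band-power
#' oracle — and hence a working encoder — separates the classes almost
#' perfectly. Used by the learning-capability tests; not a physiological
#' default.
#'
#' @return `[stage, kind, band]` array of mean log-amplitudes.
#' @export
toy_band_power_map <- function() {
  stages <- sleep_stages()
  kinds <- c("eeg", "eog", "emg", "ecg", "other")
  A <- array(-2, dim = c(5L, 5L, 4L), dimnames = list(stages, kinds, names(eeg_bands())))
  hot <- c(WAKE = "alpha", REM = "beta", S1 = "theta", S2 = "theta", S3 = "delta")
  level <- c(WAKE = 1.0, REM = 1.6, S1 = 2.2, S2 = 2.8, S3 = 3.4)
  for (st in stages) A[st, , hot[[st]]] <- level[[st]]
  A
}

#' Toy cohort configuration
#'
#' A seeded, well-separated synthetic cohort on the [toy_montage()]: uniform
#' stage mixing, the [toy_band_power_map()] spectra, small amplitude jitter
#' and light noise. This is the standard fixture for the package's learning
#' and cross-validation checks.
#'
#' @param n_subjects,epochs_per_subject,seed See [cohort_config()].
#' @return A `cohort_config`.
#' @export
toy_cohort_config <- function(n_subjects = 2L, epochs_per_subject = 40L, seed = 42L) {
  uniform <- matrix(0.2, 5L, 5L, dimnames = list(sleep_stages(), sleep_stages()))
  cohort_config(
    n_subjects = n_subjects,
    montage = toy_montage(),
    epochs_per_subject = epochs_per_subject,
    stage_transition = uniform,
    band_power_map = toy_band_power_map(),
    amp_sd = 0.1,
    noise_sd = 0.1,
    seed = seed
  )
}
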