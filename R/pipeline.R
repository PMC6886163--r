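#' Run the full pipeline from a configuration
#'
#' Simulate (or load) a cohort, preprocess it in the configured feature
#' domain, build the model and run subject-independent cross-validation,
#' writing every artifact to `out_dir`: the resolved configuration
#' (`config.yaml`), per-fold and summary metrics (`metrics.csv`,
#' `metrics.json`), the loss histories (`history.csv`) and the attention
#' diagnostics of the first test subject (`attention.csv`). Reruns with the
#' same configuration and seed are byte-identical.
#'
#' @param cfg A `run_config` from [load_config()], or `NULL` for defaults.
#' @param out_dir Output directory (created if missing).
#' @param cohort Optional pre-generated cohort (list of `psg_record`s);
#'   otherwise simulated from `cfg`.
#' @param verbose Print progress.
#' @return The `sleepatt_cv` result, invisibly.
#' @export
run_pipeline <- function(cfg = NULL, out_dir = tempfile("sleepatt_run_"),
                         cohort = NULL, verbose = FALSE) {
  if (is.null(cfg)) cfg <- load_config(NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(cohort)) {
    say("simulating %d subjects", cfg$cohort$n_subjects)
    ccfg <- cohort_config(
      n_subjects = cfg$cohort$n_subjects,
      montage = config_montage(cfg),
      epochs_per_subject = cfg$cohort$epochs_per_subject,
      band_power_map = if (cfg$cohort$montage == "toy") toy_band_power_map()
                       else default_band_power_map(),
      stage_transition = if (cfg$cohort$montage == "toy") {
        matrix(0.2, 5L, 5L, dimnames = list(sleep_stages(), sleep_stages()))
      } else default_stage_transition(),
      amp_sd = cfg$cohort$amp_sd, noise_sd = cfg$cohort$noise_sd,
      seed = cfg$seed
    )
    cohort <- generate_cohort(ccfg)
  }

  say("preprocessing (%s domain)", cfg$domain)
  stft_hop <- cfg$preprocessing$stft$hop
  if (is.null(stft_hop)) stft_hop <- cfg$preprocessing$stft$window
  sequences <- preprocess_cohort(
    cohort, domain = cfg$domain,
    target_len = cfg$preprocessing$align$target_len,
    normalize = isTRUE(cfg$preprocessing$normalize$per_channel),
    stft_window = cfg$preprocessing$stft$window,
    stft_hop = stft_hop,
    stft_log = isTRUE(cfg$preprocessing$stft$log_magnitude)
  )
  input_lens <- lengths(sequences[[1L]]$epochs[[1L]]$channels)
  say("per-channel feature lengths: %s", paste(input_lens, collapse = ", "))

  C <- length(input_lens)
  spec <- config_encoder_spec(cfg)
  builder <- function() {
    build_model(input_lens, montage_size = C, p = cfg$model$p, q = cfg$model$q,
                r = cfg$model$r, n_classes = cfg$model$n_classes, spec = spec,
                activation = cfg$model$activation,
                share_channel_weights = isTRUE(cfg$model$share_channel_weights))
  }
  tcfg <- train_config(
    epochs = cfg$training$epochs, batch = cfg$training$batch,
    rho = cfg$training$rho, adadelta_eps = cfg$training$adadelta_eps,
    l2_coeff = cfg$training$l2_coeff, momentum = cfg$training$momentum,
    dropout = cfg$training$dropout, window = cfg$training$window,
    patience = cfg$training$patience, loss_form = cfg$training$loss_form,
    seed = cfg$seed
  )

  say("cross-validating (k = %d)", cfg$cv$k)
  cv <- cross_validate(builder, sequences, k = cfg$cv$k, cfg = tcfg,
                       seed = cfg$seed, verbose = verbose)

  save_config(cfg, file.path(out_dir, "config.yaml"))
  utils::write.csv(cv$folds, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = cv$summary, folds = cv$folds, seed = cfg$seed),
    file.path(out_dir, "metrics.json"), digits = NA, dataframe = "columns"
  )
  hist_tbl <- dplyr::bind_rows(lapply(seq_along(cv$fits), function(f) {
    dplyr::mutate(cv$fits[[f]]$history, fold = f, .before = 1L)
  }))
  utils::write.csv(hist_tbl, file.path(out_dir, "history.csv"), row.names = FALSE)
  first_test <- cv$fold_defs[[1L]]$test_subjects[1L]
  test_seq <- Filter(function(s) s$subject_id == first_test, sequences)[[1L]]
  aw <- attention_weights(cv$fits[[1L]]$model, test_seq, window = tcfg$window)
  utils::write.csv(aw, file.path(out_dir, "attention.csv"), row.names = FALSE)
  say("artifacts written to %s", out_dir)
  invisible(cv)
}
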