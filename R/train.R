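#' Training configuration
#'
#' Defaults follow the published protocol: Adadelta with decay rho = 0.95
#' (the quoted "0.95 momentum" is read as the Adadelta decay constant, since
#' Adadelta has no separate classical momentum term), an L2 penalty of 0.001
#' on all weights added to the cost, and dropout 0.5 on the fused vectors and
#' on the attentional representation. Epoch count, batch size and early
#' stopping are unstated upstream and default to 50 epochs, 8 sequences per
#' step and a 10-epoch validation-accuracy plateau.
#'
#' @param epochs Maximum training epochs.
#' @param batch Sequences (attention windows) per optimisation step.
#' @param rho Adadelta decay constant.
#' @param adadelta_eps Adadelta numerical constant.
#' @param l2_coeff L2 penalty coefficient (gradient contribution
#'   `l2_coeff * w`).
#' @param momentum The quoted optimiser momentum; recorded for provenance and
#'   interpreted as the Adadelta decay constant `rho` (kept equal to it).
#' @param dropout Dropout rate in `[0, 1)`.
#' @param window Epochs per attention window (bounds the quadratic time
#'   attention).
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param loss_form `"two_term"` or `"categorical"`, see [batch_loss()].
#' @param seed Integer seed controlling shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch = 8L, rho = 0.95, adadelta_eps = 1e-6,
                         l2_coeff = 0.001, momentum = 0.95, dropout = 0.5,
                         window = 25L, patience = 10L, loss_form = "two_term",
                         seed = 1L) {
  stopifnot(l2_coeff >= 0, dropout >= 0, dropout < 1)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 rho = rho, adadelta_eps = adadelta_eps, l2_coeff = l2_coeff,
                 momentum = momentum, dropout = dropout,
                 window = as.integer(window), patience = patience,
                 loss_form = loss_form, seed = as.integer(seed)),
            class = "train_config")
}

adadelta_state <- function(flat) {
  list(Eg = lapply(flat, function(w) w * 0), Ed = lapply(flat, function(w) w * 0))
}

adadelta_step <- function(flat, grads, state, rho, eps) {
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * g^2
    delta <- -sqrt(state$Ed[[nm]] + eps) / sqrt(state$Eg[[nm]] + eps) * g
    state$Ed[[nm]] <- rho * state$Ed[[nm]] + (1 - rho) * delta^2
    flat[[nm]] <- flat[[nm]] + delta
  }
  list(flat = flat, state = state)
}

# Collect per-subject training windows: list of (epochs, labels) with one
# entry per attention window.
collect_windows <- function(sequences, subjects, window) {
  out <- list()
  for (seqn in sequences) {
    if (!seqn$subject_id %in% subjects) next
    for (w in make_windows(seqn$epochs, window)) {
      out[[length(out) + 1L]] <- list(
        epochs = w,
        labels = match(vapply(w, `[[`, character(1L), "label"), sleep_stages())
      )
    }
  }
  out
}

#' Train the model on one fold
#'
#' Full-batch-free minibatch training: each step forwards a batch of
#' attention windows through the whole stack on the tape, backpropagates the
#' two-term cross-entropy (windows contribute equally, mirroring the
#' per-record-then-cohort averaging of the cost), adds the L2 gradient and
#' applies an Adadelta update to every learnable tensor. Dropout is active
#' only here; evaluation passes are deterministic. The checkpoint with the
#' best validation accuracy is restored at the end (when a validation set is
#' present), and training stops early after `patience` epochs without
#' improvement. Fully reproducible given `cfg$seed`.
#'
#' @param model A [build_model()] result.
#' @param sequences List of preprocessed `epoch_sequence`s covering the
#'   fold's subjects.
#' @param split A fold from [subject_folds()] (or a list with
#'   `train_subjects` and optionally `val_subjects`).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A `sleepatt_fit`: list with the trained `model`, `history`
#'   (tibble: epoch, train_loss, val_accuracy), `best_epoch`, `cfg`.
#' @export
train <- function(model, sequences, split, cfg = train_config(), verbose = FALSE) {
  train_wins <- collect_windows(sequences, split$train_subjects, cfg$window)
  if (length(train_wins) == 0L) stop("empty training set", call. = FALSE)
  val_seqs <- if (!is.null(split$val_subjects) && length(split$val_subjects) > 0L) {
    Filter(function(s) s$subject_id %in% split$val_subjects, sequences)
  } else NULL

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  flat <- flatten_params(model)
  state <- adadelta_state(flat)
  n_classes <- model$dims$n_classes
  history <- vector("list", cfg$epochs)
  best_acc <- -Inf
  best_flat <- flat
  best_epoch <- 0L
  stall <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(train_wins))
    epoch_loss <- 0
    n_seen <- 0L
    for (b_start in seq(1L, length(ord), by = cfg$batch)) {
      batch_idx <- ord[b_start:min(b_start + cfg$batch - 1L, length(ord))]
      tape_start()
      wrapped <- wrap_model_params(set_params(model, flat))
      losses <- vector("list", length(batch_idx))
      for (j in seq_along(batch_idx)) {
        w <- train_wins[[batch_idx[j]]]
        fw <- model_forward(wrapped$model, w$epochs, train = TRUE, dropout = cfg$dropout)
        losses[[j]] <- window_loss_node(fw$probs, w$labels, n_classes, cfg$loss_form)
      }
      total <- losses[[1L]]
      if (length(losses) > 1L) for (j in 2L:length(losses)) total <- nd_add(total, losses[[j]])
      loss_node <- nd_scale(total, 1 / length(losses))
      loss_val <- as.numeric(loss_node$value)
      if (!is.finite(loss_val)) {
        tape_stop()
        stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
      }
      nd_backward(loss_node)
      grads <- lapply(wrapped$leaves, function(l) {
        g <- if (is.null(l$grad)) l$value * 0 else l$grad
        g
      })
      tape_stop()
      if (cfg$l2_coeff > 0) {
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + cfg$l2_coeff * flat[[nm]]
      }
      upd <- adadelta_step(flat, grads, state, cfg$rho, cfg$adadelta_eps)
      flat <- upd$flat
      state <- upd$state
      epoch_loss <- epoch_loss + loss_val * length(batch_idx)
      n_seen <- n_seen + length(batch_idx)
    }
    epoch_loss <- epoch_loss / n_seen

    val_acc <- NA_real_
    if (!is.null(val_seqs)) {
      mcur <- set_params(model, flat)
      pv <- predict_sequences(mcur, val_seqs, window = cfg$window)
      val_acc <- mean(pv$stage == pv$pred)
      if (val_acc > best_acc + 1e-12) {
        best_acc <- val_acc
        best_flat <- flat
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    } else {
      best_flat <- flat
      best_epoch <- epoch
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = epoch_loss,
                                       val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_acc %s", epoch, epoch_loss,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
    if (!is.null(val_seqs) && is.finite(cfg$patience) && stall >= cfg$patience) break
  }

  structure(list(model = set_params(model, best_flat),
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, cfg = cfg),
            class = "sleepatt_fit")
}

#' Evaluate a trained model on labelled sequences
#'
#' @param fit A `sleepatt_fit` (or a bare `sleepatt_model`).
#' @param sequences List of `epoch_sequence`s.
#' @param window Attention window; defaults to the training window.
#' @return One-row tibble of [stage_metrics()] plus `n_epochs`.
#' @export
evaluate <- function(fit, sequences, window = NULL) {
  model <- if (inherits(fit, "sleepatt_fit")) fit$model else fit
  if (is.null(window)) window <- if (inherits(fit, "sleepatt_fit")) fit$cfg$window else 25L
  preds <- predict_sequences(model, sequences, window = window)
  P <- as.matrix(preds[, c("p_wake", "p_rem", "p_s1", "p_s2", "p_s3")])
  dplyr::mutate(stage_metrics(preds$stage, preds$pred, probs = P),
                n_epochs = nrow(preds))
}

#' Subject-independent cross-validation
#'
#' Runs [train()] and [evaluate()] on each of `k` subject-level folds and
#' returns per-fold metrics plus the mean and standard deviation across
#' folds, the usual way cross-subject sleep-staging results are reported.
#'
#' @param model_builder Zero-argument function returning a fresh
#'   `sleepatt_model` (called once per fold so folds start from independent
#'   initialisations of the same architecture).
#' @param sequences List of preprocessed `epoch_sequence`s for the cohort.
#' @param k Number of folds.
#' @param cfg A [train_config()].
#' @param seed Seed for the fold assignment and per-fold model builds.
#' @param verbose Print per-epoch progress.
#' @return A `sleepatt_cv`: list with `folds` (tibble of per-fold metrics),
#'   `summary` (mean/sd per metric), `fits`.
#' @export
cross_validate <- function(model_builder, sequences, k = 5L, cfg = train_config(),
                           seed = 1L, verbose = FALSE) {
  ids <- vapply(sequences, `[[`, character(1L), "subject_id")
  folds <- subject_folds(ids, k = k, seed = seed)
  results <- vector("list", length(folds))
  fits <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    old <- .Random.seed_save()
    set.seed(subject_seed(seed, 10000L + f))
    model <- model_builder()
    .Random.seed_restore(old)
    fold_cfg <- cfg
    fold_cfg$seed <- subject_seed(cfg$seed, 20000L + f)
    fit <- train(model, sequences, fold, fold_cfg, verbose = verbose)
    test_seqs <- Filter(function(s) s$subject_id %in% fold$test_subjects, sequences)
    met <- evaluate(fit, test_seqs)
    results[[f]] <- dplyr::mutate(met, fold = f, .before = 1L)
    fits[[f]] <- fit
  }
  fold_tbl <- dplyr::bind_rows(results)
  metric_cols <- c("accuracy", "macro_f1", "micro_f1", "auc_roc_macro", "auc_pr_macro")
  summary_tbl <- tidyr::pivot_longer(fold_tbl[, c("fold", metric_cols)],
                                     -"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mu = mean(.data$value, na.rm = TRUE),
                     sigma = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(folds = fold_tbl, summary = summary_tbl, fits = fits,
                 fold_defs = folds),
            class = "sleepatt_cv")
}

#' @export
print.sleepatt_cv <- function(x, ...) {
  cat("Subject-independent cross-validation (", nrow(x$folds), " folds)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-13s %.4f +/- %.4f\n", s$metric[i], s$mu[i], s$sigma[i]))
  }
  invisible(x)
}

#' @export
print.sleepatt_fit <- function(x, ...) {
  cat("Trained hybrid-attention sleep stager\n")
  cat("  epochs run:", nrow(x$history), " best epoch:", x$best_epoch, "\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f, val accuracy %s\n", last$train_loss,
              ifelse(is.na(last$val_accuracy), "-", sprintf("%.3f", last$val_accuracy))))
  invisible(x)
}
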