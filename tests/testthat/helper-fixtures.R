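# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# One full-scale 14-channel record with a single labelled epoch.
full_scale_record <- function() {
  fixture("full_record", function() {
    cfg <- cohort_config(n_subjects = 1L, epochs_per_subject = 1L, seed = 301L)
    generate_record(cfg, 1L)
  })
}

# A tiny preprocessed toy sequence (1 subject, 4 epochs, 2 channels @32 Hz).
tiny_sequences <- function() {
  fixture("tiny_seqs", function() {
    cfg <- toy_cohort_config(n_subjects = 1L, epochs_per_subject = 4L, seed = 11L)
    preprocess_cohort(generate_cohort(cfg))
  })
}

# A very small model matching tiny_sequences().
tiny_model <- function(seed = 4L, p = 6L, q = 5L, r = 4L) {
  seqs <- tiny_sequences()
  withr::with_seed(seed, {
    build_model(lengths(seqs[[1]]$epochs[[1]]$channels), montage_size = 2L,
                p = p, q = q, r = r, spec = toy_encoder_spec())
  })
}

epoch_labels <- function(seqn) {
  match(vapply(seqn$epochs, `[[`, character(1L), "label"), sleep_stages())
}

# Full-stack loss for finite-difference checks (evaluation mode, no dropout).
model_loss_plain <- function(model, epochs, labels) {
  fw <- sleepatt:::model_forward(model, epochs, train = FALSE)
  P <- do.call(rbind, lapply(fw$probs, function(p) as.vector(sleepatt:::nd_value(p))))
  batch_loss(P, labels)
}

# Tape gradients of the same loss.
model_grads <- function(model, epochs, labels) {
  sleepatt:::tape_start()
  on.exit(sleepatt:::tape_stop(), add = TRUE)
  w <- sleepatt:::wrap_model_params(model)
  fw <- sleepatt:::model_forward(w$model, epochs, train = FALSE)
  ln <- sleepatt:::window_loss_node(fw$probs, labels, model$dims$n_classes)
  sleepatt:::nd_backward(ln)
  list(loss = as.numeric(ln$value), grads = lapply(w$leaves, function(l) l$grad))
}
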