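#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained fit or a cross-validation result
#'
#' `tidy()` on a `sleepatt_fit` returns the per-epoch training history; on a
#' `sleepatt_cv` the per-fold metric table in long form. `glance()` returns a
#' one-row summary (final history row, or the across-fold mean/sd spread to
#' columns).
#'
#' @param x A `sleepatt_fit` or `sleepatt_cv`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sleepatt_fit <- function(x, ...) x$history

#' @rdname tidy.sleepatt_fit
#' @export
glance.sleepatt_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 train_loss = last$train_loss, val_accuracy = last$val_accuracy)
}

#' @rdname tidy.sleepatt_fit
#' @export
tidy.sleepatt_cv <- function(x, ...) {
  tidyr::pivot_longer(x$folds,
                      cols = c("accuracy", "macro_f1", "micro_f1",
                               "auc_roc_macro", "auc_pr_macro"),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.sleepatt_fit
#' @export
glance.sleepatt_cv <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(.rows = 1L)
  for (i in seq_len(nrow(s))) {
    out[[s$metric[i]]] <- s$mu[i]
    out[[paste0(s$metric[i], "_sd")]] <- s$sigma[i]
  }
  out$n_folds <- nrow(x$folds)
  out
}

#' Plot the training history
#'
#' @param object A `sleepatt_fit`.
#' @param ... Unused.
#' @return A ggplot of training loss (and validation accuracy when present)
#'   against epoch.
#' @export
autoplot.sleepatt_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, cols = -"epoch",
                           names_to = "series", values_to = "value")
  h <- dplyr::filter(h, !is.na(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "training epoch", y = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `sleepatt_cv`.
#' @param ... Unused.
#' @return A ggplot with one point per fold and metric plus the across-fold
#'   mean.
#' @export
autoplot.sleepatt_cv <- function(object, ...) {
  long <- tidy.sleepatt_cv(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Cross-validated test metrics (x = fold mean)") +
    ggplot2::theme_minimal()
}

#' Heatmap of attention weights
#'
#' @param weights Tibble from [attention_weights()].
#' @param kind `"channel"` or `"time"`.
#' @return A ggplot heatmap of weights over epochs.
#' @export
plot_attention <- function(weights, kind = c("channel", "time")) {
  want <- match.arg(kind)
  d <- weights[weights$kind == want, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = factor(.data$index),
                                  fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "epoch", y = if (want == "channel") "channel" else "window position",
                  fill = "weight",
                  title = sprintf("%s-wise attention", want)) +
    ggplot2::theme_minimal()
}
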