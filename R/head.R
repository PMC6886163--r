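#' Classifier head parameters
#'
#' @param q Per-direction GRU hidden size (context and hidden vectors are 2q).
#' @param r Dimension of the attentional representation.
#' @param n_classes Number of stage classes (5).
#' @param activation `"tanh"` (default) or `"relu"` nonlinearity applied to
#'   the attentional representation.
#' @return List with `W_h` (r x 4q), `b_h`, `W_s` (n_classes x r), `b_s`,
#'   `activation`.
#' @export
head_params <- function(q, r, n_classes = 5L, activation = c("tanh", "relu")) {
  activation <- match.arg(activation)
  list(W_h = glorot_uniform(r, 4L * q, 4L * q, r),
       b_h = matrix(0, r, 1L),
       W_s = glorot_uniform(n_classes, r, r, n_classes),
       b_s = matrix(0, n_classes, 1L),
       activation = activation)
}

#' Attentional representation
#'
#' `h_hat = f(W_h (c_t (+) h_t) + b_h)` with `f = tanh` by default: the
#' context vector and the current hidden state concatenated (length 4q) and
#' projected to length r.
#'
#' @param c_t Context vector (length 2q).
#' @param h_t Hidden state (length 2q).
#' @param params [head_params()].
#' @return Numeric vector of length r.
#' @export
attentional_representation <- function(c_t, h_t, params) {
  v <- c(as.vector(c_t), as.vector(h_t))
  if (length(v) != ncol(params$W_h)) stop("dimension mismatch in attentional_representation",
                                          call. = FALSE)
  z <- as.vector(params$W_h %*% v + params$b_h)
  if (identical(params$activation, "relu")) pmax(z, 0) else tanh(z)
}

#' Predict the sleep stage from an attentional representation
#'
#' `y_hat = softmax(W_s h_hat + b_s)`; the label is the argmax with
#' lowest-index tie-break over the fixed stage order
#' `WAKE, REM, S1, S2, S3`.
#'
#' @param h_hat Attentional representation (length r).
#' @param params [head_params()].
#' @return List with `probs` (named simplex vector) and `label`.
#' @export
predict_stage <- function(h_hat, params) {
  if (any(!is.finite(h_hat))) stop("non-finite input to predict_stage", call. = FALSE)
  logits <- as.vector(params$W_s %*% as.vector(h_hat) + params$b_s)
  probs <- channel_scores(logits)
  names(probs) <- sleep_stages()[seq_along(probs)]
  list(probs = probs, label = names(probs)[which.max(probs)])
}

#' Two-term cross-entropy training cost
#'
#' The cost pairs each softmax output with a two-term (Bernoulli-style)
#' cross-entropy, `-(y . log y_hat + (1 - y) . log(1 - y_hat))`, averaged
#' per record and then across records — records contribute equally regardless
#' of length. Probabilities are clipped to `[eps, 1 - eps]` before the logs.
#' `form = "categorical"` instead uses the standard single-term categorical
#' cross-entropy for comparison.
#'
#' @param predictions List (or matrix rows) of N simplex probability vectors.
#' @param labels Integer class indices (1..n_classes) or N x n_classes one-hot
#'   matrix.
#' @param record_lengths Integer vector of per-record epoch counts summing to
#'   N; defaults to a single record.
#' @param form `"two_term"` (default) or `"categorical"`.
#' @param eps Clipping constant.
#' @return Scalar cost `J >= 0`.
#' @export
#' @examples
#' batch_loss(list(rep(0.2, 5)), 3)   # -(log .2 + 4 log .8)
batch_loss <- function(predictions, labels, record_lengths = NULL,
                       form = c("two_term", "categorical"), eps = 1e-7) {
  form <- match.arg(form)
  P <- if (is.matrix(predictions)) predictions else do.call(rbind, predictions)
  N <- nrow(P)
  Y <- if (is.matrix(labels)) labels else {
    if (any(labels < 1L | labels > ncol(P))) stop("label index out of range", call. = FALSE)
    m <- matrix(0, N, ncol(P)); m[cbind(seq_len(N), labels)] <- 1; m
  }
  if (nrow(Y) != N || ncol(Y) != ncol(P)) stop("labels do not match predictions", call. = FALSE)
  if (any(abs(rowSums(Y) - 1) > 1e-9) || any(Y != 0 & Y != 1)) {
    stop("labels must be one-hot", call. = FALSE)
  }
  if (is.null(record_lengths)) record_lengths <- N
  if (sum(record_lengths) != N) stop("record_lengths must sum to the number of predictions",
                                     call. = FALSE)
  Pc <- pmin(pmax(P, eps), 1 - eps)
  per_sample <- if (form == "two_term") {
    -rowSums(Y * log(Pc) + (1 - Y) * log(1 - Pc))
  } else {
    -rowSums(Y * log(Pc))
  }
  rec <- rep.int(seq_along(record_lengths), record_lengths)
  mean(tapply(per_sample, rec, mean))
}
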