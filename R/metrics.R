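#' Classification metrics for staged predictions
#'
#' Computes the five evaluation measurements used throughout the package:
#' accuracy, macro-F1 (unweighted mean of per-class F1, a class absent from
#' both truth and prediction contributes 0), micro-F1 (pooled counts; equal
#' to accuracy for single-label multiclass predictions), and the macro
#' one-vs-rest areas under the ROC curve (rank-based) and the
#' precision-recall curve (average precision). The AUCs need predicted
#' probabilities and at least two observed classes; otherwise they are `NA`
#' with a warning.
#'
#' @param truth Character/factor vector of true stages.
#' @param pred Character/factor vector of predicted stages.
#' @param probs Optional N x K probability matrix with columns in
#'   `levels` order.
#' @param levels Class order; defaults to [sleep_stages()].
#' @return One-row tibble: `accuracy`, `macro_f1`, `micro_f1`,
#'   `auc_roc_macro`, `auc_pr_macro`.
#' @export
#' @examples
#' stage_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
#'               levels = c("A", "B"))
stage_metrics <- function(truth, pred, probs = NULL, levels = sleep_stages()) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  acc <- mean(truth == pred)
  f1 <- vapply(levels, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  macro_f1 <- mean(f1)
  tp_all <- sum(truth == pred)
  micro_f1 <- 2 * tp_all / (2 * tp_all + sum(truth != pred) + sum(truth != pred))
  auc_roc <- auc_pr <- NA_real_
  if (!is.null(probs)) {
    present <- levels[levels %in% unique(truth)]
    if (length(present) < 2L) {
      warning("AUCs undefined for a single-class test set", call. = FALSE)
    } else {
      roc <- vapply(present, function(k) {
        binary_auc_roc(truth == k, probs[, match(k, levels)])
      }, numeric(1L))
      pr <- vapply(present, function(k) {
        average_precision(truth == k, probs[, match(k, levels)])
      }, numeric(1L))
      auc_roc <- mean(roc)
      auc_pr <- mean(pr)
    }
  }
  tibble::tibble(accuracy = acc, macro_f1 = macro_f1, micro_f1 = micro_f1,
                 auc_roc_macro = auc_roc, auc_pr_macro = auc_pr)
}

# Rank-based (Mann-Whitney) ROC AUC with midrank tie handling.
binary_auc_roc <- function(y, score) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision: sum of precision at every positive, in score order.
average_precision <- function(y, score) {
  y <- as.logical(y)
  if (!any(y)) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  ys <- y[o]
  cum_tp <- cumsum(ys)
  prec <- cum_tp / seq_along(ys)
  sum(prec[ys]) / sum(ys)
}

#' Subject-independent cross-validation folds
#'
#' Partitions the subjects into `k` disjoint test sets (subject-level, so no
#' epoch of a test subject ever appears in training); within each fold the
#' remaining subjects are split into validation (`floor(ratios[2] * n)`
#' subjects) and training (the rest), following the 0.7:0.1:0.2 convention.
#' The assignment is a seeded shuffle, deterministic given `seed`.
#'
#' @param subject_ids Character vector of subject ids.
#' @param k Number of folds (`k <= length(subject_ids)`).
#' @param ratios Train/validation/test proportions (test is implied by `k`
#'   when `k > 1`; for `k = 1` a single `ratios` split is used).
#' @param seed Integer seed for the subject shuffle.
#' @return List of `k` folds, each with `fold_id`, `train_subjects`,
#'   `val_subjects`, `test_subjects`.
#' @export
#' @examples
#' folds <- subject_folds(sprintf("S%02d", 1:25), k = 5, seed = 1)
#' lengths(folds[[1]])
subject_folds <- function(subject_ids, k = 5L, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  n <- length(subject_ids)
  if (k > n) stop("more folds than subjects", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  shuffled <- sample(subject_ids)
  test_sets <- if (k == 1L) {
    list(shuffled[seq_len(max(1L, round(ratios[3L] * n)))])
  } else {
    split(shuffled, cut(seq_len(n), breaks = k, labels = FALSE))
  }
  lapply(seq_len(length(test_sets)), function(f) {
    test <- test_sets[[f]]
    rest <- setdiff(shuffled, test)
    n_val <- max(1L, floor(ratios[2L] * n))
    val <- rest[seq_len(min(n_val, length(rest) - 1L))]
    train <- setdiff(rest, val)
    if (length(train) == 0L) stop("fold has an empty training set", call. = FALSE)
    list(fold_id = f, train_subjects = train, val_subjects = val, test_subjects = test)
  })
}
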