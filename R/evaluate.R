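#' Per-label confusion counts
#'
#' True/false positive/negative counts per label from the binary label and
#' classification matrices: a cell is TP when both are 1, TN when both are
#' 0, FP when only the prediction is 1, FN when only the label is 1. For
#' every label TP + TN + FP + FN equals the sample count.
#'
#' @param lb m x q binary label matrix.
#' @param cf m x q binary classification matrix.
#' @return Data frame with one row per label and columns `label`, `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(lb, cf) {
  lb <- as.matrix(lb); cf <- as.matrix(cf)
  stopifnot(identical(dim(lb), dim(cf)))
  data.frame(
    label = if (!is.null(colnames(lb))) colnames(lb) else as.character(seq_len(ncol(lb))),
    tp = colSums(lb == 1 & cf == 1),
    tn = colSums(lb == 0 & cf == 0),
    fp = colSums(lb == 0 & cf == 1),
    fn = colSums(lb == 1 & cf == 0),
    row.names = NULL
  )
}

#' Sample-level accuracy
#'
#' A sample counts as correctly predicted when at least one of its true
#' labels is called positive (one true positive suffices); the accuracy is
#' the fraction of correct samples. This is the criterion used for both
#' training accuracy (at the training threshold) and validation accuracy
#' (at the validation threshold).
#'
#' @inheritParams confusion_counts
#' @return Fraction in [0, 1].
#' @export
sample_accuracy <- function(lb, cf) {
  lb <- as.matrix(lb); cf <- as.matrix(cf)
  stopifnot(identical(dim(lb), dim(cf)))
  cp <- rowSums(lb == 1 & cf == 1) > 0
  mean(cp)
}

#' Class confusion matrix from argmax predictions
#'
#' Cross-tabulates actual class against the single predicted (argmax)
#' class: rows are actual classes, columns predicted. A multi-label sample
#' contributes one row-count per actual label, so the total count equals
#' the number of (sample, actual-label) pairs.
#'
#' @param lb m x q binary label matrix.
#' @param predicted length-m vector of predicted class indices or names
#'   (the argmax class of each sample).
#' @return q x q count matrix (rows actual, columns predicted).
#' @export
confusion_matrix_counts <- function(lb, predicted) {
  lb <- as.matrix(lb)
  q <- ncol(lb)
  cls <- if (!is.null(colnames(lb))) colnames(lb) else as.character(seq_len(q))
  if (is.character(predicted) || is.factor(predicted)) {
    predicted <- match(as.character(predicted), cls)
  }
  stopifnot(length(predicted) == nrow(lb), all(predicted %in% seq_len(q)))
  cm <- matrix(0L, q, q, dimnames = list(actual = cls, predicted = cls))
  for (i in seq_len(nrow(lb))) {
    for (j in which(lb[i, ] == 1)) {
      cm[j, predicted[[i]]] <- cm[j, predicted[[i]]] + 1L
    }
  }
  cm
}

#' Drug-level k-fold split
#'
#' Partitions *drugs* (not samples) into k validation folds, so that all
#' replicate samples of a drug stay on the same side of every split and
#' replicate near-duplicates cannot leak between training and validation.
#'
#' @param drugs character vector of drug ids.
#' @param k number of folds (>= 2, <= number of drugs).
#' @param seed integer seed for the shuffle.
#' @return List of k elements, each `list(train = ..., validation = ...)`;
#'   validation folds are disjoint and cover every drug exactly once.
#' @export
k_fold_split <- function(drugs, k, seed = 1L) {
  drugs <- unique(as.character(drugs))
  if (k < 2L) stop("k_folds must be at least 2")
  if (k > length(drugs)) stop("k_folds exceeds the number of drugs")
  ord <- with_seed(seed, sample(drugs))
  fold_of <- rep(seq_len(k), length.out = length(ord))
  lapply(seq_len(k), function(f) {
    list(train = sort(ord[fold_of != f]), validation = sort(ord[fold_of == f]))
  })
}

#' Iteration-averaged per-drug probability matrix
#'
#' Averages the full-data probability matrices recorded over the final
#' averaging window of a fit elementwise, then averages within each drug
#' over that drug's credible-set samples, giving one probability row per
#' drug. Rows remain stochastic (each sums to 1).
#'
#' @param fit a `"softmax_mlc"` fit (or a bare list of probability
#'   matrices).
#' @param drugs named character vector mapping each training sample (row of
#'   the probability matrices) to its drug.
#' @return drugs x q probability matrix.
#' @export
averaged_probability_matrix <- function(fit, drugs) {
  hist <- if (inherits(fit, "softmax_mlc")) fit$prob_history else fit
  stopifnot(length(hist) >= 1L)
  mean_p <- Reduce(`+`, hist) / length(hist)
  drugs <- as.character(drugs)
  stopifnot(length(drugs) == nrow(mean_p))
  agg <- rowsum(mean_p, group = drugs, reorder = FALSE)
  agg / as.vector(table(factor(drugs, levels = rownames(agg))))
}

#' Drug-level cross-validation of the softmax classifier
#'
#' Splits the cohort into k drug-level folds, refits the classifier on each
#' training side and scores sample accuracy on both sides: at the training
#' threshold on the training fold and at the (lower) validation threshold
#' on the held-out fold.
#'
#' @param x m x n credible-set sample matrix.
#' @param y m x q binary label matrix (rows aligned with `x`).
#' @param drugs named character vector mapping samples to drugs.
#' @param k number of folds.
#' @param training_threshold,validation_threshold probability cut-offs.
#' @param seed integer seed (fold split and per-fold training).
#' @param ... further hyper-parameters passed to [softmax_train()].
#' @return Data frame with one row per fold: `fold`,
#'   `training_accuracy`, `validation_accuracy`.
#' @export
cross_validate <- function(x, y, drugs, k = 5L,
                           training_threshold = 0.30,
                           validation_threshold = 0.06, seed = 1L, ...) {
  folds <- k_fold_split(drugs, k, seed = seed)
  res <- lapply(seq_along(folds), function(f) {
    tr <- drugs %in% folds[[f]]$train
    va <- !tr
    fit <- softmax_train(x[tr, , drop = FALSE], y[tr, , drop = FALSE],
                         training_threshold = training_threshold,
                         seed = seed + f, ...)
    cf_tr <- predict(fit, x[tr, , drop = FALSE], type = "class",
                     threshold = training_threshold)
    cf_va <- predict(fit, x[va, , drop = FALSE], type = "class",
                     threshold = validation_threshold)
    data.frame(
      fold = f,
      training_accuracy = sample_accuracy(y[tr, , drop = FALSE], cf_tr),
      validation_accuracy = sample_accuracy(y[va, , drop = FALSE], cf_va)
    )
  })
  do.call(rbind, res)
}
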