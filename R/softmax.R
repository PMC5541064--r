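#' Row-normalised training targets
#'
#' Converts the binary label matrix into row-stochastic softmax targets:
#' each row of the label matrix is divided by its number of labels, so a
#' two-label sample targets probability 1/2 on each of its classes.
#'
#' @param lb m x q binary label matrix, every row with at least one 1.
#' @return m x q row-stochastic matrix, positive only where `lb` is 1.
#' @export
normalize_targets <- function(lb) {
  lb <- as.matrix(lb)
  rs <- rowSums(lb)
  if (any(rs == 0)) stop("label matrix has all-zero row(s)")
  lb / rs
}

# Append the bias input (a column of ones) to a sample matrix.
augment_bias <- function(x) {
  x <- as.matrix(x)
  cbind(x, bias = rep(1, nrow(x)))
}

# m x q softmax probabilities for augmented inputs X (m x (n+1)) under
# theta (q x (n+1)); max-logit subtraction keeps the exponentials finite.
softmax_prob_matrix <- function(theta, X) {
  logits <- X %*% t(theta)
  if (!all(is.finite(logits))) stop("non-finite logits in softmax")
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  e / rowSums(e)
}

#' Softmax class probabilities for one sample
#'
#' The softmax regression hypothesis: class j receives probability
#' exp(theta_j' x) / sum_l exp(theta_l' x), with x augmented by the bias
#' input 1. Computed with max-logit subtraction for numerical stability.
#' With q = 2 this reduces to the logistic hypothesis.
#'
#' @param theta q x (n+1) parameter matrix, last column the bias unit.
#' @param x length-n feature vector (unaugmented).
#' @return Length-q probability vector (positive, sums to 1).
#' @export
softmax_probabilities <- function(theta, x) {
  p <- softmax_prob_matrix(theta, augment_bias(matrix(x, nrow = 1L)))
  stats::setNames(as.vector(p), rownames(theta))
}

#' Regularised cross-entropy objective
#'
#' The training objective: mean cross-entropy between row-stochastic
#' targets and softmax probabilities, plus `lambda` times the squared
#' Frobenius norm of the non-bias weights (the structural-risk term).
#' Probabilities are floored at 1e-300 inside the logarithm.
#'
#' @param theta q x (n+1) parameter matrix.
#' @param x m x n sample matrix (unaugmented).
#' @param y m x q row-stochastic target matrix.
#' @param lambda regularisation weight (default 1).
#' @return Scalar objective value.
#' @export
softmax_objective <- function(theta, x, y, lambda = 1) {
  X <- augment_bias(x)
  stopifnot(ncol(X) == ncol(theta), nrow(X) == nrow(y),
            nrow(theta) == ncol(y))
  p <- softmax_prob_matrix(theta, X)
  if (any(p[y > 0] < 1e-300)) {
    warning("probabilities clamped at 1e-300 in cross-entropy")
  }
  ce <- -sum(y * log(pmax(p, 1e-300))) / nrow(X)
  w <- theta[, -ncol(theta), drop = FALSE]
  ce + lambda * sum(w * w)
}

#' Analytic gradient of the objective
#'
#' Gradient of [softmax_objective()] restricted to a (mini-)batch:
#' (P - Y)'X / m on all columns plus 2*lambda*theta on the non-bias
#' columns.
#'
#' @inheritParams softmax_objective
#' @return q x (n+1) gradient matrix.
#' @export
softmax_gradient <- function(theta, x, y, lambda = 1) {
  X <- augment_bias(x)
  p <- softmax_prob_matrix(theta, X)
  g <- crossprod(p - y, X) / nrow(X)
  pen <- 2 * lambda * theta
  pen[, ncol(theta)] <- 0
  g + pen
}

#' Fit the multi-label softmax regression classifier
#'
#' Trains a q-class softmax regression model on trial-level expression
#' samples with (possibly multi-label) class targets, by mini-batch
#' gradient descent on the L2-regularised cross-entropy. Multi-label rows
#' are row-normalised ([normalize_targets()]) so each target sums to 1.
#' Parameters start at zero (the objective is convex, so initialisation
#' only affects the trajectory); one iteration is one epoch of seeded,
#' shuffled mini-batches. Within the final `averaging_window` iterations
#' the full-data probability matrix is recorded, to be averaged by
#' [averaged_probability_matrix()].
#'
#' The hyper-parameter defaults are the learning-curve optimum for this
#' model family: learning rate 0.06, training threshold 0.30, regularisation
#' weight 1, with at least 200 iterations and the last 100 averaged.
#'
#' @param x m x n sample matrix (rows are perturbation samples).
#' @param y m x q binary label matrix (see [label_matrix()]).
#' @param learning_rate gradient-descent step size.
#' @param lambda regularisation weight on the non-bias squared weights.
#' @param batch_size mini-batch size (capped at m).
#' @param iterations number of epochs.
#' @param averaging_window number of final epochs whose full-data
#'   probability matrices are retained (must be <= `iterations`).
#' @param training_threshold probability cut-off used for the per-epoch
#'   training accuracy recorded in the history.
#' @param seed integer seed driving the batch shuffles.
#' @return An object of class `"softmax_mlc"` with components `theta` (the
#'   q x (n+1) parameter matrix, bias last), `classes`, `history` (per-epoch
#'   `loss` and `accuracy`), `prob_history` (list of full-data probability
#'   matrices over the averaging window), and the hyper-parameters.
#' @seealso [predict.softmax_mlc()], [averaged_probability_matrix()]
#' @export
softmax_train <- function(x, y, learning_rate = 0.06, lambda = 1,
                          batch_size = 32L, iterations = 200L,
                          averaging_window = 100L,
                          training_threshold = 0.30, seed = 1L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  m <- nrow(x)
  stopifnot(m == nrow(y), m >= 1L)
  if (averaging_window > iterations) {
    stop("averaging_window must not exceed iterations")
  }
  batch_size <- min(as.integer(batch_size), m)
  targets <- normalize_targets(y)
  X <- augment_bias(x)
  q <- ncol(y)
  theta <- matrix(0, nrow = q, ncol = ncol(X),
                  dimnames = list(colnames(y), colnames(X)))
  loss <- numeric(iterations)
  acc <- numeric(iterations)
  prob_history <- vector("list", min(averaging_window, iterations))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      ord <- sample.int(m)
      for (start in seq(1L, m, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, m)]
        g <- softmax_gradient(theta, x[idx, , drop = FALSE],
                              targets[idx, , drop = FALSE], lambda)
        theta <- theta - learning_rate * g
      }
      p <- softmax_prob_matrix(theta, X)
      loss[it] <- -sum(targets * log(pmax(p, 1e-300))) / m +
        lambda * sum(theta[, -ncol(theta)]^2)
      if (!is.finite(loss[it])) {
        stop(sprintf("training diverged at iteration %d (loss = %g); %s",
                     it, loss[it],
                     "reduce the learning rate or increase lambda"))
      }
      acc[it] <- sample_accuracy(y, (p >= training_threshold) * 1L)
      win_pos <- it - (iterations - length(prob_history))
      if (win_pos >= 1L) {
        dimnames(p) <- list(rownames(x), colnames(y))
        prob_history[[win_pos]] <- p
      }
    }
  })
  structure(
    list(
      theta = theta, classes = colnames(y),
      history = data.frame(iteration = seq_len(iterations),
                           loss = loss, accuracy = acc),
      prob_history = prob_history,
      hyper = list(learning_rate = learning_rate, lambda = lambda,
                   batch_size = batch_size, iterations = iterations,
                   averaging_window = averaging_window,
                   training_threshold = training_threshold, seed = seed)
    ),
    class = "softmax_mlc"
  )
}

#' @export
print.softmax_mlc <- function(x, ...) {
  h <- x$hyper
  cat("Multi-label softmax regression classifier\n")
  cat(sprintf("  classes: %d (%s)\n", length(x$classes),
              paste(x$classes, collapse = " ")))
  cat(sprintf("  parameters: %d x %d (bias included)\n",
              nrow(x$theta), ncol(x$theta)))
  cat(sprintf("  trained %d iterations (lr %g, lambda %g, batch %d)\n",
              h$iterations, h$learning_rate, h$lambda, h$batch_size))
  if (h$iterations > 0L) {
    n <- nrow(x$history)
    cat(sprintf("  final loss %.4f, training accuracy %.3f (threshold %.2f)\n",
                x$history$loss[n], x$history$accuracy[n],
                h$training_threshold))
  }
  invisible(x)
}

#' @export
summary.softmax_mlc <- function(object, ...) {
  out <- list(
    classes = object$classes,
    hyper = object$hyper,
    history_tail = utils::head(object$history[rev(seq_len(nrow(object$history))), ], 5L),
    weight_norm = sqrt(sum(object$theta[, -ncol(object$theta)]^2))
  )
  class(out) <- "summary.softmax_mlc"
  out
}

#' @export
print.summary.softmax_mlc <- function(x, ...) {
  cat("Multi-label softmax regression classifier\n")
  cat(sprintf("  non-bias weight norm: %.4f\n", x$weight_norm))
  cat("  last iterations:\n")
  print(x$history_tail, row.names = FALSE)
  invisible(x)
}

#' @export
coef.softmax_mlc <- function(object, ...) object$theta

#' Predict from a fitted softmax classifier
#'
#' @param object a `"softmax_mlc"` fit.
#' @param newdata m x n sample matrix.
#' @param type `"prob"` for the m x q probability matrix, `"class"` for the
#'   thresholded binary classification matrix.
#' @param threshold probability cut-off used when `type = "class"`.
#' @param ... unused.
#' @return m x q numeric (probabilities) or binary (classification) matrix.
#' @export
predict.softmax_mlc <- function(object, newdata, type = c("prob", "class"),
                                threshold = 0.30, ...) {
  type <- match.arg(type)
  p <- softmax_prob_matrix(object$theta, augment_bias(newdata))
  dimnames(p) <- list(rownames(newdata), object$classes)
  if (type == "prob") p else predict_classification(p, threshold)
}

#' Learning-curve plot of a softmax fit
#'
#' Plots per-iteration loss and training accuracy.
#'
#' @param x a `"softmax_mlc"` fit.
#' @param ... passed to [plot()].
#' @export
plot.softmax_mlc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$iteration, x$history$loss, type = "l",
       xlab = "iteration", ylab = "objective", main = "Loss", ...)
  plot(x$history$iteration, x$history$accuracy, type = "l", ylim = c(0, 1),
       xlab = "iteration", ylab = "training accuracy",
       main = "Accuracy", ...)
  invisible(x)
}

#' Threshold probabilities into a classification matrix
#'
#' A sample is called positive for every class whose probability reaches
#' the cut-off: CF_ij = 1 iff p_ij >= threshold. With a softmax over q
#' classes a low threshold can call several classes per sample, which is
#' what makes the classifier multi-label.
#'
#' @param p m x q probability matrix.
#' @param threshold cut-off in [0, 1] (e.g. 0.30 for training accuracy,
#'   0.06 for validation accuracy).
#' @return m x q binary matrix.
#' @export
predict_classification <- function(p, threshold) {
  stopifnot(threshold >= 0)
  (as.matrix(p) >= threshold) * 1L
}
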