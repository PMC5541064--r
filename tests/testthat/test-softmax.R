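test_that("targets are row-normalised over a sample's labels", {
  lb <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  y <- normalize_targets(lb)
  expect_equal(y[1, ], c(1, 0, 0))
  expect_equal(y[2, ], c(0.5, 0.5, 0))
  expect_equal(unname(rowSums(y)), rep(1, 3))
  expect_error(normalize_targets(rbind(c(0, 0, 0))), "all-zero")
})

test_that("softmax probabilities are stochastic, shift-invariant and logistic at q = 2", {
  theta0 <- matrix(0, nrow = 4, ncol = 6)
  expect_equal(unname(softmax_probabilities(theta0, rnorm(5))), rep(0.25, 4))

  set.seed(1)
  theta <- matrix(rnorm(4 * 6), nrow = 4)
  x <- rnorm(5)
  p <- softmax_probabilities(theta, x)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  # adding a constant to every logit leaves the output unchanged
  shifted <- theta; shifted[, 6] <- shifted[, 6] + 3.7
  expect_equal(softmax_probabilities(shifted, x), p)

  # q = 2 with logits (1, 0) reduces to the logistic hypothesis
  th2 <- rbind(c(0, 1), c(0, 0))      # one feature + bias
  p2 <- softmax_probabilities(th2, 0)
  expect_equal(unname(p2), c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))))
})

test_that("the objective matches closed forms and an elementwise oracle", {
  x <- diag(3) * 10
  y <- diag(3)
  # near-one-hot predictions, lambda = 0 -> objective ~ 0
  theta_sep <- cbind(diag(3) * 100, 0)
  expect_lt(softmax_objective(theta_sep, x, y, lambda = 0), 1e-6)
  # uniform predictions vs one-hot targets -> ln q
  theta0 <- matrix(0, 3, 4)
  expect_equal(softmax_objective(theta0, x, y, lambda = 0), log(3))

  set.seed(8)
  xr <- matrix(rnorm(4 * 2), 4, 2)
  yr <- normalize_targets(cbind(1, rbinom(4, 1, 0.5), rbinom(4, 1, 0.5)))
  th <- matrix(rnorm(9), 3, 3)
  lam <- 0.7
  # naive double-loop oracle
  oracle <- 0
  for (i in 1:4) {
    pi <- softmax_probabilities(th, xr[i, ])
    for (j in 1:3) oracle <- oracle - yr[i, j] * log(pi[j])
  }
  oracle <- oracle / 4 + lam * sum(th[, 1:2]^2)
  expect_equal(softmax_objective(th, xr, yr, lam), unname(oracle),
               tolerance = 1e-12)
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(5)
  x <- matrix(rnorm(5 * 4), 5, 4)
  y <- normalize_targets(cbind(1, rbinom(5, 1, 0.5), rbinom(5, 1, 0.5)))
  theta <- matrix(rnorm(3 * 5, sd = 0.3), 3, 5)
  lam <- 0.5
  g <- softmax_gradient(theta, x, y, lam)
  h <- 1e-6
  num <- theta * 0
  for (i in seq_len(nrow(theta))) {
    for (j in seq_len(ncol(theta))) {
      tp <- theta; tp[i, j] <- tp[i, j] + h
      tm <- theta; tm[i, j] <- tm[i, j] - h
      num[i, j] <- (softmax_objective(tp, x, y, lam) -
                      softmax_objective(tm, x, y, lam)) / (2 * h)
    }
  }
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-6)
})

test_that("the penalty contributes exactly 2*lambda*theta on non-bias columns", {
  set.seed(6)
  x <- matrix(rnorm(8), 4, 2)
  y <- normalize_targets(cbind(rbinom(4, 1, 0.5) + 1, 1))
  theta <- matrix(rnorm(6), 2, 3)
  diff <- softmax_gradient(theta, x, y, lambda = 2) -
    softmax_gradient(theta, x, y, lambda = 0)
  expected <- 2 * 2 * theta
  expected[, 3] <- 0
  expect_equal(diff, expected, ignore_attr = TRUE)
})

test_that("training honours degenerate and descent contracts", {
  set.seed(2)
  x <- matrix(rnorm(12 * 6), 12, 6)
  y <- label_matrix(rep(list("A", c("A", "C"), "B"), 4)[1:12],
                    classes = c("A", "B", "C"))
  rownames(y) <- NULL
  fit0 <- softmax_train(x, y, iterations = 0, averaging_window = 0)
  expect_true(all(fit0$theta == 0))

  # full-batch small-step descent: objective non-increasing
  fit <- softmax_train(x, y, learning_rate = 0.005, lambda = 0.1,
                       batch_size = 12, iterations = 40,
                       averaging_window = 1, seed = 3)
  expect_true(all(diff(fit$history$loss) <= 1e-10))

  expect_error(softmax_train(x, y, iterations = 10, averaging_window = 20),
               "averaging_window")
})

test_that("a separable three-class problem is fit to perfect training accuracy", {
  set.seed(13)
  centers <- diag(3) * 6
  x <- centers[rep(1:3, each = 10), ] + matrix(rnorm(90, sd = 0.3), 30, 3)
  y <- diag(3)[rep(1:3, each = 10), ]
  colnames(y) <- c("A", "B", "C")
  fit <- softmax_train(x, y, lambda = 0.01, iterations = 100,
                       averaging_window = 10, seed = 14)
  cf <- predict(fit, x, type = "class", threshold = 0.30)
  expect_equal(sample_accuracy(y, cf), 1)
  # and the fit is genuinely discriminative, not just above threshold
  expect_equal(unname(max.col(predict(fit, x))), rep(1:3, each = 10))
})

test_that("classification thresholding follows the closed >= rule", {
  p <- rbind(c(0.5, 0.3, 0.2))
  expect_equal(unname(predict_classification(p, 0.30)), rbind(c(1, 1, 0)))
  expect_equal(unname(predict_classification(rbind(c(0.07, 0.05)), 0.06)),
               rbind(c(1, 0)))
  expect_true(all(predict_classification(p, 1.5) == 0))
})

test_that("confusion counts match the cell-by-cell oracle and conserve m", {
  lb <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_true(all(confusion_counts(lb, lb)[, c("fp", "fn")] == 0))

  one <- confusion_counts(rbind(c(1, 0)), rbind(c(0, 1)))
  expect_equal(one$fn, c(1, 0))
  expect_equal(one$fp, c(0, 1))

  set.seed(19)
  lbr <- matrix(rbinom(18, 1, 0.5), 6, 3)
  cfr <- matrix(rbinom(18, 1, 0.5), 6, 3)
  got <- confusion_counts(lbr, cfr)
  for (j in 1:3) {
    tp <- tn <- fp <- fn <- 0
    for (i in 1:6) {
      if (lbr[i, j] == 1 && cfr[i, j] == 1) tp <- tp + 1
      if (lbr[i, j] == 0 && cfr[i, j] == 0) tn <- tn + 1
      if (lbr[i, j] == 0 && cfr[i, j] == 1) fp <- fp + 1
      if (lbr[i, j] == 1 && cfr[i, j] == 0) fn <- fn + 1
    }
    expect_equal(unlist(got[j, c("tp", "tn", "fp", "fn")], use.names = FALSE),
                 c(tp, tn, fp, fn))
  }
  expect_equal(got$tp + got$tn + got$fp + got$fn, rep(6, 3))
})

test_that("sample accuracy counts one true positive as a correct sample", {
  expect_equal(sample_accuracy(rbind(c(1, 1, 0)), rbind(c(1, 0, 1))), 1)
  expect_equal(sample_accuracy(rbind(c(1, 0)), rbind(c(0, 0))), 0)

  lb <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 0, 1), c(1, 0, 1))
  cf <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  # enumeration oracle: samples 1, 3, 4 have a TP
  expect_equal(sample_accuracy(lb, cf), 3 / 5)
})

test_that("the argmax confusion matrix tallies (sample, actual-label) pairs", {
  lb <- rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 1))
  pred <- c(1, 2, 2, 1)
  cm <- confusion_matrix_counts(lb, pred)
  expect_equal(sum(cm), sum(lb))
  # hand tally: actual 1 -> pred {1, 2}; actual 2 -> pred {2, 2, 1}
  expect_equal(unname(cm), rbind(c(1, 1), c(1, 2)))

  perfect <- confusion_matrix_counts(diag(3), 1:3)
  expect_equal(unname(perfect), diag(3) * 1L)
  expect_equal(unname(rowSums(cm)), unname(colSums(lb)))
})

test_that("k-fold splits partition drugs without replicate leakage", {
  drugs <- sprintf("d%02d", 1:10)
  folds <- k_fold_split(drugs, 5, seed = 2)
  expect_length(folds, 5)
  vals <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(vals) == 2))
  expect_setequal(unlist(vals), drugs)
  expect_equal(anyDuplicated(unlist(vals)), 0L)
  for (f in folds) expect_length(intersect(f$train, f$validation), 0)
  expect_error(k_fold_split(drugs, 1), "at least 2")
  expect_error(k_fold_split(drugs, 11), "exceeds")

  # leakage audit on a synthetic cohort: a drug's samples never straddle a fold
  cohort <- generate_cohort(small_spec(), seed = 50)
  sample_drugs <- cohort$expression$drugs
  folds2 <- k_fold_split(sample_drugs, 3, seed = 51)
  for (f in folds2) {
    tr_samples <- names(sample_drugs)[sample_drugs %in% f$train]
    va_samples <- names(sample_drugs)[sample_drugs %in% f$validation]
    expect_length(intersect(sample_drugs[tr_samples], sample_drugs[va_samples]), 0)
    expect_setequal(c(tr_samples, va_samples), names(sample_drugs))
  }
})

test_that("iteration-averaged probabilities are the windowed per-drug means", {
  p <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  drugs <- c(s1 = "d1", s2 = "d2")
  expect_equal(averaged_probability_matrix(list(p, p, p), drugs),
               rbind(d1 = p[1, ], d2 = p[2, ]))
  # window of two matrices P and 3P averages to 2P
  expect_equal(averaged_probability_matrix(list(p, 3 * p), drugs),
               rbind(d1 = 2 * p[1, ], d2 = 2 * p[2, ]))
  # per-drug averaging over a drug's samples
  drugs2 <- c(s1 = "d1", s2 = "d1")
  expect_equal(unname(averaged_probability_matrix(list(p), drugs2)),
               unname(rbind(colMeans(p))))
  # means of row-stochastic matrices stay row-stochastic
  cohort <- generate_cohort(small_spec(n_drugs = 10), seed = 60)
  core <- fit_cohort_core(cohort, seed = 61, iterations = 5,
                          averaging_window = 3)
  expect_equal(unname(rowSums(core$prob)), rep(1, nrow(core$prob)))
})
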