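# Shared fixtures: small synthetic cohorts and an end-to-end core run
# (generate -> credible set -> train -> DTN-T) used by several test files.

small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_drugs = 30, n_genes = 120, trials_per_drug = c(2L, 5L)),
    list(...)
  )
  do.call(synthetic_spec, args)
}

# Run the analysis core on a cohort and return the pieces downstream tests
# need. Iteration counts are scaled down where a test only needs structure.
fit_cohort_core <- function(cohort, seed, iterations = 200L,
                            averaging_window = 100L) {
  cs <- credible_expression(cohort$expression, seed = seed + 100L)
  y <- label_matrix(cohort$labels[cs$drugs], cohort$classes)
  fit <- softmax_train(cs$values, y, iterations = iterations,
                       averaging_window = averaging_window,
                       seed = seed + 300L)
  prob <- averaged_probability_matrix(fit, cs$drugs)
  dtnt <- build_dtn_t(prob, cohort$labels)
  list(credible = cs, y = y, fit = fit, prob = prob, dtnt = dtnt)
}

# Independent Pearson oracle from the covariance formula, elementwise.
cor_oracle <- function(u, v) {
  cu <- u - mean(u); cv <- v - mean(v)
  sum(cu * cv) / sqrt(sum(cu^2) * sum(cv^2))
}

# Independent average-rank Spearman oracle: Pearson on midranks.
spearman_oracle <- function(u, v) {
  cor_oracle(rank(u, ties.method = "average"), rank(v, ties.method = "average"))
}

# Brute-force enrichment-ratio oracle: literal set counting over the drug
# list, independent of the matrix algebra in the implementation.
er_oracle <- function(edges, labels, x, y) {
  drugs <- rownames(edges)
  dx <- Filter(function(d) x %in% labels[[d]], drugs)
  to_y <- Filter(function(d) edges[d, y] == 1, drugs)
  any_e <- Filter(function(d) any(edges[d, ] == 1), drugs)
  a <- length(intersect(dx, to_y))
  b <- length(to_y)
  c_ <- length(intersect(dx, any_e))
  d <- length(any_e)
  if (b == 0 || c_ == 0) 0 else (a / b) / (c_ / d)
}
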