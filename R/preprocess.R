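#' Pearson correlation matrix of a drug's trials
#'
#' Pairwise Pearson correlation between replicate perturbation trials.
#' A zero-variance trial cannot be correlated; its off-diagonal entries are
#' defined as 0 (with a warning) so that trial indices stay stable.
#'
#' @param trials t x n matrix, one row per trial.
#' @return Symmetric t x t matrix with unit diagonal, entries in [-1, 1].
#' @export
trial_correlation_matrix <- function(trials) {
  trials <- as.matrix(trials)
  t <- nrow(trials)
  sds <- apply(trials, 1L, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance trial(s); correlations set to 0")
  }
  r <- matrix(0, t, t)
  ok <- which(!flat)
  if (length(ok) >= 2L) {
    r[ok, ok] <- stats::cor(t(trials[ok, , drop = FALSE]))
  }
  diag(r) <- 1
  dimnames(r) <- list(rownames(trials), rownames(trials))
  r
}

# Mean pairwise Pearson correlation within a group of trial indices;
# singletons are scored -Inf (intra-class correlation needs >= 2 members).
group_correlation_score <- function(corr, idx) {
  if (length(idx) < 2L) return(-Inf)
  sub <- corr[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Select the most internally correlated k-means group of trials
#'
#' Partitions a drug's replicate trials into (at most) `k` groups by k-means
#' on the raw Z-score vectors and returns the group with the maximum mean
#' intra-group Pearson correlation. Singleton groups are scored worst; when
#' no split can produce a two-member group (fewer than `k + 1` trials, or
#' all trials identical) every trial is returned.
#'
#' @param trials t x n matrix of replicate trials.
#' @param k number of k-means groups; capped at the number of distinct
#'   trials. Default 2: the smallest split that can reject outlier trials.
#' @param seed integer seed for the k-means restarts.
#' @return Integer vector of selected trial indices (`s1_indices`).
#' @export
select_representative_group <- function(trials, k = 2L, seed = 1L) {
  trials <- as.matrix(trials)
  t <- nrow(trials)
  stopifnot(t >= 1L, k >= 1L)
  if (t == 1L) return(1L)
  k <- min(k, t)
  n_distinct <- nrow(unique(trials))
  k <- min(k, n_distinct)
  # k-means needs k < t, and a k = t split is all singletons anyway
  if (k == 1L || k >= t) return(seq_len(t))
  cl <- with_seed(seed, stats::kmeans(trials, centers = k, nstart = 10L))$cluster
  corr <- suppressWarnings(trial_correlation_matrix(trials))
  groups <- split(seq_len(t), cl)
  scores <- vapply(groups, function(idx) group_correlation_score(corr, idx),
                   0)
  if (all(!is.finite(scores))) {
    return(groups[[1L]])
  }
  groups[[which.max(scores)]]
}

#' Credible training set of a drug
#'
#' Collapses a drug's replicate trials into the credible set S used for
#' learning: S1, the most internally correlated k-means group of trials
#' ([select_representative_group()]), plus S2, the mean over *all* trials
#' appended as one independent sample. The result always has |S1| + 1 rows.
#'
#' @inheritParams select_representative_group
#' @param drug_id optional drug identifier carried through to the result.
#' @return A list of class `"credible_set"`: `drug_id`, `s1_indices`, `s2`
#'   (the mean vector), and `samples`, the (|S1| + 1) x n matrix.
#' @export
credible_set <- function(trials, k = 2L, seed = 1L, drug_id = NULL) {
  trials <- as.matrix(trials)
  s1 <- select_representative_group(trials, k = k, seed = seed)
  s2 <- colMeans(trials)
  samples <- rbind(trials[s1, , drop = FALSE], s2)
  rn <- rownames(trials)
  if (is.null(rn)) rn <- sprintf("t%d", seq_len(nrow(trials)))
  rownames(samples) <- c(rn[s1], "S2_mean")
  structure(
    list(drug_id = drug_id, s1_indices = s1, s2 = s2, samples = samples),
    class = "credible_set"
  )
}

#' Credible sets for a whole cohort
#'
#' Applies [credible_set()] to every drug of an expression table and stacks
#' the per-drug samples into one training matrix.
#'
#' @param expr an [expression_table()].
#' @param k,seed passed to [credible_set()]; each drug gets a sub-seed
#'   derived from `seed` so the result is reproducible drug by drug.
#' @return An [expression_table()] of credible-set samples (rows named
#'   `<drug>_S<row>`), with `drugs` mapping each row to its drug.
#' @export
credible_expression <- function(expr, k = 2L, seed = 1L) {
  stopifnot(inherits(expr, "expression_table"))
  drug_ids <- unique(expr$drugs)
  blocks <- vector("list", length(drug_ids))
  for (i in seq_along(drug_ids)) {
    d <- drug_ids[[i]]
    trials <- expr$values[expr$drugs == d, , drop = FALSE]
    cs <- credible_set(trials, k = k, seed = seed + i, drug_id = d)
    rownames(cs$samples) <- sprintf("%s_S%02d", d, seq_len(nrow(cs$samples)))
    blocks[[i]] <- cs$samples
  }
  values <- do.call(rbind, blocks)
  drugs <- rep(drug_ids, vapply(blocks, nrow, 0L))
  names(drugs) <- rownames(values)
  expression_table(values, drugs)
}
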