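#' Build the drug--therapeutic-property network DTN-T
#'
#' Takes the drugs x q iteration-averaged probability matrix and zeroes, for
#' every drug, the probabilities of its known therapeutic properties, so
#' that what remains quantifies *repositioning* potential only.
#'
#' @param p drugs x q probability matrix with drug row names and class
#'   column names.
#' @param labels named list, drug -> known label letters; every drug in `p`
#'   must be present with at least one label.
#' @return An object of class `"dtnt"`: list with `p` (the zeroed matrix)
#'   and `labels`.
#' @export
build_dtn_t <- function(p, labels) {
  p <- as.matrix(p)
  if (is.null(rownames(p)) || is.null(colnames(p))) {
    stop("probability matrix must carry drug and class names")
  }
  missing <- setdiff(rownames(p), names(labels))
  if (length(missing)) {
    stop("drug(s) without labels: ", paste(missing, collapse = ", "))
  }
  validate_labels(labels[rownames(p)], colnames(p))
  for (d in rownames(p)) {
    p[d, labels[[d]]] <- 0
  }
  structure(list(p = p, labels = labels[rownames(p)]), class = "dtnt")
}

#' @export
print.dtnt <- function(x, ...) {
  cat(sprintf("DTN-T: %d drugs x %d therapeutic properties (known labels zeroed)\n",
              nrow(x$p), ncol(x$p)))
  invisible(x)
}

#' Prune DTN-T into a binary edge matrix
#'
#' A drug has a repositioning edge to a property when its DTN-T probability
#' reaches the threshold (closed rule, `>=`), so pruning is monotone: the
#' edge set at a higher threshold is a subset of the edge set at a lower
#' one.
#'
#' @param dtnt a [build_dtn_t()] object.
#' @param threshold probability cut-off in [0, 1].
#' @return drugs x q binary edge matrix.
#' @export
prune_dtn <- function(dtnt, threshold) {
  stopifnot(inherits(dtnt, "dtnt"), threshold >= 0, threshold <= 1)
  (dtnt$p >= threshold) * 1L
}

#' Enrichment ratio of property X repositioning to property Y
#'
#' ER_{X,Y} = (a/b) / (c/d) where, over the pruned edge matrix,
#' a = drugs with label X having an edge to Y, b = drugs with any label
#' having an edge to Y, c = drugs with label X having at least one edge,
#' and d = drugs with at least one edge. ER > 1 means drugs of property X
#' are over-represented among those repositioned into Y. An undefined
#' ratio (b = 0 or c = 0) is reported as 0 with `degenerate = TRUE`.
#'
#' @param edges drugs x q binary edge matrix (from [prune_dtn()]).
#' @param labels named list, drug -> known label letters.
#' @param x,y property letters, `x != y`.
#' @return List with `er`, the counts `a`, `b`, `c`, `d`, and `degenerate`.
#' @export
enrichment_ratio <- function(edges, labels, x, y) {
  stopifnot(x != y)
  edges <- as.matrix(edges)
  drugs <- rownames(edges)
  has_x <- vapply(drugs, function(d) x %in% labels[[d]], NA)
  edge_to_y <- edges[, y] > 0
  any_edge <- rowSums(edges) > 0
  a <- sum(has_x & edge_to_y)
  b <- sum(edge_to_y)
  c_ <- sum(has_x & any_edge)
  d <- sum(any_edge)
  degenerate <- b == 0 || c_ == 0
  er <- if (degenerate) 0 else (a / b) / (c_ / d)
  list(er = er, a = a, b = b, c = c_, d = d, degenerate = degenerate)
}

#' Full enrichment-ratio matrix at one threshold
#'
#' [enrichment_ratio()] for every ordered property pair of a pruned DTN-T.
#' The diagonal is structurally missing (a drug's known labels are zeroed,
#' so X -> X has no support) and stored as `NA`.
#'
#' @param dtnt a [build_dtn_t()] object.
#' @param threshold probability cut-off passed to [prune_dtn()].
#' @return q x q matrix of enrichment ratios with `NA` diagonal; the count
#'   and degeneracy arrays are attached as attributes `"counts"` (q x q x 4)
#'   and `"degenerate"`.
#' @export
er_matrix <- function(dtnt, threshold) {
  edges <- prune_dtn(dtnt, threshold)
  cls <- colnames(edges)
  q <- length(cls)
  er <- matrix(NA_real_, q, q, dimnames = list(from = cls, to = cls))
  counts <- array(0L, c(q, q, 4L), dimnames = list(cls, cls, c("a", "b", "c", "d")))
  degen <- matrix(FALSE, q, q, dimnames = list(cls, cls))
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) next
      r <- enrichment_ratio(edges, dtnt$labels, cls[[i]], cls[[j]])
      er[i, j] <- r$er
      counts[i, j, ] <- c(r$a, r$b, r$c, r$d)
      degen[i, j] <- r$degenerate
    }
  }
  attr(er, "counts") <- counts
  attr(er, "degenerate") <- degen
  attr(er, "threshold") <- threshold
  er
}

# Off-diagonal cells of an ER matrix as a vector, for correlations.
er_offdiag <- function(er) er[row(er) != col(er)]

#' Threshold stability of the enrichment-ratio matrix
#'
#' Computes the ER matrix at every threshold of the grid and the Pearson
#' correlation between every pair of ER matrices over their off-diagonal
#' cells finite in both (the diagonal is structurally missing). High
#' correlation across a threshold range shows the ER pattern is not an
#' artifact of a particular pruning cut-off.
#'
#' @param dtnt a [build_dtn_t()] object.
#' @param thresholds threshold grid; default 0.20 to 0.95 in steps of 0.05.
#' @return grid x grid symmetric correlation matrix (dimnames are the
#'   thresholds); pairs with fewer than 3 common finite cells are `NA`. The
#'   per-threshold ER matrices are attached as attribute `"er_matrices"`.
#' @export
er_threshold_stability <- function(dtnt, thresholds = seq(0.20, 0.95, by = 0.05)) {
  stopifnot(length(thresholds) >= 2L, all(thresholds >= 0 & thresholds <= 1))
  ers <- lapply(thresholds, function(t) er_matrix(dtnt, t))
  names(ers) <- format(thresholds)
  n <- length(thresholds)
  rho <- matrix(NA_real_, n, n, dimnames = list(names(ers), names(ers)))
  vecs <- lapply(ers, er_offdiag)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- is.finite(vecs[[i]]) & is.finite(vecs[[j]])
      if (sum(ok) >= 3L) {
        v1 <- vecs[[i]][ok]; v2 <- vecs[[j]][ok]
        r <- if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
          if (i == j) 1 else NA_real_
        } else {
          stats::cor(v1, v2)
        }
        rho[i, j] <- rho[j, i] <- r
      }
    }
  }
  attr(rho, "er_matrices") <- ers
  rho
}

#' Combined enrichment-ratio matrix over the top thresholds
#'
#' Averages the ER matrices of the highest (most stable) pruning
#' thresholds cellwise: by default the six thresholds 0.70--0.95, whose ER
#' matrices are mutually highly correlated. Cells missing at some
#' thresholds are excluded from that cell's mean; all-missing cells stay
#' missing.
#'
#' @param dtnt a [build_dtn_t()] object.
#' @param thresholds thresholds to combine (default `seq(0.70, 0.95, 0.05)`).
#' @return q x q combined ER matrix with `NA` diagonal.
#' @export
combined_er <- function(dtnt, thresholds = seq(0.70, 0.95, by = 0.05)) {
  ers <- lapply(thresholds, function(t) er_matrix(dtnt, t))
  stack <- array(unlist(ers), dim = c(dim(ers[[1L]]), length(ers)))
  out <- apply(stack, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  dimnames(out) <- dimnames(ers[[1L]])
  out
}

#' Top enrichment-ratio pairs
#'
#' The k largest finite cells of an ER matrix, in descending order with a
#' deterministic lexicographic (from, then to) tie-break.
#'
#' @param er q x q ER matrix.
#' @param k number of pairs to return (capped at the number of finite
#'   cells).
#' @return Data frame with columns `from`, `to`, `er`.
#' @export
top_er_pairs <- function(er, k = 5L) {
  stopifnot(k >= 1L)
  cls_from <- rownames(er)
  cls_to <- colnames(er)
  idx <- which(is.finite(er), arr.ind = TRUE)
  df <- data.frame(
    from = cls_from[idx[, 1L]],
    to = cls_to[idx[, 2L]],
    er = er[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$er, df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}
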