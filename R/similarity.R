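#' Jaccard coefficient of two item sets
#'
#' |A ∩ B| / |A ∪ B|, the similarity measure used for side-effect profiles.
#' Two empty sets are defined to have similarity 1 (two drugs with no
#' recorded side effects are indistinguishable on this feature).
#'
#' @param a,b vectors treated as sets (duplicates ignored).
#' @return Value in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Tanimoto coefficient of two item sets
#'
#' |A ∩ B| / (|A| + |B| - |A ∩ B|), the similarity measure used for
#' fingerprint bit sets. On sets this coincides with the Jaccard
#' coefficient; the empty-empty case is likewise defined as 1.
#'
#' @inheritParams jaccard
#' @return Value in [0, 1].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Pairwise drug similarity network
#'
#' Applies a set-similarity metric to every pair of drugs' feature sets
#' (side-effect terms or fingerprint bits).
#'
#' @param sets named list, drug -> vector of item ids.
#' @param metric `"jaccard"` or `"tanimoto"`.
#' @return Symmetric drugs x drugs matrix with unit diagonal and entries
#'   in [0, 1].
#' @export
similarity_network <- function(sets, metric = c("jaccard", "tanimoto")) {
  metric <- match.arg(metric)
  f <- if (metric == "jaccard") jaccard else tanimoto
  drugs <- names(sets)
  n <- length(drugs)
  s <- matrix(1, n, n, dimnames = list(drugs, drugs))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s[i, j] <- s[j, i] <- f(sets[[i]], sets[[j]])
      }
    }
  }
  s
}

#' Node-to-community coefficients
#'
#' Projects a drug similarity network onto the (overlapping) ATC
#' communities: the coefficient of drug d for community C is the mean
#' similarity between d and the members of C, excluding d itself. A
#' community with no other member scores 0.
#'
#' @param similarity symmetric drugs x drugs similarity matrix.
#' @param partition named list, community (class letter) -> drug ids; all
#'   partition drugs must appear in `similarity`.
#' @return drugs x communities matrix of coefficients in [0, 1] (the
#'   DTN-SE / DTN-ST projection).
#' @export
node_to_community <- function(similarity, partition) {
  drugs <- rownames(similarity)
  stopifnot(!is.null(drugs), all(unlist(partition) %in% drugs))
  out <- matrix(0, length(drugs), length(partition),
                dimnames = list(drugs, names(partition)))
  for (cl in names(partition)) {
    members <- partition[[cl]]
    for (d in drugs) {
      others <- setdiff(members, d)
      if (length(others)) {
        out[d, cl] <- mean(similarity[d, others])
      }
    }
  }
  out
}

#' Per-drug Spearman correlation across two drug--property networks
#'
#' For every shared drug, the Spearman rank correlation (average ranks on
#' ties) between its q-dimensional DTN-T repositioning row and its
#' q-dimensional similarity-projection row (DTN-SE or DTN-ST). A drug whose
#' row is constant in either network has no defined rank correlation and
#' gets `NA`.
#'
#' @param dtnt a [build_dtn_t()] object (or a bare drugs x q matrix).
#' @param projection drugs x q coefficient matrix from
#'   [node_to_community()].
#' @return Named numeric vector of correlations, one per shared drug.
#' @export
cross_network_spearman <- function(dtnt, projection) {
  p <- if (inherits(dtnt, "dtnt")) dtnt$p else as.matrix(dtnt)
  shared <- intersect(rownames(p), rownames(projection))
  cls <- intersect(colnames(p), colnames(projection))
  stopifnot(length(shared) > 0L, length(cls) >= 2L)
  vapply(shared, function(d) {
    u <- p[d, cls]
    v <- projection[d, cls]
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(u, v, method = "spearman")
  }, 0)
}
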