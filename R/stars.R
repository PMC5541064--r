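#' Find star drugs in a DTN-T
#'
#' A "star drug" call is a (drug, property) pair whose repositioning
#' probability strictly exceeds the star threshold; since known labels are
#' zeroed in DTN-T, every call is for a *novel* therapeutic property. The
#' default threshold 0.9 marks high-confidence repositioning.
#'
#' @param dtnt a [build_dtn_t()] object.
#' @param star_threshold probability cut-off in (0, 1]; strictly-greater
#'   comparison.
#' @return Data frame with columns `drug`, `property`, `probability`,
#'   sorted by decreasing probability (ties broken by drug then property).
#' @export
find_stars <- function(dtnt, star_threshold = 0.9) {
  stopifnot(inherits(dtnt, "dtnt"), star_threshold > 0, star_threshold <= 1)
  idx <- which(dtnt$p > star_threshold, arr.ind = TRUE)
  calls <- data.frame(
    drug = rownames(dtnt$p)[idx[, 1L]],
    property = colnames(dtnt$p)[idx[, 2L]],
    probability = dtnt$p[idx],
    stringsAsFactors = FALSE
  )
  calls <- calls[order(-calls$probability, calls$drug, calls$property), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Probability-1 star subset (SD1)
#'
#' Star drugs with at least one call at probability 1 (tested within 1e-9,
#' since the probabilities are iteration averages of floats).
#'
#' @param star_calls data frame from [find_stars()].
#' @return Character vector of drug ids.
#' @export
sd1 <- function(star_calls) {
  sort(unique(star_calls$drug[star_calls$probability >= 1 - 1e-9]))
}

#' Correlation-supported star subsets (SD2 / SD3)
#'
#' Star drugs whose cross-network Spearman correlation (against DTN-SE for
#' SD2, DTN-ST for SD3) strictly exceeds the threshold: their
#' transcriptional repositioning profile is echoed by side-effect or
#' structural similarity.
#'
#' @param star_calls data frame from [find_stars()].
#' @param rho named vector from [cross_network_spearman()].
#' @param rho_threshold correlation cut-off (default 0.4); strictly-greater
#'   comparison.
#' @return Character vector of drug ids. Star drugs absent from `rho` are
#'   excluded with a warning.
#' @export
sd_by_correlation <- function(star_calls, rho, rho_threshold = 0.4) {
  stars <- unique(star_calls$drug)
  missing <- setdiff(stars, names(rho))
  if (length(missing)) {
    warning("star drug(s) without a correlation value: ",
            paste(missing, collapse = ", "))
  }
  present <- intersect(stars, names(rho))
  sort(present[!is.na(rho[present]) & rho[present] > rho_threshold])
}

#' Combined credible star-drug set
#'
#' Union of SD1 (probability-1 calls), SD2 (side-effect supported) and SD3
#' (structure supported), with per-drug support annotation; drugs with two
#' or more supports are the most convincing repositioning candidates.
#'
#' @param sd1,sd2,sd3 character vectors of drug ids.
#' @return Data frame with columns `drug`, `supports` (semicolon-joined
#'   subset of `SD1;SD2;SD3`) and `n_supports`.
#' @export
credible_star_set <- function(sd1, sd2, sd3) {
  drugs <- sort(unique(c(sd1, sd2, sd3)))
  supports <- vapply(drugs, function(d) {
    paste(c("SD1", "SD2", "SD3")[c(d %in% sd1, d %in% sd2, d %in% sd3)],
          collapse = ";")
  }, "")
  data.frame(
    drug = drugs,
    supports = unname(supports),
    n_supports = (drugs %in% sd1) + (drugs %in% sd2) + (drugs %in% sd3),
    stringsAsFactors = FALSE
  )
}

#' Score star calls against planted ground truth
#'
#' Precision and recall of (drug, property) star calls against the planted
#' (drug, latent class) truth of a synthetic cohort.
#'
#' @param star_calls data frame from [find_stars()].
#' @param truth data frame with columns `drug` and `latent_class`.
#' @return List with `precision`, `recall`, `n_calls`, `n_truth`.
#' @export
score_star_calls <- function(star_calls, truth) {
  calls <- paste(star_calls$drug, star_calls$property)
  truths <- paste(truth$drug, truth$latent_class)
  tp <- sum(calls %in% truths)
  list(
    precision = if (length(calls)) tp / length(calls) else NA_real_,
    recall = if (length(truths)) tp / length(truths) else NA_real_,
    n_calls = length(calls),
    n_truth = length(truths)
  )
}

#' Tune the star threshold on a cohort with known truth
#'
#' Chooses, over a grid, the star threshold maximising the F1 score of the
#' star calls against planted truth (ties resolved towards the larger,
#' more conservative threshold). Intended to be run on a held-out tuning
#' cohort, with the chosen threshold then applied unchanged to evaluation
#' cohorts.
#'
#' @param dtnt a [build_dtn_t()] object for the tuning cohort.
#' @param truth planted-truth data frame of the tuning cohort.
#' @param grid candidate thresholds.
#' @return The selected threshold (scalar).
#' @export
tune_star_threshold <- function(dtnt, truth, grid = seq(0.05, 0.95, by = 0.05)) {
  f1 <- vapply(grid, function(t) {
    s <- score_star_calls(find_stars(dtnt, t), truth)
    if (is.na(s$precision) || s$precision + s$recall == 0) return(0)
    2 * s$precision * s$recall / (s$precision + s$recall)
  }, 0)
  best <- max(f1)
  grid[max(which(f1 == best))]
}
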