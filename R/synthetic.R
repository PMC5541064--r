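#' Synthetic cohort specification
#'
#' Collects the generative parameters for an L1000-like drug-perturbation
#' cohort with known ground truth. The defaults emulate the scale and signal
#' regime of Level-4 landmark-gene data: 978 genes measured as Z-scores
#' (unit residual noise), a few to ~17 replicate trials per drug, 14
#' first-level ATC classes with a quarter of drugs carrying two labels, and
#' a class-specific transcriptional signature touching 10% of the genes at
#' one Z-score unit. A `planted_fraction` of drugs additionally receives the
#' expression signature of a latent class that is withheld from the label
#' table — the ground truth that repositioning should recover.
#'
#' @param n_drugs number of drugs in the cohort.
#' @param n_genes number of landmark genes (features).
#' @param n_classes number of therapeutic classes (at most 26; the first 14
#'   use the ATC alphabet).
#' @param trials_per_drug integer range `c(min, max)` of replicate trials.
#' @param multilabel_fraction probability that a drug carries two labels.
#' @param signal per-class mean-shift magnitude, in Z-score units, applied
#'   (with a random sign per gene) to the class's signature genes.
#' @param signature_fraction fraction of genes in each class signature.
#' @param noise_sd residual standard deviation of a trial around its drug's
#'   mean profile.
#' @param planted_fraction fraction of drugs given a latent extra class.
#' @param sideeffect_pool,fingerprint_pool total item-pool sizes for the
#'   side-effect and fingerprint set generators.
#' @param within_class_share probability that a drug includes each item of
#'   its classes' characteristic blocks.
#' @param background_rate probability that a drug includes each background
#'   (class-neutral) pool item.
#' @return A validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_drugs = 480, n_genes = 978, n_classes = 14,
                           trials_per_drug = c(3L, 17L),
                           multilabel_fraction = 0.25,
                           signal = 1, signature_fraction = 0.1,
                           noise_sd = 1, planted_fraction = 0.1,
                           sideeffect_pool = 480, fingerprint_pool = 1024,
                           within_class_share = 0.6,
                           background_rate = 0.05) {
  spec <- list(
    n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
    n_classes = as.integer(n_classes),
    trials_per_drug = as.integer(trials_per_drug),
    multilabel_fraction = multilabel_fraction, signal = signal,
    signature_fraction = signature_fraction, noise_sd = noise_sd,
    planted_fraction = planted_fraction,
    sideeffect_pool = as.integer(sideeffect_pool),
    fingerprint_pool = as.integer(fingerprint_pool),
    within_class_share = within_class_share,
    background_rate = background_rate
  )
  if (spec$n_classes > 26L) stop("n_classes must be at most 26")
  if (spec$n_classes < 2L) stop("n_classes must be at least 2")
  if (length(spec$trials_per_drug) != 2L || spec$trials_per_drug[[1L]] < 1L ||
      diff(spec$trials_per_drug) < 0L) {
    stop("trials_per_drug must be an increasing range with minimum >= 1")
  }
  probs <- c(spec$multilabel_fraction, spec$planted_fraction,
             spec$within_class_share, spec$background_rate,
             spec$signature_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (spec$signal < 0) stop("signal must be non-negative")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  structure(spec, class = "synthetic_spec")
}

spec_classes <- function(spec) {
  if (spec$n_classes <= 14L) {
    atc_letters()[seq_len(spec$n_classes)]
  } else {
    LETTERS[seq_len(spec$n_classes)]
  }
}

#' Generate a synthetic drug-perturbation cohort
#'
#' Each drug receives one (or, with probability `multilabel_fraction`, two)
#' therapeutic labels and a mean expression profile equal to the sum of its
#' classes' signature shifts; a `planted_fraction` of drugs also adds the
#' signature of one latent class that is absent from the label table.
#' Replicate trials are the drug mean plus independent Gaussian noise.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(spec, seed)`.
#' @return A list of class `"tx_cohort"` with elements `expression` (an
#'   [expression_table()]), `labels` (drug -> ATC letters, latent classes
#'   excluded), `truth` (data frame of planted `drug`, `latent_class`
#'   pairs), `classes`, and `signatures` (class -> signed gene-shift
#'   vectors, for diagnostics).
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- spec_classes(spec)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    drugs <- sprintf("drug%03d", seq_len(spec$n_drugs))
    n_sig <- max(1L, round(spec$signature_fraction * spec$n_genes))
    signatures <- lapply(classes, function(cl) {
      v <- numeric(spec$n_genes)
      idx <- sample.int(spec$n_genes, n_sig)
      v[idx] <- spec$signal * sample(c(-1, 1), n_sig, replace = TRUE)
      v
    })
    names(signatures) <- classes

    labels <- vector("list", spec$n_drugs)
    names(labels) <- drugs
    for (d in seq_len(spec$n_drugs)) {
      k <- 1L + (stats::runif(1) < spec$multilabel_fraction)
      labels[[d]] <- sort(sample(classes, k))
    }

    n_planted <- round(spec$planted_fraction * spec$n_drugs)
    planted_drugs <- if (n_planted > 0L) sort(sample(drugs, n_planted)) else character()
    latent <- vapply(planted_drugs, function(d) {
      sample(setdiff(classes, labels[[d]]), 1L)
    }, "")
    truth <- data.frame(drug = planted_drugs, latent_class = unname(latent),
                        stringsAsFactors = FALSE)

    t_per_drug <- sample(seq(spec$trials_per_drug[[1L]],
                             spec$trials_per_drug[[2L]]),
                         spec$n_drugs, replace = TRUE)
    total <- sum(t_per_drug)
    values <- matrix(stats::rnorm(total * spec$n_genes, sd = spec$noise_sd),
                     nrow = total, ncol = spec$n_genes)
    sample_ids <- character(total)
    drug_of <- character(total)
    row <- 0L
    for (d in seq_len(spec$n_drugs)) {
      mu <- Reduce(`+`, signatures[labels[[d]]])
      if (drugs[[d]] %in% planted_drugs) {
        mu <- mu + signatures[[latent[[drugs[[d]]]]]]
      }
      for (t in seq_len(t_per_drug[[d]])) {
        row <- row + 1L
        values[row, ] <- values[row, ] + mu
        sample_ids[[row]] <- sprintf("%s_t%02d", drugs[[d]], t)
        drug_of[[row]] <- drugs[[d]]
      }
    }
    dimnames(values) <- list(sample_ids, genes)
    structure(
      list(
        expression = expression_table(values, stats::setNames(drug_of, sample_ids)),
        labels = labels,
        truth = truth,
        classes = classes,
        signatures = signatures
      ),
      class = "tx_cohort"
    )
  })
}

#' @export
print.tx_cohort <- function(x, ...) {
  cat(sprintf(
    "tx_cohort: %d drugs, %d trials x %d genes, %d classes, %d planted latent labels\n",
    length(x$labels), nrow(x$expression$values), ncol(x$expression$values),
    length(x$classes), nrow(x$truth)
  ))
  invisible(x)
}

# Shared machinery for the two label-correlated feature-set generators:
# the item pool is split into disjoint per-class characteristic blocks
# (half of the pool) plus a class-neutral background.
generate_feature_sets <- function(labels, spec, pool_size, prefix,
                                  truth = NULL, seed = 1L) {
  classes <- spec_classes(spec)
  items <- sprintf("%s%04d", prefix, seq_len(pool_size))
  block_size <- floor(pool_size / (2L * spec$n_classes))
  blocks <- stats::setNames(lapply(seq_along(classes), function(i) {
    items[(i - 1L) * block_size + seq_len(block_size)]
  }), classes)
  background <- items[-seq_len(block_size * spec$n_classes)]
  latent <- if (!is.null(truth) && nrow(truth)) {
    stats::setNames(truth$latent_class, truth$drug)
  } else {
    character()
  }
  with_seed(seed, {
    sets <- lapply(names(labels), function(d) {
      cls <- labels[[d]]
      if (d %in% names(latent)) cls <- union(cls, latent[[d]])
      own <- unlist(blocks[cls], use.names = FALSE)
      keep <- own[stats::runif(length(own)) < spec$within_class_share]
      bg <- background[stats::runif(length(background)) < spec$background_rate]
      sort(unique(c(keep, bg)))
    })
    names(sets) <- names(labels)
    attr(sets, "blocks") <- blocks
    sets
  })
}

#' Generate label-correlated side-effect sets
#'
#' Emulates SIDER-style drug--side-effect annotations: each therapeutic
#' class has a characteristic block of side-effect terms; a drug includes
#' each term of its classes' blocks with probability `within_class_share`,
#' plus background terms at `background_rate`. Drugs with a planted latent
#' class also draw from that class's block, so side-effect similarity
#' carries the repositioning signal.
#'
#' @param labels named list, drug -> label letters (as in a `"tx_cohort"`).
#' @param spec a [synthetic_spec()].
#' @param truth optional data frame of planted `(drug, latent_class)` pairs.
#' @param seed integer seed.
#' @return Named list, drug -> character vector of item ids; the per-class
#'   blocks are attached as attribute `"blocks"`.
#' @export
generate_side_effect_sets <- function(labels, spec = synthetic_spec(),
                                      truth = NULL, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  generate_feature_sets(labels, spec, spec$sideeffect_pool, "se", truth, seed)
}

#' Generate label-correlated fingerprint bit sets
#'
#' Stand-in for atom-pair structural fingerprints, built identically to
#' [generate_side_effect_sets()] but from its own bit pool: structurally
#' similar (same-class) drugs share characteristic bits.
#'
#' @inheritParams generate_side_effect_sets
#' @return Named list, drug -> character vector of bit ids.
#' @export
generate_fingerprints <- function(labels, spec = synthetic_spec(),
                                  truth = NULL, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  generate_feature_sets(labels, spec, spec$fingerprint_pool, "fp", truth, seed)
}
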