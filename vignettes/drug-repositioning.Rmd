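---
title: "Repositioning drugs from landmark-gene responses: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repositioning drugs from landmark-gene responses: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`txrepo` casts drug repositioning as multi-label classification of
perturbation transcriptomes. This vignette is the package's account of the
model, its assumptions, the parameters that matter, and the design
decisions taken where more than one reading was defensible. The README
shows the code; here we explain why it is built the way it is.

## The model and its assumptions

A cohort consists of drugs, each observed in several perturbation *trials*:
Z-score vectors over the 978 L1000 landmark genes (Level-4-style data, one
cell line). First-level ATC codes provide up to 14 therapeutic labels per
drug. The working assumptions are:

1. **Signal is class-shared.** Drugs of one therapeutic class perturb a
   common set of genes, so a linear classifier on landmark Z-scores can
   represent a class as a direction in expression space.
2. **Replicates are noisy copies.** Trials of one drug differ by assay
   noise (and occasionally by outright failure), not by systematic
   condition effects — dose and time are collapsed.
3. **Misclassification is information.** When the trained classifier
   assigns substantial probability to a class a drug does not carry, and
   that class assignment is echoed by side-effect or structural
   similarity, the drug is a repositioning candidate rather than an error.

### Replicate aggregation: the credible set

For each drug we compute the trial–trial Pearson correlation matrix, split
the trials into k-means groups, and keep the group with the maximum mean
intra-group correlation (S1); the mean over *all* trials is appended as one
more sample (S2). Design points:

- **k defaults to 2** — the smallest split that can reject outlier trials;
  it is configurable (`kmeans_k`). The k-means runs on the raw Z-score
  vectors with Euclidean distance and 10 seeded restarts.
- **Singleton groups score worst**: mean pairwise correlation needs two
  members. When no two-member group can exist (fewer than k + 1 trials, or
  all trials identical) every trial is returned — with two trials there is
  no basis for calling either one the outlier.
- **S2 averages all trials, not just S1's.** Averaging everything retains
  information from the rejected trials at 1/t weight.
- **Zero-variance trials** get correlation 0 rather than being dropped, so
  trial indices stay stable for downstream bookkeeping.

### The classifier

Softmax regression with a q × (n+1) parameter matrix θ (bias unit last):

$$P(y=j \mid x) = \frac{e^{\theta_j^\top x}}{\sum_{l=1}^{q} e^{\theta_l^\top x}}$$

- **Multi-label targets are row-normalised**: a sample with labels
  {C, N} targets (…, ½, …, ½, …). This keeps the target a probability
  distribution, which is what the cross-entropy objective needs, and lets
  one softmax express label competition instead of training q independent
  binary classifiers.
- **Objective**: mean cross-entropy plus λ·‖θ‖² over the non-bias weights.
  λ defaults to 1. That is a deliberately strong penalty: on cohorts with
  hundreds of samples and a ~100-gene class signature it keeps per-weight
  magnitudes small while class logits (sums over the signature genes)
  remain well separated. A weakly regularised fit behaves very differently
  — it memorises each drug's labels, drives the training loss to zero, and
  in doing so *suppresses* exactly the off-label probability mass that
  repositioning mines. Regularisation here is not just overfitting
  hygiene; it is what makes the probability matrix interpretable.
- **Optimisation**: mini-batch gradient descent, learning rate 0.06, batch
  32, one *iteration* = one epoch of seeded shuffled mini-batches (this is
  the reading under which "at least 200 iterations" and "average the last
  100 iterations" are well defined). θ starts at zero: the objective is
  convex, so initialisation affects only the trajectory, and zeros make
  runs reproducible without seed-dependence in θ₀. Training aborts with
  diagnostics if the loss becomes non-finite.
- **Thresholds**: a sample is *correct* when at least one true label is
  called. Training accuracy uses the 0.30 cut-off; validation accuracy the
  laxer 0.06 (just below the uniform probability 1/14 ≈ 0.071), each on
  its side of the drug-level folds. These are the two cut-offs of the
  model family's learning-curve optimum, kept as defaults.
- **Cross-validation splits drugs, not samples.** Replicates of one drug
  are near-duplicates; splitting them across folds would leak training
  data into validation.
- **The probability matrix is pre-threshold.** The full-data probability
  matrices of the final 100 epochs are averaged elementwise (smoothing
  mini-batch jitter), then averaged within each drug over its credible-set
  samples. Rows stay stochastic; values are continuous probabilities, not
  binary calls.

### Networks and candidate calling

Zeroing every drug's known labels in the drug-level probability matrix
gives **DTN-T**. Downstream choices:

- **Edge rule is closed (`>=`)** when pruning DTN-T at a threshold, so a
  probability of exactly 1.0 still forms an edge at threshold 1.0.
- **Enrichment ratio** ER\_{X,Y} = (a/b)/(c/d) with a = X-labelled drugs
  with an edge to Y, b = any drug with an edge to Y, c = X-labelled drugs
  with any edge, d = drugs with any edge. The diagonal is structurally
  missing (own labels are zeroed) and stored as `NA`. A zero denominator
  (no drugs repositioned into Y at all, or no X drug with any edge) yields
  ER = 0 with a degeneracy flag — keeping matrices finite for the
  stability correlations while preserving the distinction for audit.
- **Threshold stability** uses the grid 0.20–0.95 in steps of 0.05 (16
  values): the only uniform grid in which the top range 0.70–0.95
  contains exactly the six matrices that are combined by averaging.
  Correlations between ER matrices use off-diagonal cells finite in both.
- **Node-to-community coefficient**: the mean similarity between a drug
  and the members of an ATC community, excluding the drug itself —
  the simplest graph-to-community projection; a community with no other
  member scores 0. Whether to include the drug itself when it belongs to
  the community was open; self-exclusion avoids every drug trivially
  scoring 1 on its own communities.
- **Tanimoto** is implemented in its standard set form
  |A∩B|/(|A|+|B|−|A∩B|), which on sets coincides with Jaccard (a fact the
  tests exploit as a cross-check); both define the empty–empty case as 1.
- **Per-drug Spearman** between a drug's 14-dim DTN-T row and its 14-dim
  projection row uses average ranks on ties and all 14 components,
  including the zeroed known labels (no exclusion rule is obviously
  right; this is the simplest and is applied uniformly). A constant row
  has no rank correlation and yields `NA`.
- **Star calls use strict `>`** for both the probability threshold (0.9)
  and the correlation threshold (0.4), matching "more than" / "exceeded"
  semantics; probability-1 membership (SD1) is tested within 1e-9 because
  the probabilities are averages of floats.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage can be tested
against known ground truth. Its defaults are the study conditions and are
not tuned per test:

| parameter | default | rationale |
|---|---|---|
| `n_drugs` | 480 | cohort size of a one-cell-line FDA-approved-drug panel |
| `n_genes` | 978 | the landmark gene set |
| `n_classes` | 14 | first-level ATC |
| `trials_per_drug` | 3–17 | ≈10 on average, matching ~4800 trials for 480 drugs |
| `multilabel_fraction` | 0.25 | a quarter of approved drugs carry a second first-level code |
| `signal` | 1 Z-unit | a modest, realistic consensus perturbation amplitude |
| `signature_fraction` | 0.10 | a class touches ~100 of 978 landmark genes |
| `noise_sd` | 1 | Level-4 Z-scores have unit residual scale |
| `planted_fraction` | 0.10 | latent extra classes to recover |
| `within_class_share` | 0.6 | a drug shows most, not all, of its class's side effects/bits |
| `background_rate` | 0.05 | class-neutral annotation noise |

Each class's signature is an additive mean shift (random sign per gene) on
a random 10% gene subset; multi-label drugs sum their shifts, and planted
drugs add the signature of a latent class withheld from the label table.
Side-effect and fingerprint sets draw from disjoint per-class item blocks
(half the pool) plus background; planted drugs draw from their latent
class's block too, so similarity networks carry the repositioning echo.
All randomness flows from one seed per sub-generator, restoring the
caller's RNG state afterwards.

What the generator does **not** emulate: gene–gene correlation structure,
dose/time covariates, heavy-tailed L1000 noise, class imbalance as extreme
as real ATC frequencies, or drugs whose own-label signature is absent.
Because every planted drug keeps its full own-label signal, the latent
class must compete with it inside one softmax — synthetic repositioning
probabilities therefore top out around 0.2–0.4 rather than the ≈1.0 seen
for real star drugs, and recovery runs tune the calling threshold on a
held-out cohort (`tune_star_threshold()`, F1-optimal, ties towards the
conservative side) instead of using the real-data 0.9. Consequently,
passing recovery tests demonstrates that the chain detects planted
off-label signal with high precision under these idealised conditions; it
does not certify calibrated probabilities on real data.

## Numerical choices

- Softmax uses max-logit subtraction; log-probabilities are floored at
  1e-300 (warning when the floor binds). Non-finite logits or losses abort
  with diagnostics rather than propagating `NaN`.
- GCT values are written with 17 significant digits so a write/read cycle
  is value-identical; analysis TSVs print 6 decimals for a diffable,
  deterministic acceptance surface.
- Ties in `top_er_pairs()` break lexicographically (from, then to); the
  tuned star threshold breaks F1 ties towards the larger threshold.
- Degenerate inputs: single-trial drugs yield a two-row credible set
  (trial + its mean); a drug labelled with every class has an all-zero
  DTN-T row; empty feature sets are similar to each other (similarity 1)
  by the empty-set convention.

## Problem sizes in the tests and acceptance run

Unit and property tests run on 10–60-drug cohorts with 120–300 genes,
where structural contracts (shapes, determinism, monotonicity, oracles) do
not depend on scale. Recovery checks use the full 978-gene feature space
with 200-drug cohorts — the smallest size at which the study regime (λ = 1,
~80% training accuracy, clean planted-class separation) is reproduced — with
three evaluation seeds and one held-out tuning seed. These sizes are the
package's validation design; `synthetic_spec()` scales to the full 480-drug
cohort unchanged.

## Known limitations

- The classifier is linear in the landmark Z-scores; strongly non-linear
  class structure is out of reach by construction.
- ER values on sparse edge sets are unstable (small denominators); the
  degeneracy flags and the threshold-stability screen are the guardrails,
  and no significance test is attached to ER.
- The side-effect and fingerprint inputs are consumed as given sets;
  computing fingerprints from structures, and retrieving any external
  database, are out of scope.
- Validation accuracy at the 0.06 threshold is a lenient criterion
  (uniform probabilities already exceed it); it measures that probability
  mass has not been driven *away* from true labels, not sharp top-1
  performance — the confusion matrix and training-threshold accuracy are
  the sharper instruments.
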