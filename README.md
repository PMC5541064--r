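# txrepo

Drug repositioning from transcriptional responses by multi-label softmax
regression.

## The problem

A drug's transcriptional response — the Z-scored expression change of the
978 LINCS L1000 landmark genes after a cell line is perturbed with the
compound — carries information about *all* of its pharmacology, not only the
indication it was approved for. `txrepo` treats repositioning as a
multi-label classification task: perturbation trials are samples, the 978
landmark genes are features, and the 14 first-level ATC codes (A, B, C, D,
G, H, J, L, M, N, P, R, S, V) are the labels. A drug that a well-trained
classifier insists on assigning to a therapeutic class it does *not* carry
is a repositioning candidate.

The package is aimed at computational pharmacologists who want the whole
chain — replicate aggregation, classifier, network statistics, candidate
calling — as tested, seedable R functions, with a synthetic cohort
generator providing ground truth for validation.

## The method

**Replicate aggregation.** For each drug the replicate trials are grouped by
k-means on the raw Z-score vectors; the group with the maximum mean
intra-group Pearson correlation is kept (S1) and the mean over all trials is
appended as one more sample (S2). S = S1 ∪ {S2} is the drug's *credible set*
of training samples.

**Classifier.** Softmax regression with parameter matrix θ (q × (n+1), bias
included): P(y = j | x) = exp(θⱼᵀx) / Σₗ exp(θₗᵀx). Multi-label targets are
row-normalised (a drug with labels {C, N} targets ½ on each), and the fit
minimises the regularised cross-entropy

    R(θ) = −(1/m) Σᵢ Σⱼ Yᵢⱼ ln pᵢⱼ + λ ‖θ_non-bias‖²

by mini-batch gradient descent (defaults: learning rate 0.06, λ = 1, batch
32, ≥200 epochs). A sample counts as correctly predicted when at least one
of its true labels is called at the operative probability threshold (0.30
on training folds, 0.06 on drug-level validation folds). The full-data
probability matrices of the last 100 epochs are averaged, then averaged
within each drug, giving one probability row per drug.

**Networks and candidates.** Zeroing each drug's known labels yields DTN-T,
the drug–therapeutic-property network. Pruned at a threshold t, the
enrichment ratio ER_{X,Y} = (a/b)/(c/d) measures how over-represented
X-labelled drugs are among those repositioned into Y; ER matrices are
screened for threshold stability (Pearson across a 0.20–0.95 grid) and the
six most stable high thresholds are averaged. Side-effect (Jaccard) and
structural fingerprint (Tanimoto) similarity networks are projected onto
the 14 ATC communities (mean similarity to community members, self
excluded) and compared with DTN-T per drug by Spearman correlation.
*Star drugs* are calls with probability strictly above 0.9; SD1 is the
probability-1 subset and SD2/SD3 are stars whose cross-network correlation
exceeds 0.4 against the side-effect/structure projections.

## Worked example

```r
library(txrepo)

spec   <- synthetic_spec(n_drugs = 80)          # 978 genes, 14 classes, planted latent labels
cohort <- generate_cohort(spec, seed = 42)
cohort
#> tx_cohort: 80 drugs, 879 trials x 978 genes, 14 classes, 8 planted latent labels

cs  <- credible_expression(cohort$expression, seed = 43)
y   <- label_matrix(cohort$labels[cs$drugs], cohort$classes)
fit <- softmax_train(cs$values, y, seed = 44)
fit
#> Multi-label softmax regression classifier
#>   classes: 14 (A B C D G H J L M N P R S V)
#>   parameters: 14 x 979 (bias included)
#>   trained 200 iterations (lr 0.06, lambda 1, batch 32)
#>   final loss 2.5419, training accuracy 0.802 (threshold 0.30)

prob  <- averaged_probability_matrix(fit, cs$drugs)
dtnt  <- build_dtn_t(prob, cohort$labels)
calls <- find_stars(dtnt, star_threshold = 0.15)
head(calls)
#>      drug property probability
#> 1 drug020        P   0.2385710
#> 2 drug066        R   0.2330285
#> 3 drug038        J   0.2313557
#> ...
score_star_calls(calls, cohort$truth)
#> $precision [1] 1      $recall [1] 0.875    $n_calls [1] 7    $n_truth [1] 8
```

Seven of the eight drugs that were secretly given the expression signature
of an extra therapeutic class are called, with no false calls. (On synthetic
cohorts the repositioning probabilities are smaller than on real data —
the planted signal competes with a fully present own-label signature — so
the calling threshold is lower than the 0.9 used for real star drugs;
`tune_star_threshold()` picks it on a held-out cohort.)

`run_pipeline(pipeline_config(synthetic = spec), out_dir, seed)` runs the
same chain end to end and writes every artifact (GCT expression, credible
sets, probability matrix, DTN-T, ER/stability matrices, DTN-SE/DTN-ST,
per-drug correlations, star tables, JSON run log) as diffable text.

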