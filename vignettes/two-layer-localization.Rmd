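---
title: "A two-layer ensemble predictor of human protein subcellular localization"
author: "ProtSubLoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer ensemble predictor of human protein subcellular localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtSubLoc)
```

## The problem

A human protein may reside in one compartment or in several at once, and
its compartment(s) constrain its function. ProtSubLoc predicts, for each
query protein, a *set* of compartments out of six: cell membrane,
cytoplasm, endoplasmic reticulum/Golgi, mitochondrion, nucleus and
extracellular space. The strictness of the task is reflected in the
headline metric, the absolute true success rate (ATSR): a prediction
counts as correct only when the predicted set equals the true set exactly,
so both missing a compartment and inventing one score zero for that
protein.

## Model architecture

The predictor has two layers.

**Layer 1 — one-to-one.** Each compartment owns a small group of binary
soft-margin RBF SVMs (`r paste(c(5, 5, 5, 5, 7, 5), collapse = ", ")` per
compartment in code order; 32 in total). Within a group, every sub-model
shares the full positive set (proteins annotated to the compartment) while
the negatives — typically a large majority — are shuffled once and split
into disjoint near-equal chunks, one chunk per sub-model. This partition
has two properties worth stating:

* every negative protein is used by exactly one sub-model, so no negative
  information is discarded, and each sub-model sees a far less imbalanced
  problem than the full one-vs-rest split;
* the group size is odd (3–9), so a majority vote over the group can never
  tie.

All features are z-scored with training-set center and scale; the same
parameters are stored in the model and applied to queries. Without this
standardization the RBF kernel is dominated by the wide-range blocks and
the sub-models collapse toward majority-class behavior.

**Layer 2 — many-to-many.** The 32 signed decision values feed two
combiners:

* **Vote**: per compartment, the fraction of its own sub-models voting
  positive; the compartment enters the predicted set iff that fraction
  exceeds one half.
* **GANN**: a feed-forward network (32 inputs, 16 sigmoid hidden units, 6
  sigmoid outputs) whose weights are evolved by a genetic algorithm rather
  than gradient descent — population 500, blend (BLX-0.5) crossover at
  rate 0.7,
  weights bounded in [−25, 25], tournament selection of size 3, elitism of
  one, fitness the negative mean squared error against the 0/1 label
  matrix, stopping at MSE ≤ 0.05 or 1000 generations. A compartment enters
  the set when its activation reaches 0.5.

The *default* combiner renders the observation that the network is the
stronger singleplex predictor while voting handles multiplex proteins
better: since plexity is unknown at query time, the network's own set size
is the proxy — its set is used when it names exactly one compartment,
otherwise the vote set is used. Every combiner falls back to its
top-scoring compartment when thresholding yields an empty set, so a
prediction is never empty.

To keep the second layer honest, its training rows are *out-of-fold*
first-layer outputs: an internal stratified fold loop retrains the
sub-models and collects decision values only for held-out proteins, so no
network training row comes from sub-models that saw that protein. The
nested cross-validation protocol (`nestedCV()`) applies the same
discipline fold-wise and reports a leakage audit flag.

## Feature encoders and their parameters

Features are computed over four regions — the full sequence, the
N-terminal 30 residues, the centered middle third, and the C-terminal 50
residues — because targeting signals concentrate at sequence ends.

* **AAC** (80 values): residue frequencies per region.
* **Weighted sign aa index** (800 values): each region's composition is
  projected onto 100 physicochemical scales drawn at runtime from the
  `seqinr` AAindex catalogue (the first 100 complete scales, for
  determinism); each projection is encoded as its sign bit plus the base-10
  log of its magnitude, floored at 1e-6 so a vanishing projection stays
  finite. Sign and magnitude are interleaved per scale.
* **PC-PseAAC** (28 values): type-1 pseudo amino acid composition with
  λ = 8 correlation tiers and weight ω = 0.05 over three standardized
  properties (hydrophobicity, hydrophilicity, side-chain mass). At λ = 0
  it reduces exactly to AAC — a property the test suite checks.
* **Surface accessibility** (12 values, optional): per region, mean RSA,
  mean ASA scaled by 250 Å², and the fraction of exposed residues, from
  user-supplied per-residue profiles; missing profiles yield a flagged
  zero block instead of an error.
* **SSP** (optional): the full sequence block of the query's most similar
  reference protein (Smith–Waterman, BLOSUM62, gap open 11 / extend 1,
  minimum score 50; ties to the lexicographically smallest id; self
  fallback below threshold). At training time the query's own id is
  excluded so no protein borrows its own features. Off by default: the
  alignment pass is quadratic in the reference size.
* **GO terms** (35 binary values by default): candidate terms are ranked by
  greedy mRMR — relevance is the mean mutual information with the six
  one-vs-rest compartment indicators, redundancy the mean mutual
  information with already-selected terms (difference criterion), ties
  broken lexicographically so selection is order-invariant. Unannotated
  proteins may borrow the terms of their most similar annotated reference.

## The synthetic generator: realism and limits

Real curated localization data could not be shipped, so the package
includes a generator whose defaults mirror the statistical shape of the
curated human dataset the design assumes: sequences of 80–600 residues,
per-compartment prevalences proportional to the curated counts (1453,
1542, 562, 462, 2064, 795), and a 15% multiplex fraction for
training-style sets (44% reproduces the independent-test condition).
Compartment signal enters through residue usage: each compartment has five
signature residues (e.g. K/R/P/E/D for the nucleus, F/I/L/V/W for the
membrane) boosted in a Dirichlet-centered composition, and three
informative GO terms that fire with probability 0.9 for members. Simulated
surface accessibility links burial to Kyte–Doolittle hydropathy and uses
the Tien et al. maximum-ASA normalization.

The generator is deliberately simple: residues are i.i.d. given the
composition, so there are no motifs, no signal peptides, no domain
structure, and sequence similarity between unrelated proteins is near
chance. Consequences worth keeping in mind: the SSP block is uninformative
on synthetic data (and is off in the evaluation configuration), and
absolute accuracies on synthetic proteomes — especially at high
`profileStrength` — are not comparable to accuracies on curated real data.
What the synthetic runs do establish is that the pipeline recovers planted
signal end to end under a leakage-audited protocol.

## Numerical choices

* Mutual information uses empirical 2×2 counts with 0·log 0 = 0 and no
  pseudo-counts; natural log (selection only compares differences, so the
  base is immaterial).
* The weighted-sign log is base 10 with a 1e-6 floor; changing the base
  rescales one feature block uniformly and is absorbed by standardization.
* Feature standardization keeps constant columns at zero (scale forced to
  1) so the RBF kernel ignores them.
* SVM hyperparameters are the `e1071` defaults (cost 1, γ = 1/p) with the
  package's own standardization instead of `e1071`'s per-model scaling,
  so every sub-model sees the identical feature space.
* GA mutation: the published operating point fixes the mutation *rate* at
  0.3 but not the operator. Here 0.3 is the per-offspring probability;
  within a mutated offspring each gene is perturbed with probability 0.05
  by N(0, 2) noise and clipped to the bounds. Perturbing every gene at
  rate 0.3 directly was tested and degenerates into random search at this
  genome size (~630 weights), while the per-offspring reading converges to
  the 0.05 MSE target within about a hundred generations on a separable
  fixture.
* GA crossover: a per-gene blend (BLX-0.5) rather than a plain gene swap.
  Swapping genes only recombines values already present in the population,
  which stalls refinement around MSE ≈ 0.03 on the separable fixture;
  blending lets children interpolate and extrapolate parental weights, and
  the same fixture then converges below MSE 0.005 with near-perfect
  exact-set recovery.
* All stochastic steps (negative shuffles, fold splits, GA, generator)
  derive from explicit integer seeds; identical seeds give byte-identical
  outputs, which the test suite verifies at the file level.

## Open questions settled here

Decisions the published operating point leaves open, and how this
implementation fixes them: the GA operator details above; tournament size
3 and elitism 1; strict-majority voting with the highest-vote-fraction
fallback; the network-set-size proxy in the default combiner; leave-self-out
similarity at training time; lexicographic tie-breaks in both mRMR and
similarity search; and GO-candidate handling when a training fold has too
few usable terms (the GO block is dropped for that fold rather than padded).

## Running the protocol

```r
sim <- simulateProteome(generatorConfig(nProteins = 600, seed = 1))
cv <- nestedCV(sim$proteins, featureConfig(useSA = FALSE), folds = 5,
               seed = 1, gann = gannConfig(maxGen = 200))
cv$vote$overall
cv$leakageAudit
```

The same protocol is exposed from the shell via
`inst/scripts/protsubloc` (sub-commands `simulate`, `train`, `predict`,
`evaluate`, `cv`) and summarized by `scripts/acceptance.R`.
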