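---
title: "Similarity-based side-effect prediction: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based side-effect prediction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrsim)
```

## The problem and the model

adrsim predicts unknown adverse drug reactions from the premise that drugs
which resemble each other — chemically, biologically or phenotypically —
tend to share side effects, and that side effects which sit close together
in the body's anatomical organisation tend to be caused by the same drugs.
Rather than learning directly on high-dimensional property vectors, the
package reduces every drug–side-effect pair $(d, s)$ to at most seven
similarity-derived features:

* **ddi_d** — Jaccard overlap of directed drug–drug interaction triples
  $(\text{partner}, \text{type}, \text{direction})$. Two drugs that
  interact with the same partners, in the same way and the same direction,
  behave alike pharmacologically.
* **ddi_n** — Jaccard overlap of GO-term sets attached to "component
  genes": for each drug, the union of proteins lying on *all* unweighted
  shortest paths between every pair of its targets in a confidence-filtered
  PPI network (endpoints included). This captures functional similarity of
  the network neighbourhoods a drug perturbs.
* **snp** — Jaccard overlap of the gene sets regulated (eQTL) by SNPs
  associated with each drug's indicated diseases, a genetic proxy for
  phenotypic similarity of indications.
* **indication**, **target** — plain Jaccard overlap of indication and
  target sets.
* **chemical** — Tanimoto coefficient of binary path fingerprints
  (Open Babel FP2, 1024 bits, via ChemmineR/ChemmineOB; any precomputed
  fingerprint table is accepted as an alternative backend).
* **se_ah** — side-effect anatomical-hierarchy similarity: the mean over
  the three levels (organ, subsystem, system) of the per-level Jaccard of
  label sets.

For a pair $(d, s)$, each drug-drug feature is the **maximum** similarity
between $d$ and the *other* drugs known (in the training subset only) to
cause $s$; the hierarchy feature mirrors this, taking the maximum
similarity between $s$ and the other side effects known for $d$. Pairs are
classified by four base learners (random forest, Gaussian naive Bayes,
XGBoost, L2 logistic regression) and a stacking ensemble whose
meta-learner consumes the four base probabilities.

## Leakage control

Feature values are functions of the labels, so careless evaluation would
leak held-out information. Two rules prevent this:

1. Candidate sets come from **training positives only** — the feature
   value of a validation or test pair depends on no validation or test
   label. The test suite asserts bit-identity of all feature values after
   deleting every non-train label.
2. **Self-exclusion** — if $(d, s)$ itself is a training positive, $d$ is
   removed from its own candidate set (otherwise every training positive
   would receive feature value 1.0 from its own association).

Because feature values shift with the training positives, evaluation uses
repeated hold-out rather than cross-validation: the positive set and one
freshly sampled balanced negative set are re-split 8:1:1 in every
replicate, and metrics are averaged across replicates.

## Undefined similarities and missing features

A Jaccard similarity between two empty property sets is 0/0 and is kept as
*undefined* (`NA`), never 0 — an empty-profile drug is unknown, not
dissimilar. Tanimoto similarity is undefined whenever either fingerprint
has no set bit. Undefined values are skipped when taking the feature
maximum; a pair whose candidate set is empty or entirely undefined gets a
missing feature, imputed as 0 ("no similar drug known"), with no
missingness indicator added. `filter_universe()` applies the modelling
preconditions up front: side effects kept only with at least `min_drugs`
(default 5) positive drugs, and drugs kept only with at least one defined
similarity to a co-associated drug, iterated to a fixed point because each
removal can trigger the other rule.

One subtlety in the hierarchy similarity: the level count $n$ is fixed at
3, and a level where *both* side effects carry no label contributes 0 to
the sum — the conservative reading that never inflates similarity. A
consequence we document and test: self-similarity equals the fraction of
annotated levels, reaching 1 exactly when all three levels are annotated.
(An alternative — dropping both-empty levels from the average — would
force self-similarity to 1 but changes the denominator away from the fixed
$n = 3$; we kept the fixed denominator.)

The network feature includes a drug's in-network targets in its component
set even when pairs of targets are disconnected, so single-target drugs
and fragmented target sets still receive a defined, if small, gene set.
All shortest paths between a target pair are used, not one arbitrary path,
which makes the construction deterministic and monotone under edge
additions that create new equally short paths. PPI edges below a
confidence of 0.7 (on a 0–1 scale) are discarded by default. The SNP
feature uses regulated genes only — SNP identifiers themselves are not
added to the sets, since the genes are what carry the biology; the chain
is easy to extend if SNP-level overlap is wanted.

## Splitting, negatives and determinism

Negatives are drawn uniformly from the non-positive cross product,
distinct within a set and resampled independently across the (by default
100) sets, each set exactly matching the positive count — duplicates
within one set would add no information and break the balance invariant.
The 8:1:1 split takes floors for the first two subsets and the remainder
for the test subset: 76,645 positives split 61,316 / 7,664 / 7,665.
Positives and negatives are partitioned with identical counts, so every
subset is exactly class-balanced. Every stochastic step (negative
sampling, splitting, tree learners, the meta network) is seeded and
single-threaded; a (seed, inputs) pair reproduces a run bit for bit.

## Classifiers and tuning

Hyperparameters are tuned by a small, fixed grid search maximising
validation AUC: random forest trees in {100, 500} with depth unlimited or
10; XGBoost depth {3, 6} and learning rate {0.1, 0.3} at 100 rounds; ridge
logistic regression with penalty in {0.1, 0.01, 0.001}; Gaussian naive
Bayes has nothing to tune. The grids are deliberately modest: with seven
bounded features in [0, 1], model capacity is not the limiting factor and
a large search would only invite validation overfitting. The stacking
meta-learner is a single-hidden-layer network (8 logistic units, weight
decay 0.01, at most 500 iterations) fit on the base models' *validation*
probabilities — the only labelled data the bases have not seen — and the
weight decay plays the regularising role an early-stopping holdout
otherwise would at this scale (four inputs, a few hundred meta-training
rows). Candidate prediction uses the run with the highest random-forest
validation AUC, scoring every never-used pair in the universe against that
run's training positives.

## Enrichment testing

Predicted positives among the candidate pairs are compared with an
external pharmacovigilance reference via a 2×2 contingency table,
restricted to the scored universe (a pair never scored can be counted
neither way). `fisher_exact()` computes the hypergeometric point
probability of each table sharing the observed margins with log-gamma
arithmetic (exact at $n \sim 10^5$, where factorials overflow doubles),
sums those not exceeding the observed probability for the two-sided p
(minimum-likelihood rule, the convention of standard statistical
software), and reports the conditional maximum-likelihood odds ratio —
solved from the conditional score equation $E_\psi[X] = x$ to a root
tolerance of $10^{-12}$ — alongside the sample odds ratio $xw/yz$. The
two estimates agree to about four decimals at pharmacovigilance-scale
counts.

## What the synthetic generator emulates — and what it does not

`generate_universe()` plants the one assumption the method rests on:
similar drugs share both properties and side effects. Drugs belong to
latent clusters; each cluster owns element pools per property type (drawn
with probability 0.7 within cluster, 0.02 outside), a panel of interaction
partners with fixed types and directions, a target clique in the PPI, GO
and eQTL pools, and a fingerprint template (bits flipped with probability
0.05 per drug). Side effects form cluster-linked blocks confined to a
single anatomical subsystem, and a drug acquires a block side effect with
probability 0.6 versus 0.02 outside — rates chosen so that, at the default
200 drugs × 80 side effects × 10 clusters, virtually all side effects
clear the five-drug support threshold and a ten-replicate pipeline runs in
minutes on one CPU.

The generator does **not** emulate realistic chemistry (fingerprints are
templates, not molecules), scale-free PPI topology, the heavy-tailed
degree distributions of real association data, or reporting biases of
pharmacovigilance systems. Passing tests on synthetic data therefore
demonstrate that the machinery is correct and that planted signal of the
assumed form is recovered (mean held-out AUC ≥ 0.8 on the default
configuration, chance-level on a label-shuffled control) — not that any
particular real-data accuracy will be attained.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the published-table
enrichment statistics at their full printed counts (they are closed-form),
the oracle-equivalence checks on randomized instances of up to 20 drugs /
10 side effects (100 trials per operation), the split contract at the full
76,645-positive scale, and the structure-recovery study on the default
200 × 80 synthetic universe with 5 hold-out replicates of the
random-forest branch — sizes at which the whole battery completes in a few
minutes while still exercising every code path at realistic density.

## Known limitations

* Feature assignment loops over samples in R; at hundreds of thousands of
  pairs it becomes the dominant cost. Grouping by side effect and
  vectorising the candidate maxima is the natural next optimisation.
* The conditional-MLE odds ratio is reported as `Inf`/0 at boundary tables
  rather than a finite penalised estimate.
* `filter_universe()` enforces *any* defined similarity; the stricter
  variant (defined in all selected features) can be emulated by filtering
  with a reduced similarity list.
* Identifiers are opaque case-sensitive strings; no cross-database mapping
  is attempted — inputs must arrive pre-mapped to a common vocabulary.
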