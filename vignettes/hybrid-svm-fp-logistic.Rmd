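---
title: "Beta-turn prediction with localized SVMs aggregated by fractional-polynomial logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-turn prediction with localized SVMs aggregated by fractional-polynomial logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaturn)
```

## The problem

Beta-turns are tight chain reversals in which two residues three peptide
bonds apart bring their C-alpha atoms within 7 Å.  About one residue in
four in globular proteins sits on a beta-turn, so per-residue turn/non-turn
classification is a 1:3 imbalanced problem.  Turns matter for fold
recognition and peptidomimetic design, which is why dedicated predictors
exist alongside general secondary-structure methods.

`betaturn` implements a hybrid predictor.  Its inputs per chain are a
PSI-BLAST position-specific scoring matrix (PSSM, L x 20 log-odds scores),
a 3-state predicted secondary structure string over {H, E, C}, and
optionally a 9-state predicted shape string over {S, R, U, V, K, A, T, G,
N} classifying the phi/psi torsion region.  Producing those annotations
(PSI-BLAST against nr, a secondary-structure predictor, a shape-string
server) is out of scope: the package reads precomputed files.

## The model

**Features.**  Raw PSSM scores x are squashed elementwise by the logistic
function f(x) = 1/(1+e^-x), so every value lies in (0, 1).  Secondary
structure and shape symbols are one-hot encoded (H = 100, E = 010,
C = 001; S through N analogously over nine bits).  A sliding window of 7
residues is concatenated per residue and the prediction is made for the
central residue; chains are zero-padded at the termini ((window-1)/2
positions per side).  Zero is outside the open (0,1) range of scaled
scores, so pad positions are distinguishable from data; padding rules are
not dictated by the method itself, and zero-padding is the convention of
window-based secondary-structure predictors.  Three feature organizations
are supported: PSSM+PSS windowed jointly (7 x 23 = 161 features), PSSM
windowed with only the central residue's PSS appended (143), and
PSSM+PSS+shape windowed (7 x 32 = 224).

**Clustered undersampling and localized SVMs.**  The non-turn class is
split into k = 3 clusters by k-means on the encoded features ("original
variables" — they are already in [0, 1], so no further standardization is
applied).  Each cluster is merged with *all* positives, giving three
approximately balanced sub-training sets, and one RBF-kernel SVM is
trained per subset, with (C, gamma) tuned per subset by seeded internal
cross-validated accuracy over a grid (ties resolved toward the smallest C,
then the smallest gamma).  The three SVMs are never used as voters: every
example passes through all three, and the signed decision values
d = (d1, d2, d3) become the covariates of an aggregating logistic
regression.  "Signed distance" is taken as the raw decision value
(kernel expansion plus bias), whose sign encodes the predicted side;
dividing by the kernel-space norm of w to get geometric margins is
available as an option (`normalize_distances`) for sensitivity analysis,
since either reading is defensible.

For k-means we use the seeded multi-restart Hartigan-Wong algorithm
(`stats::kmeans`, 10 restarts) rather than a k-means++ initialization:
with 10 restarts on data whose negative class actually is multi-modal the
restart variance is negligible, and the partition is deterministic given
the seed.  An empty cluster after all restarts is an error suggesting a
smaller k; the pipeline never silently trains fewer than k models.

**Cross-fitted distances for the aggregation stage.**  A subtle failure
mode drove one design decision.  Every positive example is in every
sub-training set, so each localized SVM can nearly memorize the positives;
decision values computed in-sample on the training residues then separate
the classes almost perfectly, and a logistic regression fit on them learns
degenerate transforms and weights that do not transfer to new chains.  The
aggregating model is therefore fit on *cross-fitted* distances (the
stacking convention): residues are split into 3 seeded folds, each fold's
d-columns come from SVMs retrained without that fold using the already
tuned (C, gamma), and the final prediction-time SVMs are still the ones
trained on the full subsets — at prediction every residue passes through
all three frozen models exactly as the architecture prescribes.  In-sample
distances remain available (`lr_distances = "insample"`).

**Fractional-polynomial logistic regression.**  The aggregator is a
binomial GLM fit by hand-rolled IRLS with step-halving; the selection
criterion is the deviance, DEV = -2 ln L.  Each covariate may enter
untransformed, as a first-degree fractional polynomial x^p with p from
{-2, -1, -0.5, 0, 0.5, 1, 2, 3} (power 0 denotes ln x), or as a
second-degree polynomial with powers (p, q) from the same set — 36
candidate pairs, where the repeated pair (p, p) contributes the
mathematical-limit basis {x^p, x^p ln x}.  Because decision values take
non-positive values, each covariate is first shifted by -min + delta,
delta being the smallest gap between adjacent distinct values, and — when
its IQR is extreme — rescaled by a power of ten to keep powers ±2 and 3
away from overflow.

Form selection uses the closed test at level alpha (default 0.05, the
conventional choice; configurable): best FP2 against the null on 4 df
(failure omits the variable), against the straight line on 3 df (failure
keeps it linear), against the best FP1 on 2 df (success selects FP2,
failure FP1).  Degrees of freedom 4/3/2 follow the multivariable
fractional polynomial (MFP) literature.  Variables are processed in order
of increasing uni-variate linear p-value, and whole-model cycles repeat
until a cycle changes no transform (or `max_cycles`); the per-cycle
deviance trace is retained and exportable as TSV.  Pairwise interaction
screening — add each product of first-basis columns one at a time, keep
LR-significant pairs, then re-check each by Wald and LR jointly and drop
failures once — is implemented but off by default, since there is no
evidence the aggregation model needs interactions and the screen costs
extra fits.  Wald statistics come from the observed-information covariance
at the MLE; selection decisions always use LR tests.

At prediction time the stored shifts and scales are applied to the new
distances; values that fall non-positive under a log or fractional power
are clamped to the training minimum with a warning rather than erroring —
a deliberate robustness choice for slightly out-of-range chains.  The
turn/non-turn call thresholds the probability at 0.5 by default.

## Evaluation

Cross-validation is at the protein level: all residues of a chain stay in
one fold, fold sizes differ by at most one protein, and a seeded greedy
pass balances each fold's turn-residue count toward the global ~25%
(exact stratification is impossible with whole chains).  426 chains over
7 folds give six folds of 61 and one of 60.  Per-fold Qtotal, Qpredicted,
Qobserved, MCC and AUC are reported along with their unweighted mean (the
headline convention) and pooled-count versions, since pooled and averaged
summaries differ in general.  Leave-one-protein-out is available
(`loo = TRUE`) but is not the default — at hundreds of chains it is
needlessly expensive.  ROC curves sweep every distinct score with ties
grouped; AUC is the trapezoid area and equals the Mann-Whitney statistic.
Metrics with zero denominators (e.g. precision with no positive calls)
are reported as 0 with an explicit flag rather than NaN.

## The synthetic generator

Real benchmarks (BT426/BT547/BT823 plus external predictor outputs) are
not shippable, so the package generates data with the statistical
structure the method assumes: i.i.d. per-residue labels at a 25% positive
fraction (optionally contiguous 4-residue turn segments, since real
beta-turns span four residues); pseudo-PSSM rows from class-conditional
Gaussians, where the non-turn class is a mixture of three well-separated
subpopulation modes (per-coordinate SD 1 — the premise that makes k-means
partitioning meaningful) and the turn class sits at a moderate offset
(SD 0.35) from their centre; and PSS/shape symbols from class-conditional
categorical tables in which turns are predominantly coil.  The offset was
fixed once so that held-out discrimination lands in the ~0.8–0.9 AUC range
real beta-turn predictors occupy, rather than at saturation where every
aggregation scheme ties.  Setting `separation = 0` removes the class
signal entirely (including the symbol-table contrast), which should and
does drive downstream AUC to chance.

What the generator does *not* emulate: integer-valued log-odds scores,
positional autocorrelation of real profiles, sequence-dependent structure,
and annotation errors of upstream predictors.  Passing tests therefore
demonstrate correctness of the machinery and the internal consistency of
the method's claims on data satisfying its assumptions — not benchmark
performance on real chains.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own trade-off between power and turnaround: ensemble
comparisons train on 30 chains of 40–100 residues (~2,000 residues) and
test on 12 held-out chains, over 5 seeds, with the coarse 2x2 (C, gamma)
grid and 3 internal tuning folds; fractional-polynomial recovery runs at
n = 10,000 with 20 replicates per truth and 200 replicates for the
type-I-rate check at n = 2,000.  IRLS converges on a deviance change
below 1e-10 with up to 100 iterations and 30 step-halvings; weights are
floored at 1e-10; rank-deficient designs are errors naming the collinear
columns; apparent complete separation is flagged, never silent.  Scans
over FP powers treat a failed fit as infinite deviance rather than
aborting the scan.

## Known limitations

The headline numbers of the original benchmark studies are not
reproducible here by design: they require the BT datasets, PSI-BLAST
profiles against nr, and external PSS/shape predictions.  The closed
test's umbrella 4-df comparison is approximate (the best-FP2 statistic is
a maximum over 36 fits), so its realized type-I rate is only close to
nominal.  Neighbouring FP2 power pairs are nearly collinear on short
positive ranges, so exact-power recovery is inherently noisy even when
the FP2 *form* is recovered reliably.  Cross-fitting triples the SVM
training cost of the aggregation stage; for large corpora consider fewer
cross-fit folds or `lr_distances = "insample"` with a much larger
training set, where memorization pressure is weaker.
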