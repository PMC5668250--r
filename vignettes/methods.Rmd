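---
title: "Predicting DNA-binding proteins from evolutionary and structural profiles"
author: "DNABindProfiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-binding proteins from evolutionary and structural profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNABindProfiles)
```

## The problem and the model

Whether a protein binds DNA can be predicted surprisingly well from two
per-residue profiles that are routine to compute: the position-specific
scoring matrix (PSSM) produced by iterative profile search (PSI-BLAST,
conventionally three iterations against nr at E = 0.001), which captures
evolutionary conservation, and the predicted-structure profile produced
by the SPIDER family of predictors (an "SPD3" file), which carries a
three-state secondary-structure call, predicted accessible surface area
(ASA), four backbone torsion angles and three structure-class
probabilities per residue.

The method implemented here turns those two profiles into a fixed-length
vector of 14 formula-defined feature blocks, reduces the vector by
recursive feature elimination (RFE) under a linear maximum-margin
ranker, and classifies with a support vector machine. The pipeline is
deliberately modular: each block is an explicit formula over a profile
matrix, so each is testable in isolation against a naive implementation
of its defining sum.

### Feature blocks

Let $N$ be the logistically normalized $L \times 20$ PSSM,
$N_{ij} = 1/(1+e^{-m_{ij}})$ for log-odds $m_{ij}$. Four generic
operators are applied to profile matrices $X$ ($L \times W$):

* **composition**: $\frac{1}{L}\sum_{i=1}^{L} X_{ij}$, one value per
  column;
* **bigram at lag $g$**:
  $\frac{1}{L}\sum_{i=1}^{L-g} X_{ik}\,X_{i+g,l}$ over all column pairs
  $(k,l)$ — $W^2$ values;
* **auto-covariance to distance factor $DF$**:
  $\frac{1}{L}\sum_{i=1}^{L-k} X_{ij}\,X_{i+k,j}$ for lags
  $k = 1 \dots DF$ — $W \cdot DF$ values (the lag-$k$ diagonal of the
  bigram);
* **segmented distribution**: per column, the normalized row index at
  which the cumulative column mass first reaches $p\%$ of the column
  total, for $p \in \{s, 2s, \dots, 50\}$, measured from both termini —
  $2\cdot(50/s)$ values per column.

Note the $1/L$ denominator in the bigram and auto-covariance sums even
though only $L-g$ terms exist. That is the defining convention of this
feature family and we keep it verbatim; it shrinks values slightly for
short sequences. We read the composition sum as running over all $L$
rows (a variant that drops the final residue appears in one printing of
the formula; it contradicts the companion definitions and the word
"composition", so we treat it as a typo and flag the choice here).

The evolutionary half of the vector (1345 features) is: amino-acid
composition of the PSSM **consensus sequence** (20), CTD
composition/transition/distribution descriptors of the consensus (105),
bigram of $N$ at lag 1 (400), composition of $N$ (20), auto-covariance
at $DF = 10$ (200), bigram at lag 2 (400), and segmented distribution at
a 10 % step (200). The structural half (201 features) is: secondary-
structure composition and occurrence in (H, E, C) order (3 + 3), a
combined composition block of mean ASA, the sine/cosine of the four
torsion angles (converted to radians first), and the three class
probabilities (1 + 8 + 3 = 12), angle bigram (64), angle auto-covariance
(80), probability bigram (9) and probability auto-covariance (30).

Three interpretation points deserve record. First, the normalization of
the PSSM is specified in this literature only by reference; we use the
elementwise logistic because it maps unbounded log-odds into $(0,1)$
independently of sequence length, which is what the bounded-product
semantics of the bigram formulas require. This is the most consequential
free choice in the package. Second, the feature family is sometimes
described as totalling 1548; the per-block sizes above — each
individually verifiable — sum to 1546, and the package follows the
block-wise accounting. Third, the segmented-distribution step is
sometimes quoted as "5, 10, 25"; no combination of those values yields
the documented 200-dimensional block, so the package exposes a single
`stepPercent` parameter defaulting to 10 (which does), with 5 and 25
available.

### CTD groupings

The CTD descriptors need five three-class partitions of the amino-acid
alphabet; we use the five classical ones — hydrophobicity, normalized
van der Waals volume, polarity, polarizability and charge — which is the
only five-property scheme consistent with the 105-dimensional block
(5 properties × 21 descriptors). They are returned by `ctdGroupings()`
as data, so users can substitute their own partitions. The distribution
percentile for a class with $n_g$ occurrences picks occurrence number
$\lceil q\,n_g \rceil$ for $q \in \{0.25, 0.5, 0.75\}$; first and last
occurrences are exact; a class absent from the sequence contributes
zeros, and a length-1 sequence has zero transitions by convention.

## Selection and classification

RFE starts from all 1546 standardized columns, fits a linear SVM
(C = 1000), ranks columns by squared hyperplane weight, removes the
weakest column, and repeats until `k` remain; `k = 86` is the method's
operating point. One-at-a-time elimination makes selections nested
across `k`, which the tests verify. Standardization is internal and
learned on the training rows only — coefficient magnitudes are not
comparable across raw blocks that mix counts, probabilities and square
Angstroms — with a variance floor of 1e-8 guarding constant columns.
The `step` parameter can remove an integer number or a fraction of the
remaining columns per refit; it exists because the one-at-a-time ladder
costs ~1500 SVM fits per run. The cross-validation experiments in this
package's tests and acceptance script use `step = 0.2` (about 13 refits
per fold); spot checks at `step = 1` on the planted-signal data give the
same conclusions.

The final classifier is a soft-margin SVM, by default linear with
C = 1000 (γ = 0.01 is stored for the RBF and sigmoid alternatives,
where it is the kernel width; for the linear kernel it is inert). We
use the libsvm implementation via `e1071`; the kernel formulas are also
exposed directly as `kernelEval()`. Decision scores are signed distances
to the hyperplane (not calibrated probabilities); a protein is called
binding iff its score is positive. The trained-model container stores
standardization, the selection and an orientation flag, so prediction
accepts raw-unit feature vectors and is reproducible after
`saveModel()`/`loadModel()`.

## Evaluation protocol

`classificationMetrics()` implements sensitivity, specificity, accuracy
and Matthews correlation from the confusion counts, with MCC defined as
0 when any denominator factor vanishes. The ROC area is the
Mann–Whitney statistic (ties half credit), equal to trapezoidal
integration over thresholds and invariant to monotone score transforms;
the PR area is trapezoidal over the threshold sweep. `kfoldCV()` runs
repeated stratified k-fold cross-validation with a caller-supplied seed
(the splitting scheme is otherwise unspecified in this literature;
stratification is the conservative default), pooling each repeat's
held-out predictions; `jackknifeCV()` is the deterministic leave-one-out
special case.

Two protocols differ in where selection happens. The default re-runs
standardization **and** RFE inside every training fold, so the held-out
fold never influences its own predictor. The alternative `globalSelection`
selects once on the complete table before splitting — the protocol under
which tuned features are homogeneous with the evaluation items. On
label-shuffled synthetic data the default stays at chance while
`globalSelection` scores far above it (the classic selection-bias effect);
that contrast is asserted in the acceptance tests, and is why the
leakage-free protocol is the default.

## The synthetic generator

Real inputs require PSI-BLAST against nr and a SPIDER run, neither of
which belongs in a test suite. `generateProfilePair()` emulates the
*statistical shape* of both files: integer log-odds in $[-10, 10]$
centred at $-1$ with a $+6$ bump on the query residue's own column and
Gaussian noise (sd 2); a sticky three-state Markov secondary-structure
string (self-transition 0.8); gamma-distributed ASA (shape 2, scale 30);
uniform torsion angles; and Dirichlet probability rows concentrated
(α = 6) on the residue's true state. The planted class difference adds
`effect` to the mean of the R and K log-odds columns and to the helix
Dirichlet weight of binding proteins — basic residues contact the DNA
backbone in real binders, which makes the documentation read sensibly,
but the tests rely only on the signal's detectability, not its biology.
With `effect = 0` the classes are identically distributed by
construction.

What the generator does **not** emulate: positional autocorrelation of
conservation, realistic secondary-structure segment lengths, the
coupling between ASA, angles and structure class, homology between
proteins, and class imbalance. Passing tests therefore demonstrate that
the pipeline computes its formulas correctly, recovers a planted signal,
and is calibrated under the null — not that it reaches any particular
accuracy on real benchmarks, which would require the external datasets
and tools.

## Problem sizes and numerical choices

The test suite and acceptance script use sizes chosen to finish in
minutes on one CPU while keeping the statistical assertions meaningful:
the planted-signal recovery runs 100 + 100 proteins of length 50–150
(5-fold CV, seed 42, expected accuracy ≥ 0.9); the null calibration runs
50 + 50 proteins × 10 repeats, asserting mean accuracy within the
binomial chance band $[0.4, 0.6]$ for 100 pooled predictions; the
leakage contrast runs 30 + 30 shuffled-label proteins. RFE in these
experiments uses `step = 0.2`; the exactly-`k`, nesting and
planted-recovery contracts are asserted at `step = 1`.

Other conventions: profile parsing stores angles in degrees (the feature
layer converts to radians); SPD3 probability columns are re-mapped from
the file's (C, E, H) order to internal (C, H, E); consensus ties break
toward the first PSI-BLAST column; segmented-distribution thresholds use
$\geq$ with a $10^{-12}$ relative tolerance against accumulated rounding;
the SVM solver tolerance is 1e-4, and fold assignment is stratified
round-robin after a seeded shuffle.

## A worked run

```{r example, eval = FALSE}
coll <- generateCollection(nPos = 30, nNeg = 30, effect = 3, seed = 42)
x <- featureTable(coll)          # 60 x 1546
y <- collectionLabels(coll)
model <- trainBindingModel(x, y, k = 86, rfeStep = 0.2)
predict(model, x[1:3, ])
jackknifeCV(x, y, k = 86, rfeStep = 0.2)
```

## Known limitations

The package consumes PSI-BLAST and SPIDER output; it does not run those
tools, construct benchmark datasets, or serve predictions over the web.
Checkpoint (binary) PSSMs, gapped or masked residues and ambiguity
codes are rejected rather than guessed at. Accuracy claims on real
proteins require real profiles; the synthetic generator is a test
instrument, not a benchmark.
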