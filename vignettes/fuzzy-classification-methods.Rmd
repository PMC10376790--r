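---
title: "Fuzzy classification of heterogeneous biomedical data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy classification of heterogeneous biomedical data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzytree)
```

## The problem

Biomedical studies rarely produce one kind of data. A single diagnostic
question may involve physiological signals (EEG traces), wide laboratory
panels with far more measurements than subjects, mixed numeric/categorical
clinical records, and expert judgments expressed with explicit uncertainty.
Each of these usually gets its own processing stack, which makes results
hard to compare across sources. `fuzzytree` takes a different route: every
data type is converted to a common representation — *fuzzy attributes*,
where each sample holds a membership degree in each linguistic term of each
attribute — and a single fuzzy classifier is trained on that representation.
Fuzzy memberships also give a principled home to the cognitive uncertainty
(vagueness, ambiguity, incomplete specification) that is endemic to
clinical data.

The stage chain depends only on the data type:

| data type            | stages                                                |
|----------------------|-------------------------------------------------------|
| signal               | segmentation → FFT spectrum → PCA → FCM fuzzification |
| large-dimensional    | PCA → FCM fuzzification                               |
| numeric/categorical  | FCM / one-hot fuzzification                           |
| expert (fuzzy)       | none — classified directly                            |

`run_pipeline()` executes the chain; each stage is also exposed on its own.

## Fuzzy sets and datasets

A fuzzy attribute $A_i$ has $m_i \ge 2$ linguistic terms; a sample's value
is a membership vector $(\mu_{i,1}, \dots, \mu_{i,m_i}) \in [0,1]^{m_i}$.
The cardinality $M(A) = \sum_u \mu_A(u)$ generalizes set size and underlies
all mass computations. A `fuzzy_dataset` holds $K$ samples over $n$ input
attributes and one output attribute whose terms are the class labels. Crisp
data are the one-hot special case, so classical tables embed exactly.

## The split criterion

Tree induction needs a score for "how much does input attribute $A_i$ tell
us about the class?". We accumulate a fuzzy frequency table with cells

$$F_{jk} = \sum_{s=1}^{K} w_s \, T\!\left(\mu_{i,j}(s),\, \mu_{B,k}(s)\right),$$

where $T$ is a t-norm (product by default, minimum optional) and $w_s$ the
sample's membership mass at the current node. Normalizing $F$ to a joint
distribution $p$, the score is the Shannon mutual information in bits,

$$I(A_i; B) = \sum_{j,k} p_{jk} \log_2 \frac{p_{jk}}{p_{j\cdot} p_{\cdot k}},
\qquad 0 \log 0 := 0,$$

with masses below $10^{-12}$ treated as zero to avoid log underflow. On
crisp data this is exactly the classical information gain, which gives us a
strong oracle: induction on crisp tables must reproduce textbook ID3 trees,
and the test suite checks that on every two-attribute Boolean function.
Cumulative variants of information estimates for fuzzy decision trees exist
in the literature; we deliberately use plain fuzzy mutual information
because it is fully specified, oracle-testable, and has the bounds
$0 \le I \le \min(H(A_i), H(B))$ that the property tests assert.

## Fuzzy decision tree induction and the pruning parameters

Induction is recursive. Every sample enters the root with mass 1; a split
on $A_i$ sends mass $T(w_s, \mu_{i,j}(s))$ down branch $j$. At each node,
with $M_{node}$ the total mass and confidence the normalized class mass,
the node becomes a leaf when any of the following holds:

* the dominant-class confidence reaches $\beta$ (the node is pure enough);
* the mass fraction $M_{node}/M_{total}$ does not exceed $\alpha$ (the node
  is too small to trust); with this strict inequality $\alpha = 1$ prunes
  even the root, and $\alpha = 0$ never mass-prunes;
* no unused attribute remains (attributes are never reused along a path).

Otherwise it splits on the unused attribute with maximal $I(A_i;B)$, ties
to the lowest index for determinism. Zero-mass branches become leaves that
inherit the parent's confidence. These orientations give the documented
monotone contract — decreasing $\alpha$ or increasing $\beta$ can only grow
the tree — which the acceptance suite verifies on a seeded grid.
The defaults $\alpha = 0.05$, $\beta = 0.95$ are a mild-pruning compromise:
small enough to resolve genuine structure, large enough that a node
carrying under 5% of the mass or already 95% pure stops growing. For exact
logical reconstruction (e.g. recovering a structure function from complete
crisp data) use $\alpha = 0$, $\beta = 1$.

Inference aggregates over all root-to-leaf paths: the instance's branch
memberships are t-norm-combined along each path, leaf confidences are
weighted by path mass, summed, and renormalized; the crisp decision is the
argmax (ties to the lowest class index). `decision_table()` enumerates the
full Cartesian product of input terms — the complete, interpretable
knowledge representation the tree induces from a possibly incomplete
training table.

The fuzzy naive Bayes baseline (`fnb()`) uses class-prior masses and
Laplace-smoothed term-by-class conditional masses; an instance's attribute
contribution is the membership-weighted expectation of the conditional.
It exists as the standard comparison classifier for very small samples.

## Fuzzification

Numeric attributes are fuzzified by one-dimensional fuzzy C-means
(`fit_fcm()`): memberships $\mu_j(x) = 1/\sum_l (d_j/d_l)^{2/(q-1)}$,
centers the $\mu^q$-weighted means, iterated until the largest center shift
drops below `tol`. Defaults: fuzzifier $q = 2$ (the standard choice; larger
values blur term boundaries), `tol = 1e-6`, `max_iter = 300`, three terms
per attribute ("low"/"medium"/"high"). Initialization is deterministic — the
$m$ evenly spaced quantiles through the distinct values — so a fit is
reproducible without a seed; seeded random restarts are available for
multimodal columns. Centers are sorted ascending and term labels follow
that order, giving attributes a stable semantics. Two numerical edge rules:
a value exactly at a center is a full member of that term, and a constant
column is rejected with a pointer to categorical encoding. Note that FCM
memberships are monotone only *between* adjacent centers; in the tails they
rebound toward $1/m$, a known property of the FCM membership function, so
the monotone-locality test runs on the inter-center grid.

Categorical columns and the class column become degenerate crisp attributes
(one term per category). Missing numeric values and categories unseen at
transform time receive uniform memberships — maximal ignorance — with a
warning. Expert data that already arrive as membership degrees are
validated and passed through untouched (`expert_dataset()`).

## Signal pre-processing

`segment_signal()` cuts records into consecutive non-overlapping windows of
`floor(seconds × rate)` samples, discarding the remainder (padding would
fabricate signal). `fft_features()` takes the one-sided FFT magnitude
spectrum with a rectangular window by default — chosen so that pure-tone
fixtures have exact single-bin spectra, which keeps the DFT tests analytic;
a Hann window is available for leakage-sensitive material. A two-sided mode
exists for Parseval checks. `fit_pca()` standardizes features to z-scores
first (spectral bins have wildly different scales), drops zero-variance
columns with a warning, and orients every loading column so its
largest-magnitude entry is positive, making the decomposition
deterministic. Component count defaults: 8 for signal pipelines, 5 for wide
tables.

## Evaluation protocol

Metrics are the five confusion ratios (accuracy, specificity, sensitivity,
precision, F1) computed one-vs-rest against an explicit positive class;
0/0 is reported as `NA` (undefined), never an exception, and undefined
values are excluded from macro averages. `holdout_split()` uses half-up
rounding for the train size (70:30 by default) and largest-remainder
quotas under stratification; `subsample_eval()` repeats the hold-out with
round seeds derived as `seed + rep`. The pipeline fits the pre-processing
(PCA, FCM) on the full dataset and then splits the fuzzified data, matching
the protocol in which a dataset is transformed once and then divided; the
`predict()` methods for every stage support the stricter
fit-on-train-only protocol if a user prefers it.

## What the synthetic generators emulate — and what they do not

The four generators reproduce the *shape* and *separability structure* of
four study archetypes, at these default conditions:

* **signal**: 500 records (400 background / 100 seizure-like) of 23.6 s at
  200 Hz, cut into 2.95 s segments (8 per record, 4000 total). Background
  is a 10 Hz tone plus unit Gaussian noise; the seizure-like class adds a
  3 Hz oscillation with a slow burst envelope whose amplitude relative to
  the background rhythm is the effect size (default 3, chosen as a
  clearly-detectable spectral effect). Effect size 0 makes the classes
  identical by construction.
* **wide**: 78 rows × 186 standard-normal columns, balanced classes, 20
  informative columns shifted by ±1 (effect size 2). Columns always exceed
  rows.
* **clinical**: 177 rows, 29 attributes (11 binary flags, age/BMI, 16
  log-normal markers), 70:30 survival-style outcome, shifts scaled by
  effect size 1.5 — moderate, overlapping distributions, so hold-out
  accuracy lands well below 1 by design.
* **expert**: 10 of the 16 crisp situations of a 2/2/4-term input space,
  classes from a monotone structure function of the summed states,
  memberships Dirichlet-sharpened toward the true term (`certainty = 8`;
  `Inf` is crisp).

They are deterministic given the seed and document themselves in a
manifest. They do **not** emulate EEG physiology, artifact contamination,
batch effects, missing-not-at-random patterns, or clinically realistic
covariance between attributes. A pipeline that passes the recovery tests
here is verified as a correct *implementation*; nothing about these tests
certifies performance on real recordings.

## Numerical choices and degenerate inputs

* Tie-breaks everywhere go to the lowest index (attributes, classes,
  terms) — determinism over optimality.
* Leaf purity is compared with a `1e-9` slack so crisp-pure nodes hit
  `beta = 1` despite floating-point mass summation.
* Frequency-table masses below `1e-12` count as zero in entropies.
* A single-sample dataset inducts a single-leaf tree; it is not an error.
* Zero posterior mass in `predict.fdt()` (possible off-tree with the min
  t-norm) falls back to a uniform confidence vector.
* Serialized models store doubles at full JSON precision; round-trips
  reproduce crisp decisions bit-identically and confidences to below
  `1e-12`.

## Problem sizes used in the checks

The test and acceptance runs use the generators' default conditions above:
the signal pipeline therefore processes 4000 segments × 296 spectral bins
before reduction to 8 components, the wide pipeline 78 × 186, the clinical
pipeline 177 × 29 over 10 subsampling rounds, and the expert pipeline 10
samples over 20 rounds. A full acceptance run takes a few seconds on one
CPU.

## Known limitations

* Attribute non-reuse means continuous structure needing repeated splits
  on one attribute must be captured by more terms instead.
* The mutual-information score is averaged (not cumulative/order-aware);
  ordering-sensitive information estimates from the fuzzy decision tree
  literature are out of scope because their exact form is not fully
  specified in accessible sources.
* Mixed data types within one dataset are supported (numeric + categorical),
  but mixing *archetypes* — e.g. joining signal-derived attributes with
  clinical ones — is left to the user via feature-level concatenation
  before fuzzification.
* One-vs-rest metrics with macro averaging are the only multi-class
  reduction offered; no ROC/AUC.
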