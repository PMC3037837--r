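---
title: "Methods: hybrid gene selection with expression and ontology similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid gene selection with expression and ontology similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generank)
```

## The problem

Two-class expression studies (tumour vs normal microarrays, or any
small-sample bulk comparison) measure thousands of genes on a few dozen
samples.  Classifiers built on the full matrix overfit, and univariate
gene rankings return long lists of mutually redundant genes: co-regulated
genes, probes for the same transcript, and members of one pathway carry
nearly the same discriminative information.  `generank` implements a
three-stage selection pipeline that addresses relevance and redundancy
separately, and evaluates everything under a protocol that cannot leak
test information into the selection.

## The pipeline

**Stage 1 — Fisher filtering.**  Every gene is scored by the Fisher
criterion

$$F(g) = \frac{(m_1(g) - m_2(g))^2}{s_1^2(g) + s_2^2(g)},$$

the squared class-mean difference relative to the summed within-class
variances, and the top $k$ (default $k = 500$) genes are kept.  Variances
use the $n-1$ estimator everywhere in the package.  A gene with zero
pooled variance scores 0 when the class means agree and $+\infty$ when
they differ (it separates the classes perfectly and ranks first).  Ties
keep input order, so rankings are deterministic.

**Stage 2 — greedy redundancy reduction.**  The ranked list is walked
from the most discriminative gene down; each kept gene deletes every
lower-ranked gene whose similarity to it reaches a threshold $ts$
(default 0.8, the empirically tuned value; `tune_threshold()` scans the
grid $\{0.10, 0.15, \dots, 0.95\}$).  Similarity averages two parts:

$$S(g_i, g_j) = \tfrac{1}{2}\left(S_{\mathrm{exp}}(g_i, g_j) +
  S_{\mathrm{sem}}(g_i, g_j)\right).$$

$S_{\mathrm{exp}}$ is the Pearson correlation of the two expression
profiles.  By default its absolute value is used: the threshold lives in
$[0,1]$ and a strongly anti-correlated gene is as redundant as a
correlated one.  (`pearson = "raw"` restores the signed coefficient.)

$S_{\mathrm{sem}}$ is an ontology-based similarity.  Annotation
frequencies are counted over the user-supplied gene-to-term corpus —
each gene–term instance increments the term and all of its `is_a`
ancestors exactly once, so multiple DAG paths never double count — and a
term's information content is $IC(c) = -\ln(\mathrm{freq}(c) /
\mathrm{maxFreq})$.  The base of the logarithm is irrelevant because only
the Lin ratio

$$\mathrm{sim}(c_1, c_2) =
  \frac{2\,IC(\mathrm{MICA}(c_1, c_2))}{IC(c_1) + IC(c_2)}$$

is used, where MICA is the most informative common ancestor (terms count
as their own ancestors).  When both terms sit at probability 1 the ratio
is $0/0$; it is defined as 0 — terms that annotate everything share no
discriminating information.  Gene-level similarity aggregates term pairs
by best-match average by default (`max` and `avg` are available); the
aggregation rule is not fixed by the underlying method description, so it
is a configurable design choice here.  Cross-namespace term pairs (MF vs
BP vs CC) contribute 0: the hierarchies share no ancestry.  Ontology
annotation is incomplete in practice, so when either gene has no usable
annotation the pair's similarity falls back to $S_{\mathrm{exp}}$ alone
and the pair is flagged `expression_only` in the similarity model's
provenance matrix.

**Stage 3 — SVM-RFE.**  A soft-margin linear SVM is trained on the
surviving genes; features are ranked by $w_i^2$ and the lowest-ranked is
removed; this repeats until no features remain (`step` can remove several
per round; the default `"auto"` halves the list while more than 100
features remain, then removes one at a time).  The elimination order
induces nested candidate subsets; each is scored by stratified internal
cross-validation on the training data, and the smallest subset attaining
the maximum mean accuracy is returned — parsimony is the tie-break, since
the underlying criterion specifies only "highest accuracy".

## The SVM solver

No linear SVM implementation with exposed dual coefficients is available
in the supported dependency set, and the dual contract is load-bearing
here (the RFE criterion is built from $W = \sum_i \alpha_i y_i X_i$), so
the package ships a small SMO solver (C++, maximal-violating-pair working
set).  Pairwise updates keep $\sum_i y_i \alpha_i = 0$ exact to floating
point; the stopping rule is a KKT gap below $10^{-10}$.  The bias $b$ is
the average of $-y_t \nabla f_t$ over free support vectors, or the
violating-pair midpoint when no multiplier is strictly inside $(0, C)$ —
in that case $b$ is only unique up to an interval, which the test suite
accounts for when comparing against the quadratic-programming oracle.
$C$ defaults to 1: the hard-margin formulation is presented by the
method, but real training folds are rarely separable.

## Evaluation protocol

`external_cv()` partitions samples into stratified folds (stratification
avoids single-class folds at $n \approx 40$; plain random folds are
available) and re-runs the *entire* selection pipeline inside every
training fold; a linear SVM on the selected genes classifies the held-out
fold.  Aggregate accuracy, sensitivity and specificity are unweighted
means of the per-fold metrics; per-fold metrics with zero denominators
are undefined (`NA`) and excluded from the mean with a warning.
`internal_cv_biased()` deliberately implements the flawed protocol —
selection once on all data, cross-validation only over the classifier —
to demonstrate selection bias; it shares the fold partitioner, so the
same seed yields identical folds in both modes.

Fold assignment is a deterministic function of (labels, fold count,
seed).  One seed drives everything stochastic in a run, and internal CV
seeds are derived from it, so reports are exactly reproducible.

## The synthetic world

`generate_expression()` emits post-preprocessing-scale data: iid standard
Gaussian background, informative genes shifted by `effect_size`
within-class standard deviations in the positive class, and redundancy
groups built as a source gene plus near-copies (`copy_noise_sd`
Gaussian noise; the default 0.3 gives copy-to-source correlation near
0.96, comfortably above the 0.8 threshold).  A `raw_intensity` mode
exponentiates to lognormal intensities for exercising `preprocess()`
(log10 then per-sample standardization).  Defaults — 1000 genes, 20+20
samples, 20 informative at effect 2.0, 5 groups of 5 copies — state the
small-sample microarray regime used across the test suite and were fixed
before any test outcome was observed.

`generate_ontology()` builds a balanced `is_a` tree (a general-DAG
multi-parent fixture exists for ancestor-logic tests) and mirrors the
redundancy structure: each group shares one leaf term (within-group
semantic similarity 1), other genes scatter across the remaining leaves,
and a configurable fraction stays unannotated to exercise the
expression-only fallback.

What a green test establishes — and does not.  The generator's Gaussian,
exchangeable-noise world validates the machinery: formula correctness,
oracle equivalence, planted-structure recovery, leakage-freedom, and the
selection-bias phenomenon.  It does not emulate probe-level artifacts,
heavy-tailed noise, batch structure, or correlated background, so
passing tests do not certify performance on real arrays.  One acceptance
comparison is honestly red for exactly this reason: with 20 clean
informative genes at effect 2.0, a linear SVM on *all* 1000 genes
already classifies perfectly, so the selection pipeline (external-CV
accuracy ≈ 0.95, selecting 2–4 genes) cannot strictly exceed the
no-selection baseline the way it does on real data, where the baseline
is far from its ceiling.  The criterion is kept as stated rather than
weakened; the red result is the synthetic world's property, not the
pipeline's.

## Numerical and design choices

* Standardization is per sample column (the convention of the datasets
  this method targets); a per-gene option exists but is not the default.
* The greedy input is sorted descending by Fisher score.  The method's
  textual description says "ascending order of discriminative power",
  but its algorithm keeps the first gene as the most discriminative;
  descending is the reading consistent with the algorithm's rationale.
* Deletion fires at similarity $\ge ts$, exactly as the greedy
  pseudocode's comparison.
* Threshold tuning evaluates each grid value by external CV, so tuned
  accuracies are selection-bias-free; tuning on the whole dataset before
  CV would be biased and is not offered as a default path.
* Term frequencies are estimated from the user-supplied annotation
  corpus (the analyzed genes), not from a whole-genome annotation set;
  the estimation corpus is unspecified upstream, and using the supplied
  corpus keeps the artifact self-contained.
* Obsolete ontology terms are dropped at parse time together with edges
  touching them; `part_of` relationships are ignored unless explicitly
  included.
* Mean imputation per gene is a deliberately simple stand-in; the
  ontology-aware imputation used upstream for one dataset is out of
  scope.
* RFE ties in $w_i^2$ break by original feature order (the earlier
  feature survives), making elimination orders deterministic.

## Limitations

Binary classification only; linear kernels only; no probe-to-gene
mapping or normalization beyond log-transform and standardization.  The
redundancy stage materializes a dense similarity matrix over the
filtered list — fine at $k = 500$, not intended for $k \gg 10^4$.
Semantic similarity requires the expression matrix and annotation file
to share a gene identifier namespace; no identifier translation is
attempted.
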