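---
title: "Mid-level data fusion for multi-sensor identification: methods and design notes"
author: "senseFuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mid-level data fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senseFuse)
```

## The problem

Authenticating herbal decoction pieces — here, distinguishing *Bletilla
striata* (BS) tubers from the look-alikes *Gastrodia elata* (GE),
*Polygonatum odoratum* (PO) and *Bletilla ochracea* (BOS) — is hard for any
single instrument: an electronic nose summarizes odor in ~10 metal-oxide
sensor responses, an electronic tongue gives ~8 taste-membrane potentials, an
electronic eye gives ~85 calibrated color values, and an HPLC fingerprint
gives a vector of peak areas. Each source sees a different facet of the
material, and the pairs that confuse one instrument (BS vs BOS notoriously)
may be trivial for another.

senseFuse implements **mid-level (feature-level) data fusion**: each source is
reduced to a handful of component scores, the per-source scores are
concatenated into one fused feature table, and a classifier is trained on the
fused table. This keeps the complementary information of all sources while
avoiding both the dimensionality of raw concatenation (low-level fusion) and
the information loss of merging final decisions (high-level fusion).

## The procedure

A run of `runPipeline()` executes the following stages, in order. Training
stages only ever see calibration rows; validation labels are first read at the
evaluation stage.

### 1. Kennard–Stone partition

Samples are split into a calibration set (default 100 of 134) and a
validation set by the Kennard–Stone algorithm: the pair at maximal Euclidean
distance is selected first, then the sample maximizing its minimum distance
to the selected set is added repeatedly. The procedure is deterministic given
the input order; ties resolve to the lowest row index. Distances are measured
in the z-scored concatenation of all source blocks — the method itself does
not prescribe a feature space for splitting, and the joint standardized space
weights every source comparably.

### 2. Standardization (z-score)

Every block is column-standardized,

$$X'_{ij} = \frac{X_{ij} - \bar X_j}{S_j},$$

with the *sample* standard deviation ($n-1$ denominator, the chemometric
convention). In the default `"calibration"` mode the statistics
$\bar X_j, S_j$ are fitted on calibration rows only and applied to all rows,
so nothing about the validation set can leak into the fitted scale. A
`"pooled"` mode that fits the statistics on all rows jointly is provided for
comparison with the older whole-dataset practice; it is deliberately **not**
the default, because pooled reduction reveals information about the
validation samples and flatters generalization estimates. In pooled mode the
PCA eigenvectors are still fitted on the calibration correlation matrix
(which is invariant to the per-column affine choice); the mode only changes
the standardized values inserted into the component expressions.

A column with zero variance on the fitting rows has no defined z-score; the
fit fails naming the column rather than silently dropping it.

### 3. Feature extraction

**Unsupervised (PCA).** The correlation matrix of the standardized
calibration block is eigen-decomposed. Retained are the smallest $k$
components whose cumulative variance ratio reaches the threshold (default
0.90, reading "more than 90% of the variance" minimally). Validation samples
are scored by inserting their standardized rows into the linear expression of
each retained component,

$$Z_i = a_{i1}X'_1 + a_{i2}X'_2 + \dots + a_{im}X'_m,$$

so they never alter the model — the leakage-free projection that motivates
the package. Two numerical conventions make results reproducible across
platforms: eigenvalues are sorted descending, and each eigenvector is
oriented so that its largest-magnitude coefficient is positive.

**Supervised (PLS-DA latent variables).** A NIPALS partial-least-squares fit
regresses the centred one-hot class indicator on the standardized block,
deflating both matrices after each component; calibration T-scores are
pairwise orthogonal by construction, and new samples are scored sequentially
through the stored weights and loadings. The latent-variable count is chosen
by leave-one-out cross-validation (`selectNlvLOOCV()`), minimizing the LOO
misclassification rate with ties going to the *smallest* count; the search
range defaults to 1…min(15, rank), wide enough to cover double-digit LV
counts seen in practice on HPLC-like blocks. A `maxLv` above the matrix rank
is clipped with a warning.

### 4. Fusion

Per-source score matrices are concatenated column-wise in source order
(default EN, EE, ET, HPLC) with provenance names such as `ET-PC1` or
`EN-LV2`. No re-scaling is applied at fusion time: component scores are
already on comparable, variance-driven scales, and re-scaling would distort
the relative weight the sources earned in extraction.

### 5. Classification

Three back-ends share one contract (`classify()` returns a `Prediction` with
continuous per-class scores): the assigned class is the arg-max score class
*provided* that score reaches the threshold $\tau$; otherwise the sample is
reported `UNASSIGNED`. Arg-max ties resolve to the earliest class in class
order and are logged.

* **PLS-DA** — one-hot indicator regression via the same NIPALS engine;
  scores are predicted indicator values. $\tau = 0.5$ by default: an
  indicator regression that cannot push any class's prediction past one half
  has not committed to a class, which reproduces the existence of unassigned
  samples that a discriminant method of this kind reports. The value is a
  convention, not an estimated quantity.
* **RBF-SVM** (binary tasks only) — kernel
  $K(x,y) = \exp(-g\|x-y\|^2)$. The "kernel parameter" is $g$ in this exact
  parameterization (stated prominently because the literature is loose about
  $g$ vs $1/2\sigma^2$). The $(g, c)$ pair is chosen by stratified 10-fold
  cross-validation over a geometric grid $g = 0.05(\sqrt2)^k, k=0..15$ and
  $c \in \{0.1, 1, 10\}$ — the $\sqrt2$-spaced set that produces the
  conventional printed values 0.05, …, 1.13, …, 4.53, …, 9.05 after 2-decimal
  rounding. Folds are fixed by a seed, so selection is reproducible. Ties on
  CV error prefer fewer support vectors (cheaper, better-margined models),
  then larger cost, then smaller $g$. The dual quadratic program is delegated
  to libsvm (e1071); the grid, fold construction, CV loop and selection logic
  are implemented and tested here. The SVM always assigns ($\tau = 0$ on the
  signed decision value): a separating hyperplane has no natural "abstain"
  region on the indicator scale. Multi-class SVM is deliberately out of
  scope.
* **BP-NN** — a fully connected network with logistic-sigmoid activations,
  squared-error loss and full-batch gradient descent with a momentum term,
  $\Delta w(t) = -\eta\nabla E + \alpha\Delta w(t-1)$. Defaults (two hidden
  layers of 10, $\eta = 0.01$, $\alpha = 0.5$, 500 iterations) follow the
  common sensor-data settings. Weights initialize uniformly in $(-0.5, 0.5)$
  from a seed; zero iterations return the initialization untouched, which
  pins the update rule in tests. The loss/batching combination (squared
  error, full batch) is a design choice — momentum networks of this vintage
  are described by architecture and momentum term, not by loss bookkeeping —
  and is stated here so the gradient tests are interpretable.

### 6. Evaluation

The confusion counts TP/FP/TN/FN are computed over *assigned* samples only,
one-vs-rest with the designated positive class (BS); unassigned samples are
excluded from the counts but charged as errors in the overall accuracy. Two
accuracy conventions coexist in tabular practice and both are reported:
`acOverall` = (n − misclassified − unassigned)/n (the headline number; 1
misclassified + 1 unassigned in 100 gives 98%) and the precision-like
`acPrinted` = TP/(TP+FP). Calibration-set accuracy is reported from
leave-one-out cross-validation (retraining with the already-selected
hyperparameters), with the plain refit accuracy logged alongside; for the
BP-NN the LOO loop is off by default (`calibrationCv = "auto"`) purely
because retraining a 500-iteration network 100 times is rarely worth it —
request `"loo"` to force it. AUC is the Mann–Whitney pair statistic (ties
half-counted), with the stepwise ROC points returned for plotting.

### 7. Contribution analysis

Per fused feature, the univariate Wilk's lambda
$\Lambda = SS_{within}/SS_{total}$ measures discriminant ability (smaller is
stronger). The bounded $SS_W/SS_T$ form is used rather than a literal
within-to-between ratio: both are monotone in discriminability, but
$SS_W/SS_B$ is unbounded and undefined at equal group means, while
$SS_W/SS_T$ lives in [0, 1] and supports the "smaller is better" reading
directly. For the strongest PC-type features, the factor-loading matrix links
components back to original variables:

$$q_{ij} = \sqrt{\lambda_i}\, a_{ij},$$

the Pearson correlation between component score $i$ and standardized variable
$j$ (it satisfies $\sum_j q_{ij}^2 = \lambda_i$ and $|q_{ij}| \le 1$). A
"literal" mode $q_{ij} = \lambda_i a_{ij}$ is selectable; the square-root form
is the default because only it is a correlation coefficient, which is what a
factor loading is defined to be. For HPLC fingerprints,
`fingerprintSimilarity()` provides the weighted-cosine common-peak similarity
with marker peaks (militarine-style) up-weighted 2.5:1 — the conventional
form of the "common peak weighting" family, adopted as an interpretation
since that family does not pin down one formula.

## The synthetic generator

No instrument data ships with the package; `generateDataset()` makes the
whole pipeline runnable and testable. It emulates the four-class,
four-source study design: class sizes 45/30/30/29 (BS/GE/PO/BOS), source
dimensionalities 10/85/8/20 (EN/EE/ET/HPLC — the HPLC peak count is
data-defined in practice; 20 is a realistic mid-sized fingerprint). Each
class has a fixed template vector per source, drawn once per (seed, scenario)
from a uniform range and rescaled so the closest template pair sits at the
requested separation; samples are template plus isotropic Gaussian noise.

Defaults were fixed once, before any downstream tuning: per-source separation
$2.5\sqrt{p}$ response units with unit noise, i.e. roughly 2.5 noise standard
deviations of signal per coordinate — strong, clean class structure matching
a setting in which fused models are expected to approach perfect accuracy,
while single sources remain imperfect under the `"complementary"` scenario.
Three scenarios are provided: `"strong"` (all pairs separated in all
sources), `"complementary"` (each source collapses one designated class pair
— its two templates coincide on that source's coordinates only — while the
union of sources separates everything, making fusion demonstrably
necessary), and `"confusable"` (BS and BOS templates at a small fixed
distance in every source, default 1.5, mirroring the one genuinely confusable
species pair).

What the generator does **not** emulate: correlated within-class covariance
(real sensor arrays are strongly collinear; isotropic noise is a stand-in,
not a claim about instruments), drift and environmental artifacts,
chromatographic peak shapes, and batch heterogeneity. Passing tests on this
generator therefore demonstrate that the *algorithms* behave as specified —
leakage-freedom, selection rules, metric conventions, the benefit of fusing
complementary sources — not that any particular accuracy will be attained on
real instrument data.

## Numerical choices and degenerate inputs

* Eigenvector sign: largest-magnitude coefficient positive; arg-max ties take
  the first index. PC retention uses a `>=` comparison with a 1e-12 guard
  against floating-point shortfall at the threshold.
* NIPALS convergence: inner loop stops when the score vector changes by less
  than 1e-12 relatively, capped at 500 iterations; requesting more components
  than the matrix rank is an error rather than a silent truncation.
* Kennard–Stone ties (equidistant candidates) take the lowest row index, so
  results are reproducible under row permutation of equal data.
* Zero-variance columns, single-class training labels, mismatched dimensions,
  unknown positive classes, single-class ROC truth, and zero-norm fingerprint
  vectors all raise early, named errors.
* All randomness flows from explicit seeds: the generator seed fixes the
  dataset; the pipeline seed fans out by fixed offsets (SVM folds seed+1,
  BP-NN initialization seed+2), so one top-level integer reproduces a run
  number-for-number.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely on generated data at
the study-design scale chosen for this package: 134 samples split 100/34,
four sources of 10/85/8/20 features, 20-seed replication for the stochastic
fusion-benefit property, 100-seed replication for the small-n Kennard–Stone
equivalence, and 50 random models for the factor-loading identities. These
sizes keep every property at the scale the method is designed for while
remaining desk-runnable.

## Known limitations

* The SVM back-end is binary by design; species (multi-class) tasks must use
  PLS-DA or BP-NN.
* No probability model is attached to the SVM decision values, so
  probability-based model comparison is not offered.
* The univariate Wilk's lambda ranks features one at a time; a multivariate
  (determinant-based) lambda, VIP scores, and macro-averaged multi-class
  metrics are out of scope.
* `"pooled"` standardization is provided for comparability, but estimates of
  generalization under it should be treated as optimistic — that is the point
  of the default.
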