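---
title: "Classifying sleep apnea events from EEG sub-band features"
author: "somnoband"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sleep apnea events from EEG sub-band features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoband)
```

## The problem

During sleep, apnea events — cessations of respiratory airflow — leave a
signature in the electroencephalogram: cortical activity shifts toward slow,
more regular oscillations, and the shift differs between obstructive events
(OSA, airway collapse with continued respiratory effort) and central events
(CSA, loss of respiratory drive). `somnoband` classifies fixed-length epochs
of two-channel central EEG (the standard derivations C3-A2 and C4-A1,
digitized at 100 Hz) into three classes: OSA, CSA and NB (normal breathing).

The pipeline has five stages:

1. **Sub-band decomposition.** Each epoch channel is band-pass filtered into
   the five canonical EEG bands: delta (0.5–4 Hz), theta (4–8), alpha
   (8–12), sigma (12–16) and beta (16–40 Hz).
2. **Feature extraction.** For every band-limited signal, two features:
   the population variance (band power, in squared input units) and the
   sample entropy (signal irregularity). With 2 channels × 5 bands × 2
   features this gives the fixed 20-column feature matrix.
3. **Feature selection.** Diagonal-metric neighborhood component analysis
   (NCA) learns a nonnegative weight per feature; features below the
   relative threshold $T = \tau \cdot \max(w)$, $\tau = 0.02$, are dropped.
4. **Classification.** Class-weighted KNN, RBF-SVM and random forest on the
   retained features.
5. **Evaluation.** Stratified 10-fold cross-validation; confusion matrices,
   per-class and macro recall/precision/F1, and Cohen's kappa.

Because clinical polysomnography recordings are rarely shareable, the
package ships a synthetic two-channel epoch generator whose classes differ
in band power, signal complexity and inter-hemispheric gain, so every stage
is exercised end to end by code alone.

## Sub-band filter bank

Each band filter is an order-4 Butterworth band-pass (transfer-function
degree 8). Two implementation choices matter numerically:

* **Second-order sections.** The delta band (0.5–4 Hz at 100 Hz sampling)
  puts poles at modulus ≈ 0.99; the expanded degree-8 denominator
  polynomial is ill-conditioned there, and we measured linearity errors
  near $5\times10^{-8}$ with direct (b, a) filtering. The design therefore
  stays in zero-pole form — analog prototype poles, low-pass-to-band-pass
  transform, bilinear discretization — and is applied as a cascade of
  conjugate-pair biquads, which restores linearity to $\sim10^{-14}$.
  Gain is normalized to exactly 1 at the geometric band center
  $\sqrt{f_\mathrm{low} f_\mathrm{high}}$.
* **Zero-phase application with reflected padding.** Filters run forward
  and backward so band outputs stay time-aligned with the epoch (entropy
  and variance are then invariant to filter phase). Start-up transients are
  kept out of the data by extending the epoch at both ends with an odd
  reflection whose length is set from the slowest pole's decay
  ($\lceil 21/(1-|p|_{\max})\rceil$ samples, i.e. the time for a transient
  to fall below $\sim10^{-9}$), which matters precisely for the
  narrow delta band. Zero-phase double application squares the magnitude
  response, steepening the effective roll-off.

The filter order (4 per band) is the package default rather than a value
inherited from any particular recording system; it keeps the passband
maximally flat (Butterworth) with adequate roll-off at 100 Hz sampling, and
is configurable everywhere it appears.

```{r bands}
eeg_bands()
# one-pass gain of the alpha filter at its center and at Nyquist, in dB
round(10 * log10(bandpass_response(8, 12, 100, c(10, 50))), 1)
```

## Sample entropy

For a series $x(1),\dots,x(N)$, embedding dimension $m$ and radius $r$,
sample entropy is

$$\mathrm{SampEn}(m, r, N) = -\ln \frac{B^{m+1}(r)}{B^m(r)},$$

where $B^m$ is the fraction of template pairs of length $m$ whose Chebyshev
distance is at most $r$. Conventions (the literature's standard ones, which
also make the estimator's textbook properties exact):

* Templates of both lengths are drawn from the same start indices
  $1,\dots,N-m$, and self-matches are excluded. A constant series then
  gives $B^{m+1}/B^m = 1$ and SampEn exactly 0.
* $r = 0.2\,\mathrm{sd}(x)$ by default, recomputed from each band-limited
  signal's own standard deviation, so the statistic is invariant to
  amplitude scaling band by band.
* When no pair matches at length $m+1$ the raw statistic is infinite; the
  conditional probability is floored at its smallest resolvable value,
  $2/((N-m-1)(N-m))$, so downstream feature matrices stay finite (a warning
  is raised).

The implementation counts pairs in C++ with a sort on the first template
coordinate (only neighbors within $r$ on that coordinate can match —
counts are identical to the full $O(N^2)$ scan, at a fraction of the cost).
The test suite checks it against a naive double-loop implementation to
$10^{-12}$ over hundreds of randomized series.

Defaults $m = 2$, $r = 0.2\,\mathrm{sd}$ follow common EEG practice and are
exposed as parameters. Variance uses the population normalization ($1/N$).

## NCA feature selection

The selector learns one nonnegative weight per feature by maximizing the
regularized soft leave-one-out nearest-neighbor accuracy

$$\xi(w) = \sum_i p_i - \lambda \sum_l w_l^2, \qquad
  p_i = \sum_{j \ne i,\, y_j = y_i} p_{ij}, \qquad
  p_{ij} = \frac{\exp(-D_w(x_i, x_j))}{\sum_{k \ne i} \exp(-D_w(x_i, x_k))},$$

with the weighted per-feature distance
$D_w(x_i, x_j) = \sum_l w_l^2 \lvert x_{il} - x_{jl}\rvert$. Optimization is
L-BFGS from the fixed start $w = 1$; since weights enter squared, the
absolute values at the optimum are reported. The optimizer tolerance
defaults to $10^{-9}$ — looser settings can leave uninformative features
stranded well above zero, which directly corrupts the relative threshold
rule.

Choices made where the procedure is underdetermined:

* Features are z-scored before fitting (inside tuning loops, with
  training-fold statistics only), so the selected set is invariant to
  per-column rescaling.
* $\lambda$ is tuned on a grid of 16 equally spaced values spanning
  $[0, 15/n]$ by stratified 5-fold inner cross-validation, scored by the
  0/1 loss of a 1-NN rule in the learned weighted metric; ties break toward
  the larger (sparser) $\lambda$. When tuning is skipped the default is
  $\lambda = 1/n$, inside the small-penalty regime that grid targets.
* The threshold multiplier $\tau = 0.02$ is fixed.

## Classifiers and class weighting

Event data sets are imbalanced (central events are typically the rarest),
so all classifiers support inverse-frequency ("balanced") class weights
$w_c = n/(C\,n_c)$:

* **KNN** (default $k=5$, Euclidean): neighbor votes are multiplied by
  their class weight; ties break toward the smallest aggregate neighbor
  distance.
* **SVM** (RBF kernel, $C=1$, one-vs-one decomposition with majority vote,
  via libsvm): class weights scale the misclassification penalty.
* **Random forest** (85 trees, bootstrap + per-node feature subsampling,
  via ranger): class weights enter the impurity. Impurity-level weighting
  moves decision boundaries far less than vote- or penalty-level weighting;
  on 10:1 imbalanced synthetic data the minority-recall gain is about
  +0.02 for the forest versus +0.3 for KNN/SVM — a property of the
  mechanism, not a defect of the implementation.

Cross-validation is stratified (round-robin deal of shuffled within-class
indices), so per-fold class proportions deviate from the global ones by at
most one sample and per-class accuracy is defined in every fold. The
"average confusion matrix" is the element-wise mean of row-normalized
per-fold matrices; the raw-count pooled matrix is reported alongside.
Degenerate 0/0 metric ratios are reported as 0 with a warning rather than
NaN so fold aggregation never crashes.

In the evaluation battery, precision is $TP/(TP+FP)$; kappa is computed
from the confusion-matrix marginals as $(p_o - p_e)/(1 - p_e)$.

## Selection protocols: per-fold versus global

`run_pipeline()` defaults to refitting the NCA selection inside every
training fold, so held-out rows never influence which features the
classifier sees. The classical order — select once on all data, then
cross-validate — is available as `selection_mode = "global"` for
comparability with the common published protocol, but note it leaks
selection information into the folds and biases accuracy upward.
Cross-validation here pools epochs across the whole set; grouping folds by
recording subject would be stricter still, and pooled CV should be read
with that caveat for real multi-patient data.

## The synthetic generator

Each generated epoch is a sum of band-limited oscillations (white noise
filtered into each band and rescaled to a class-specific standard
deviation — narrowband but not tonal, so spectra resemble EEG and sample
entropy varies smoothly) plus broadband white noise controlling complexity:

```{r profiles}
synth_profiles()
```

The default contrasts encode the intended physiology-like structure: the
apnea-like classes are slow-wave dominated and regular (high delta/theta
variance, low sample entropy), normal breathing is noise-dominated and
complex; OSA and CSA differ in their delta/theta balance and in a right-
hemisphere (C4) gain for CSA. Amplitudes are in arbitrary microvolt-like
units. These profiles were chosen once, a priori, to give clearly separated
classes; with them, random-forest 10-fold CV accuracy on 300 epochs is
essentially 1.0. They are deliberately *not* calibrated to real apnea
physiology, and passing tests on this generator demonstrates that the
pipeline machinery is correct — not that comparable accuracy would be
reached on clinical recordings, where class contrasts are far weaker,
artifacts abound, and epochs from one patient are correlated.

Default sizes follow sleep-scoring convention: 30 s epochs at 100 Hz
(3000 samples). The tabular generator (`generate_feature_table()`) makes
Gaussian feature matrices with class-dependent mean shifts in chosen
columns, for testing the selection and classification stages in isolation.

## Numerical and degenerate-input conventions

* Epoch labels: an epoch takes the annotated event covering ≥ 50% of it,
  else NB; the largest overlap wins among qualifying events.
* Sampling-rate and band-edge validity (edges strictly inside (0, Nyquist))
  are enforced at construction.
* JSON artifacts are written with 17 significant digits, so reports and
  sidecars round-trip bitwise.
* All stochastic stages (generator, fold assignment, forest) derive from
  explicit seeds; a pipeline rerun from one seed is bitwise identical.

## Problem sizes used in the checks

The shipped verification exercises the pipeline at sizes chosen to probe
each property well away from its failure modes while staying desk-scale:
sample-entropy oracle sweeps over series of 50–2000 points; selection
recovery on 300-row, 20-column tables with 5 informative columns at a
3-standard-deviation effect, over 20 seeds; class-weighting contrasts on
10:1 imbalanced tables over 10 seeds; and the full pipeline on 300
synthetic epochs (100 per class) under 10-fold CV.

## Known limitations

* No artifact rejection, re-referencing or sleep staging; epochs are taken
  as given.
* Mixed apnea events and hypopnea severity grading are out of scope; the
  label alphabet is exactly {OSA, CSA, NB}.
* EDF support covers plain EDF signal records with one shared sampling
  rate; EDF+ annotation channels are skipped (events come from a CSV
  sidecar).
* The KNN neighbor count, SVM kernel settings and the per-fold-selection
  default are package choices where the underlying procedure is commonly
  left unstated; all are exposed in configuration.
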