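---
title: "Methods: incremental fuzzy-rough nearest neighbour authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental fuzzy-rough nearest neighbour authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incfrnn)
```

This vignette is the package's own account of the method it implements: the
model and its assumptions, the tunable parameters and their defaults, the
operational choices made where the underlying procedure is described only
qualitatively in the literature, what the synthetic generator does and does
not emulate, and the numerical conventions. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The classification model

The classifier is fuzzy-rough nearest neighbour (FRNN) over a mutable
**training pool** of labelled feature vectors. Similarity is the fuzzy
tolerance relation

$$R(x, y) = \min_{a \in \mathbb{A}}
  \left(1 - \frac{|a(x) - a(y)|}{a_{\max} - a_{\min}}\right),$$

the minimum over attributes of range-normalised similarity, where
$a_{\max}, a_{\min}$ are the extreme values of attribute $a$ recorded in the
pool. Two conventions make this well-defined on streams:

* **Clamping.** Test values are clamped into $[a_{\min}, a_{\max}]$ before
  the ratio, so similarities stay in $[0, 1]$ even for probes outside the
  enrolled range.
* **Constant attributes.** When $a_{\max} = a_{\min}$ the per-attribute
  similarity is defined as 1: an attribute that never varies carries no
  discriminating information.

For a probe $y$, the $k$ nearest pool objects $N$ (ties broken toward the
older object, for determinism) give per-class lower and upper approximation
memberships

$$(R{\downarrow}C)(y) = \min_{x \in N} \; I\big(R(x,y),\, C(x)\big), \qquad
  (R{\uparrow}C)(y) = \max_{x \in N} \; T\big(R(x,y),\, C(x)\big),$$

with crisp membership $C(x) \in \{0, 1\}$, the Kleene–Dienes implicator
$I(a, b) = \max(1 - a, b)$ and the minimum t-norm $T(a, b) = \min(a, b)$ —
the operator pair of the original FRNN formulation. The decision score is
$((R{\downarrow}C) + (R{\uparrow}C))/2$, maximised over classes; score ties
prefer the larger upper membership, then lexicographic label order. With
these operators over a shared neighbour set, lower $\le$ upper is *not*
guaranteed for sparse classes, so the implementation asserts only the
$[0,1]$ bounds. A high lower membership means every neighbour belongs to the
class; a high upper membership means at least one does.

`k = 5` throughout, the conventional neighbourhood size for this task
family; it is configurable everywhere.

## Incremental update strategies

Each streamed probe is classified and then handed to an update strategy.
Every pool object carries a **usage counter** `w` (how often it served as a
nearest neighbour) and an **insertion index** (arrival order).

### Probability-based updates (label-free)

The deployable strategy never sees the true label. Per probe, in order:

1. Retrieve $\min(k + 1, n)$ neighbours. The top-two relative difference is
   $D = (S_1 - S_2) / ((S_1 + S_2)/2)$ and the threshold is
   $\tfrac12 \sum_i (S_i - S_{i+1}) / ((S_i + S_{i+1})/2)$ over all
   consecutive pairs of the retrieved list. Retrieving $k+1$ is deliberate:
   the sum over $i = 1..k$ references $S_{k+1}$, so a $k$-pair sum needs
   $k+1$ similarities; smaller pools simply contribute fewer pairs.
2. Compute class probabilities from the counters *as they stand before this
   probe's update* (the order is otherwise ambiguous; fixing
   probabilities-before-increment makes replays deterministic):
   $$P(C_i) = \frac{\left(\sum w_{NN}(C_i)\right) / \left(\sum w_{NN}\right)}
                   {\sum w_{C_i}},$$
   neighbour counter mass in class $C_i$ over total neighbour counter mass,
   discounted by the class's total pool counter mass. These values are not a
   normalised distribution and are used only through their argmax; when the
   maximum is tied and the predicted class is among the tied classes, the
   predicted class is taken (otherwise lexicographic order).
3. Increment the counters of the top $k$ neighbours.
4. Insert the probe — under its **predicted** label, since no ground truth
   exists at authentication time — iff
   ($D >$ threshold and predicted $\ne$ highest-probability class) or
   ($D <$ threshold and predicted $=$ highest-probability class).
   $D =$ threshold exactly inserts nothing: both conditions are strict.
   The two conditions encode: a clear nearest-neighbour margin with
   conflicting class evidence marks a genuinely new characteristic worth
   storing, while a fuzzy margin with agreeing evidence consolidates a
   confident region.
5. While a window cap $W > 0$ is exceeded, evict the least-used object
   (minimal counter, FIFO among ties). Attribute range statistics widen on
   insertion but are *not* recomputed on deletion: an exact recompute is
   $O(nd)$ per eviction, and widened ranges only rescale similarities
   monotonically while preserving the $[0,1]$ bounds (an exact-recompute
   flag exists on `pool_delete_least_used()`).

With fewer than two pooled objects the threshold is undefined, so cold-start
probes are inserted unconditionally. New objects enter with counter 1, not
0, so the per-class counter mass in the probability denominator can never be
zero for a class that is present. Counters reset between evaluation folds.

### Actual-class updates and the FIFO-KNN baseline

The **actual-class** strategy inserts the probe under its true label when it
was misclassified — the ground-truth reference, an upper bound rather than a
deployable method. The **FIFO-KNN** baseline is plain incremental k-NN:
Euclidean distance on raw feature values, equal-weight majority vote (vote
ties fall back to the single nearest neighbour), always insert, evict the
oldest when over the cap. Inserted labels default to the predicted label
(matching the no-ground-truth setting); actual-label insertion is available
because incremental k-NN implementations historically consume labelled
instances. FIFO eviction is label- and usage-blind, so on an imbalanced
stream it can purge every client object — the motivating failure mode,
demonstrated as a regression test.

The default window threshold in the full-scale experiments is 60% of the
dataset (4050 of 6750 objects); window 0 means unlimited growth.

## The distraction descriptor

The raw-signal path assumes multichannel EEG (default five occipito-temporal
electrodes T5, T6, O1, OZ, O2 at 512 Hz) with trial onsets at 2.5 s spacing
(1 s stimulus + 1.5 s inter-stimulus interval). Processing: linear-phase
windowed-sinc FIR bandpass into alpha (8–13 Hz) and beta (13–30 Hz) — 513
taps at 512 Hz, about one second of impulse response, adequate for the 8 Hz
lower transition; reflection padding and group-delay compensation keep the
output aligned and length-preserving — then 1 s epochs from each onset, and
rejection of trials whose absolute amplitude exceeds 100 µV on any channel
(strictly larger; normal scalp EEG peaks below 100 µV).

Three feature families per channel and band:

* **PSD shape.** The periodogram is the raw FFT with
  $P(k) = |x(k)|^2 / N$ (no taper, no padding), which makes Parseval exact
  and testable. The three scalar features — *concavity* (quadratic
  coefficient of a least-squares parabola on $\log_{10}(P + 10^{-12})$ over
  in-band bins), *power variance* (variance of in-band $P$), and
  *nondominant ratio* (one minus the in-band power fraction within ±1 Hz of
  the in-band peak) — are explicit operationalizations of qualitative
  spectral-shape descriptors for which no canonical closed form exists.
  They are this package's documented surrogates, and results attached to
  them should be read accordingly.
* **Wavelet phase stability (WPS).** Complex Morlet ($\omega_0 = 6$, the
  standard resolution trade-off) at the band-centre frequency; per time
  point the across-trial resultant length of unit phasors
  $\Gamma(\tau) = \frac1M\left|\sum_m e^{i \arg(W_\psi f_m)(s,\tau)}\right|$,
  averaged over $\tau$ excluding half a wavelet support at each epoch edge.
  1 means perfect inter-trial phase locking; independent phases give
  $\approx 1/\sqrt{M}$. How to reduce the $(s,\tau)$ plane to one scalar is
  not standardised; the band-centre scale with a trimmed time mean is this
  package's declared reduction.
* **Coherence.** $C_{xy}(f) = |P_{xy}|^2 / (P_{xx} P_{yy})$ with per-trial
  Hann-tapered spectra averaged across trials before the ratio (a single
  segment gives identically 1); the Hann taper controls leakage in the
  cross-spectra while the feature reported is the in-band mean, clipped to
  $[0,1]$ against rounding. Default pairs: O1–OZ and OZ–O2, the occipital
  pairs that survive feature selection in this descriptor family.

WPS and coherence are multi-trial statistics but the classifier consumes
per-trial objects, so both are computed over a sliding block of the $B = 10$
most recent trials and assigned to the block's last trial (the first trial
borrows the block ending at trial 2, the smallest viable window). The
default grid — 5 channels × 2 bands × 3 PSD features, 5 × 2 WPS, 2 pairs ×
2 bands coherence — yields 44 named features; the candidate set of the
original experiments (210 features) is not recoverable from its description,
so this grid is a documented reconstruction, not a replication.

## Feature selection

CFS scores a subset $S$ of $k$ features by
$\mathrm{Merit}_S = k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$ —
relevance over redundancy. Correlations are absolute Pearson
(point-biserial against the binary class); the heavier
discretization-plus-symmetrical-uncertainty variant found in some toolkits
is unnecessary for continuous descriptors, a documented divergence. The
search is greedy forward with best-first patience 5 (a common default; no
search strategy is canonical), ties toward the lexicographically first
feature name, and always returns at least one feature. Note the merit is
not monotone against duplication in general: duplicating a feature whose
relevance exceeds the subset mean can raise the merit; the redundancy
penalty guarantees no gain only for duplicates at subset-average relevance
(property-tested in that form). Selection runs once on the enrolment split
of a fold, never on streamed data.

## Evaluation protocol

"Small enrolment, long stream" is formalised as **inverse 10-fold
cross-validation**: stratified folds where each fold in turn is the ~10%
initial pool and the other nine folds are streamed in arrival order. The
positive class is the **client** throughout. Metrics: accuracy, recall,
precision, F-measure from the confusion counts, and AUC by trapezoidal
integration of the ROC sweep with half-credit ties (equal to the
Mann–Whitney estimator, which the tests verify). Under 1:44 imbalance an
all-impostor predictor reaches accuracy $44/45 \approx 0.978$ with recall 0,
so recall/precision/F are the informative metrics; this artefact is asserted
as a regression test.

Strategy comparisons share one shuffled stream order per seed across all
configurations, so per-fold metrics are paired; differences get an
Anderson–Darling normality check (case 3, estimated mean and variance,
small-sample correction) and the paired t-statistic
$t = \bar D / (S_D / \sqrt N)$ with a two-sided p from $t_{N-1}$.
Significance is the standard $p \le 0.05$ rule. Degenerate difference
vectors are handled explicitly: all-zero differences report $t = 0, p = 1$;
zero variance with non-zero mean reports an infinite statistic with
$p = 0$.

## The synthetic generator

No public dataset exists for this paradigm, so the package ships a
generator in two layers.

The **raw-signal layer** (`sample_subject()`, `simulate_session()`) encodes
the statistical structure the descriptor assumes: a subject-specific alpha
peak uniform on 8–13 Hz (alpha frequency is a stable individual trait),
log-normal alpha/beta amplitudes, stimulus phase locking on target trials
via a von Mises phase with gamma-distributed concentration, inter-channel
coupling through a symmetric occipitally-weighted mixing matrix
(Cholesky of a nearest-positive-definite correction), pink background
noise, a 40/60 target/non-target trial mix, occasional >100 µV artefact
excursions, and slow multiplicative band-power drift. Ambient-distraction
conditions scale the beta amplitude (0.6 / 1.0 / 1.4 for quiet / low /
high) and the noise floor — condition effect sizes are configuration
defaults, not fidelity claims. Trials are oscillation-plus-noise; no
event-related potential morphology is simulated, because the descriptor
consumes band features only.

The **feature-space layer** (`simulate_feature_stream()`) is the fast path
for streaming experiments: per subject a multivariate normal with mean
spread 1 between subjects, within-subject standard deviation 1.0, linear
mean drift of 0.5 units over the stream along a random per-subject
direction, 45 subjects × 150 objects with one designated client (1:44
imbalance). Two defaults deserve justification. The within-subject spread
was set so that a single streamed run lands in the realistic difficulty
regime for EEG biometrics (AUC well below 1, recall in the 0.3–0.65 band)
— at half this noise every strategy is perfect and comparisons are
meaningless. The per-feature scales span three orders of magnitude
(`10^seq(-1.5, 1.5)`) because real descriptor features do: spectral power
variances (µV⁴) against unit-interval WPS and coherence values. The fuzzy
tolerance relation is invariant to these scales (it normalises by attribute
range); the raw-Euclidean KNN baseline is not, and its sensitivity to
scale — historically mitigated in toolkits by built-in normalisation — is
part of what the comparison measures.

What passing tests on this generator show is that the implementation has
the documented properties (orderings, invariants, limits) under the
declared statistical structure; they are not evidence about any particular
real EEG dataset.

## Problem sizes and numerical conventions

The streaming comparison runs the full-scale grid (6750 objects, window
4050, k = 5) over 10 replicate stream orders with one fold each; the
companion script `scripts/acceptance.R` reproduces it end to end from a
single seed. Unit and property tests use reduced grids (tens of trials,
hundreds of objects) chosen to exercise every code path quickly. Other
conventions: epsilon $10^{-12}$ under the log in the concavity fit;
coherence bins with zero auto-power are excluded; similarity ties resolve
toward older objects; eviction ties resolve FIFO; merit improvements must
exceed $10^{-12}$ to reset the search patience; all randomness flows from
explicit integer seeds and replays are byte-identical.

## Known limitations

* The PSD shape features are surrogates (above); absolute values are not
  comparable to other implementations of similarly-named features.
* The probability expression is used only through its argmax; it is not a
  normalised posterior.
* Intersession variability — enrolment and probes from different recording
  days — is not modelled by the generator and is the obvious next stressor
  for this method family.
* The feature-space generator draws i.i.d. Gaussians around drifting means;
  real descriptor blocks are autocorrelated through the sliding WPS /
  coherence windows.
* `pool_delete_least_used()` keeps widened attribute ranges by default;
  after heavy turnover similarities are mildly compressed relative to exact
  ranges (flag available).
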