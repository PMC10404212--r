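# incfrnn

Incremental fuzzy-rough nearest neighbour classification for EEG brainprint
authentication.

## The problem

EEG-based person authentication ("brainprint") treats an individual's
stimulus-evoked brain response as a biometric credential: the enrolled user
is the **client** (positive class), everyone else an **impostor**. Two
properties make this hard in practice. First, EEG is nonstationary — a
user's response drifts within and across sessions, so a static template
degrades. Second, the class distribution is extremely imbalanced (one client
among many impostors), so naive streaming updates and accuracy-style metrics
both mislead. This package implements an instance-based classifier whose
training pool is revised *incrementally* as probe objects stream in, without
ever needing the true label at authentication time, together with the full
feature-extraction and evaluation stack around it.

## The model

Classification is fuzzy-rough nearest neighbour (FRNN). Objects are compared
through the fuzzy tolerance relation

    R(x, y) = min_a ( 1 - |a(x) - a(y)| / (a_max - a_min) )

the minimum over attributes of range-normalised similarity. For a test
object `y` and each class `C`, the k nearest neighbours `N` define

    (R↓C)(y) = min_{x in N} max(1 - R(x, y), C(x))     (lower approximation)
    (R↑C)(y) = max_{x in N} min(R(x, y), C(x))         (upper approximation)

with crisp memberships `C(x) ∈ {0, 1}` (Kleene–Dienes implicator, minimum
t-norm). The predicted class maximises `(lower + upper) / 2`.

After each prediction the training pool is updated by one of three
strategies:

* **probability-based** (the method of interest, label-free): the object is
  inserted when the relative gap `D` between the top two neighbour
  similarities and the threshold
  `0.5 * Σ_i (Sim_i - Sim_{i+1}) / ((Sim_i + Sim_{i+1}) / 2)` disagree with
  the class evidence — insert iff (`D` > threshold and the predicted class
  differs from the class with the highest counter-based probability) or
  (`D` < threshold and they agree). Each class's probability is
  `[(Σ counters of neighbours in C) / (Σ counters of all neighbours)] /
  (Σ counters of all pool objects in C)`, driven by per-object usage
  counters that record how often an object served as a nearest neighbour.
  When a window cap is set, the least-used object (FIFO among ties) is
  evicted.
* **actual-class**: insert on misclassification under the true label — a
  ground-truth upper bound, not deployable for authentication.
* **FIFO-KNN**: the plain incremental k-NN baseline (Euclidean majority
  vote, always insert, evict the oldest). Being label- and usage-blind, it
  can purge every client object from an imbalanced stream — the failure
  mode the counter-based deletion is designed to avoid.

Around the classifier the package provides the EEG *distraction descriptor*
(FIR bandpass filtering into alpha 8–13 Hz and beta 13–30 Hz, 1 s trial
epochs, >100 µV artefact rejection, then per channel/band: spectral-shape
PSD features, wavelet phase stability, and inter-channel magnitude-squared
coherence), CFS feature selection with the merit
`k·r̄_cf / sqrt(k + k(k-1)·r̄_ff)`, a streaming evaluation protocol
(inverse 10-fold splits: 10% enrolment pool, 90% streamed probes; AUC,
recall, precision, F-measure; Anderson–Darling check and paired t-tests),
and a synthetic EEG generator standing in for unavailable recordings.

## Worked example

```r
library(incfrnn)

# a 15-subject imbalanced stream in feature space (subject 1 is the client)
stream <- simulate_feature_stream(n_subjects = 15, n_per_subject = 60, seed = 42)
stream$subject <- NULL

split <- inverse_tenfold_split(stream, seed = 42)[[1]]
enrol <- stream[split$train_ids, ]   # ~10% initial pool
probe <- stream[split$stream_ids, ]  # ~90% streamed

run <- stream_run(enrol, probe, classifier = "frnn",
                  config = update_config(k = 5, window_size = 540))
run
#> <stream_report> frnn/probability: 810 objects streamed; pool 90 -> 540
#>   AUC 0.9276  acc 0.9370  recall 0.6111  precision 0.5238  F 0.5641

baseline <- stream_run(enrol, probe, classifier = "knn",
                       config = knn_config(k = 5, window_size = 540))
glance(baseline)[, c("strategy", "auc", "recall", "f_measure")]
#> # A tibble: 1 × 4
#>   strategy   auc recall f_measure
#>   <chr>    <dbl>  <dbl>     <dbl>
#> 1 fifo_knn 0.654 0.0370    0.0690
```

The probability-based run recovers 61% of the client's probes (recall
0.611, AUC 0.928) while the FIFO-KNN baseline collapses to recall 0.037 on
the same stream: its label-blind evictions flush the enrolled client
objects, exactly the imbalance failure the counter-based strategy avoids.
Note that both models put accuracy above 0.93 — with 14 impostors per
client, accuracy mostly measures how easy it is to say "impostor".

`tidy(run)` returns the per-probe records, `autoplot(run)` the ROC curve;
`compare_strategies()` runs several configurations over shared stream orders
and attaches paired t-tests. `cfs_select(stream)` performs CFS subset
selection. For the raw-signal path, see `sample_subject()`,
`simulate_session()`, `session_descriptor()` and the methods vignette. A
thin CLI over the same functions lives in `inst/cli/incfrnn.R`.

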