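---
title: "Similarity-based adaptive windows for imbalanced EEG streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based adaptive windows for imbalanced EEG streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sawstream)
library(dplyr)
```

## The problem

Scalp-EEG seizure detection is an extreme class-imbalance problem: in the
corpus subset bundled with this package (see
`siena_class_distribution()`), seizure signal accounts for 1,304 seconds
against 162,987 seconds of normal signal — a mean per-patient ratio of
0.0081. A streaming classifier that adapts chunk by chunk to such data
drifts toward always predicting "normal": accuracy looks excellent while
sensitivity collapses, which is exactly the failure mode that matters
clinically.

Two data-level remedies frame this package. *Accumulate-and-undersample*
("skew") rebalancing keeps every positive ever seen and randomly
undersamples the current chunk's negatives; it restores sensitivity but
discards negatives (raising false alarms) and its positive buffer grows
without bound, eventually inverting the majority. The *similarity-based
adaptive window* (SAW) implemented here instead keeps **all** negatives
and strengthens the rare class only with recent, relevant positives.

## The procedure

Instances arrive in chunks $S(T)$ of fixed size at ticks $T = 1, 2,
\dots$. Write $P(T)$ for the positives of $S(T)$. Each positive carries a
*positive instance age* (PIA), set to 0 on arrival and incremented by one
each time the instance is carried into a later window. The user sets an
age threshold (`ath`): an instance is eligible for carrying only while
$\text{PIA} < \text{ath}$, giving it a lifetime of exactly `ath + 1`
windows (its native window plus `ath` carries).

At each tick the held positives from previous ticks form the candidate
pool. When the current chunk has positives, their per-feature mean — the
centroid $C(T) = \bar{x}$ — summarises the chunk's positive region, and
candidates are ranked by Euclidean distance
$d(a, b) = \sqrt{\sum_i (a_i - b_i)^2}$ to it. The age-eligible candidates
form the *balance rare-class set* (BRS), which is merged into the chunk to
produce the adapted window $W(T)$. Four cases arise:

1. no positives anywhere: the window is the chunk, untouched;
2. chunk has positives but nothing is held yet: window unchanged, the
   positives enter the held state;
3. chunk has no positives: every age-eligible held positive is merged;
4. both present: the centroid is computed, candidates ranked, and the BRS
   merged.

Negatives are never dropped, resampled, or carried; the multiset of
negatives in every window equals that of its chunk.

## Parameters that matter

* **`ath`** (default 8) — the PIA threshold. It is the size control of the
  BRS: under iid Bernoulli($p$) labels the steady-state positive fraction
  of the adapted window is $p(\text{ath}+1) / (1 + p\,\text{ath})$, about
  0.068 at $p = 0.008$, ath $= 8$. Larger values raise sensitivity but
  eventually bias the learner toward the positive class; values between 4
  and 9 balance the two in this regime.
* **`brs_cap`** (default `NULL`) — the description of the procedure sorts
  candidates by distance but names no top-$k$; the age constraint is
  described as the size control, and the published presence dynamics
  require every eligible positive to be carried. The default therefore
  carries all of them (the distance sort fixes order only), and `brs_cap`
  turns the sort into a true top-$k$ filter for users who want one.
* **`standardize_distances`** (default `FALSE`) — distances are computed
  on raw features; optionally they can be computed on z-scores using
  running per-feature moments of the stream, since nothing is said about
  feature scaling. Membership is unaffected when the BRS is uncapped.
* **Tie-breaks** — equal distances are resolved toward the smaller arrival
  index (older instance), making runs deterministic.
* The held pool accumulates across ticks rather than holding only the
  previous chunk's positives: the procedure is explicitly accumulative,
  and multi-window carry-over is what produces the published presence
  levels. PIA increments at carry time, after selection, which pins the
  otherwise ambiguous off-by-one: lifetime is `ath + 1` windows. Under a
  `brs_cap`, an unselected candidate does not age that tick; aging is
  per-carry, not per-tick.

## Featurization

Raw multichannel records are sliced into 1-second epochs (matching the
seconds-of-signal bookkeeping of the corpus summary) and transformed with
the discrete Fourier transform
$H_k = \sum_{r=0}^{R-1} h_r e^{-2\pi i r k / R}$. The feature set is not
prescribed by the method, so the package defaults to standard clinical
practice: log band power per channel in the delta (0.5–4 Hz), theta
(4–8), alpha (8–13), beta (13–30) and gamma (30–45 Hz) bands, with a
raw-magnitude-bins mode as the alternative. An epoch is labelled seizure
when at least half of it (configurable `overlap_threshold`) overlaps an
annotated seizure interval. Bands above the Nyquist frequency of a record
are dropped with a warning. Annotations are read from a plain CSV sidecar
(`onset`/`offset` seconds), and signals from in-memory matrices or CSV;
artifact removal, filtering and montage handling are out of scope.

## Classifiers and evaluation

The streaming learners implement a three-verb contract (`learn_one`,
`predict_one`, `reset`), so external incremental classifiers can be
plugged in. Built in are:

* an incremental Gaussian naive Bayes (Welford updates; after $n$
  single-instance updates its sufficient statistics equal the batch fit) —
  the deterministic reference learner used in most pipeline tests;
* a minimal Hoeffding tree (VFDT): leaves accumulate class counts and a
  capped buffer, and every `grace_period = 200` instances score 10
  quantile thresholds per feature by information gain
  $\text{Entropy}(R) = -\sum_i p_{i|R} \log_2 p_{i|R}$, splitting when the
  best feature's lead exceeds the Hoeffding bound
  $\epsilon = \sqrt{R^2 \ln(1/\delta) / 2n}$ at $\delta = 10^{-7}$, or
  when $\epsilon <$ `tie_threshold` (0.05);
* an online-bagging ensemble of such trees (default $M = 10$), replaying
  each instance Poisson(1)-many times per member, majority vote with ties
  toward the positive class. Per-tree drift detectors are deliberately a
  pluggable no-op hook (`on_chunk`): the referenced drift machinery is
  named but unspecified in the method's description, so adaptation here
  comes from continuous leaf updates, and an external adaptive-forest
  implementation can be substituted through the contract.

Evaluation is prequential (test-then-train): within each window every
in-scope instance is first predicted, tallying a per-chunk confusion
matrix, then learned. The seven tracked metrics are TPR, TNR, FPR, FNR,
accuracy, precision and F1. Two choices deserve a note:

* `eval_scope = "window"` (default) tests carried instances again. This
  matches reported confusion totals that exceed the chunk size (e.g. a
  1,689-instance total for a 1,600-instance chunk equals 1,600 + 89
  carried), but it re-tests instances the model has already trained on —
  an optimistic bias. `"native"` mode tests only the chunk's own
  instances while still learning the full window.
* Undefined metrics (zero denominators, e.g. precision when nothing is
  predicted positive) are reported as `NA`, never 0, and summaries report
  both the unweighted mean of per-chunk metrics (skipping `NA` chunks) and
  the pooled-matrix variant, since either aggregation is defensible.

## The synthetic generator

`generate_stream()` emulates the study conditions without any download:
100 chunks of 1,600 instances, positive rate 0.008, 10 features,
unit-variance Gaussians with class-mean separation 2.0 (spread evenly
across features), iid Bernoulli labels by default and a two-state Markov
"episode" mode (mean episode length 93 instances, the corpus' mean seizure
duration at 1-second epochs) for contiguous seizures; an optional per-tick
mean shift models distribution drift. `generate_signal_record()` produces
raw-signal records (AR(1) background, high-amplitude 5 Hz ictal
oscillation) for exercising the featurizer end to end.

What the generator does *not* emulate: EEG artifacts, channel
correlations, non-stationary background rhythms, patient heterogeneity,
or annotation noise. Tests passing on this generator demonstrate the
mechanics and the imbalance dynamics of the method, not clinical
performance on real recordings.

## Numerical and scale choices

Sizes used by the test suite were chosen to keep the full run fast on one
core while leaving each assertion well-converged: the presence-dynamics
check runs the full 100 × 1,600 stream (it is cheap — no learner), the
method-ordering comparison runs 50 chunks of 800 with the naive Bayes
learner, and tree/ensemble tests use streams of 1,500–2,000 instances.
The steady-state presence check uses $p = 0.02$ so that Monte-Carlo error
at desk scale stays well inside its ±0.01 band. Variances in the naive
Bayes are floored at $10^{-9}$; band powers are logged with a $10^{-12}$
offset; the Hoeffding tree's leaf buffers are capped at 2,000 instances,
an approximation to a streaming quantile sketch that is exact at the
scales tested.

## Known limitations

* The BRS top-$k$ ambiguity above is resolved in favour of
  age-only control; capped selection is available but not the default.
* Carried positives are re-learned (and by default re-tested); heavy
  carry-over therefore weights recent positives more than a leakage-free
  design would.
* The Hoeffding tree is minimal: no pre-pruning beyond the gain test, no
  memory management, no drift-triggered subtree replacement.
* EDF files are not parsed directly; signals enter as matrices or CSV
  with a CSV annotation sidecar.
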