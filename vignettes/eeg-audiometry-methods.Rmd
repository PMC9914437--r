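---
title: "Decoding heard and unheard tones from EEG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding heard and unheard tones from EEG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional pure-tone audiometry depends on the listener pressing a
button. `eegaudiometry` models an alternative: present tones in random
order, record multi-channel EEG simultaneously, and decide from the brain
signal alone whether each tone was heard. A perceived stimulus evokes a
P300 — a positive event-related deflection roughly 300 ms after onset —
while an unheard tone (or silence) evokes nothing, so heard-versus-unheard
becomes a binary classification of stimulus-locked EEG epochs.

The package covers the whole chain: the adaptive test protocol, a
synthetic EEG generator standing in for human recordings, BrainVision
file I/O, signal conditioning, epoch labeling from the marker stream, a
text-style (count vectorizer + TF-IDF) feature encoding, and a bank of
seven classifiers with a full metric suite and channel-ablation design.

## The adaptive random protocol

The stimulus space is 8 frequencies (125, 250, 500, 1000, 2000, 4000,
8000, 12000 Hz) x 12 hearing levels (10–120 dB HL in 10 dB steps): 96
tones per ear, 192 for both. Tones are drawn uniformly at random from the
remaining set of the current ear (left ear first, right only after the
left set is exhausted). Two pruning rules keep sessions short:

* heard at (f, L): all untested tones at frequency f with level > L are
  assumed audible and removed;
* unheard at (f, L): all untested tones at f with level < L are assumed
  inaudible and removed.

The audiogram reports, per ear and frequency, the lowest level among
heard trials, or no-response (NR) when nothing was heard. With a
deterministic listener (hears iff level ≥ threshold — the boundary is
inclusive by design so grid thresholds are exactly recoverable) the
pruning rules never discard the true threshold, so recovery is exact for
*every* presentation order; the tests verify this exhaustively on a
reduced grid (all 24 orders) and on 100 seeded full-grid sessions. The
worst case — strictly ascending levels to a listener who hears only the
top level — presents all 96 tones, and trials per ear can never exceed
96. A psychometric listener (`slope_db > 0`) hears with probability
`plogis((level - threshold)/slope)` for robustness experiments.

The intensity grid follows the 12-step 10–120 dB enumeration that makes
the 96-per-ear arithmetic consistent; the looser "0–110 dB" phrasing
found in clinical summaries of the Hughson-Westlake method is treated as
descriptive only. The classic 10-down/5-up staircase itself is out of
scope — random presentation with pruning replaces it. A heard response
prunes only the *same* frequency: generalizing across "similar"
frequencies would risk discarding true thresholds, so it is deliberately
not done.

## The synthetic EEG generator

No public recordings accompany this design, so the generator is a
first-class module rather than a fixture. It emulates what the decoding
pipeline needs and nothing more:

* 16 channels at 2000 Hz, white Gaussian background noise (default
  σ = 1 µV; 1/f "pink" shaping available);
* on each *heard* trial, a positive Gaussian bump (peak 300 ms after
  onset, σ = 60 ms, default peak 5 µV) added to the noise — a P300
  surrogate; real P300s vary in shape, latency and topography, and no
  published amplitude accompanies this protocol, so the defaults are
  stated assumptions, not measurements;
* a channel amplitude profile — 1.0 on channels 1–8, 0.5 on 9–13, 0.0 on
  14–16 — that turns the qualitative observation "the separation is seen
  on channels 1–13 and most clearly on 1–8" into a testable ground truth
  for the ablation experiments;
* the marker stream: S1/S3 at left/right stimulus onset, S2/S4 at the
  button press of heard trials (latency ~ Normal(0.45 s, 0.08 s)
  truncated at 50 ms), and S5 at the midpoint of the pause between one
  trial's response window and the next onset, plus one after the final
  trial.

Because heard and unheard epochs differ *only* by the additive template,
setting the amplitude to zero yields a true null: the tests check that
heard/unheard epoch means are then statistically indistinguishable and
that every classifier falls to chance. What passing these tests shows is
that the pipeline recovers a known additive evoked response at realistic
noise levels; it does not show performance on real EEG, with its
artifacts, non-stationarity, latency jitter and subject variability —
none of which are modeled.

## Signal conditioning

Fixed order: 50 Hz notch → 1–12 Hz band-pass → per-channel min-max
normalization → rounding to 3 decimals. The filters are applied
forward-backward (zero phase) by default so the P300 peak is not
delayed: a second-order biquad notch (Q = 30) and a 4th-order Butterworth
band-pass, both per channel. 1–12 Hz is the conventional P300 band. The
filter family, order and Q are not dictated by the protocol, only the
corner frequencies are; all are configurable in `filter_spec()`.

Normalization granularity (per channel, per epoch, or global) is an open
choice; per-channel-per-recording is used because it makes the rounded
alphabet bounded (at most 1001 distinct values per recording) without
letting single-epoch outliers rescale their own epoch. Rounding uses
round-half-even, stated explicitly for cross-language reproducibility.

## The signal-to-text encoding

Each epoch (default window: 0 to +0.7 s after the event, long enough to
contain a 300 ms deflection) becomes a "document": every rounded sample
value is formatted as a fixed-width word ("0.000"…"1.000"), channel by
channel, giving channels x samples tokens per document. Documents are
count-vectorized over the lexicographically sorted vocabulary (for these
fixed-width tokens lexicographic order equals numeric order) and weighted
by smoothed TF-IDF:

    TFIDF(t, d) = TF(t, d) * IDF(t),   IDF(t) = ln((n + 1) / (DF(t) + 1)) + 1

with raw counts as TF, `n` documents and `DF(t)` the number of documents
containing `t`. The natural logarithm is used (the base is not dictated);
since `DF ≤ n`, every IDF is ≥ 1, and weights are zero exactly where
counts are zero. Rows are L2-normalized by default — the standard pairing
for this smoothed-IDF variant — with a flag to obtain the literal
unnormalized product instead. The vocabulary and document frequencies are
frozen on the training partition; unseen test tokens are ignored. Tokens
carry no channel tag (values are words, wherever they occur); this
discards spatial identity within an epoch — channel information enters
only through which channels contribute tokens, which is what the ablation
manipulates. The encoding likewise discards token order, i.e. all timing
within the window: a document is a bag of amplitude values. That this
suffices here is itself informative — the evoked bump shifts the value
histogram — but it is a deliberately radical reduction.

## Classifiers, metrics, ablation

Seven families run on the TF-IDF features, all delegated to established
implementations with fixed seeds: Gaussian naive Bayes, gradient-boosted
trees, an RBF support-vector classifier, a CART decision tree, k-nearest
neighbours (k = 5), ridge-penalized logistic regression (a plain
unpenalized fit is ill-posed with far more terms than documents), and a
random forest. Hyperparameters are the implementations' defaults,
exposed as arguments; no tuning is performed.

Heard is the positive class. From the confusion counts the report
derives: error (FP+FN)/N — also reported as "MSE", which for 0/1 outcomes
coincides with the error rate — accuracy, recall, precision, specificity,
F1 and MCC; from the predicted probabilities, log loss (clipped at
1e-15) and trapezoidal ROC AUC. Degenerate cases follow fixed rules:
precision is undefined (rendered "-") when nothing is predicted positive,
F1 is undefined when precision or recall is, and MCC is 0 when its
denominator vanishes. A 21-row regression fixture of published confusion
matrices with their printed metric values pins this arithmetic down to
the printed precision.

Evaluation shuffles and splits 70/30 with stratification, optionally adds
stratified k-fold cross-validation (k = 5 by default; any published CV
figures refer to unavailable human data and are not targets). The
ablation harness re-runs epoch extraction, featurization (fresh
vocabulary) and all classifiers for channel subsets 1–16, 1–13 and 1–8
under the same split seed, so subsets differ only in which channels feed
the features. Because each trial also contributes a silence epoch,
unheard is the structural majority class (roughly 2:1); the harness
therefore subsamples to class balance (seeded) before splitting, making
0.5 the chance level and matching the near-balanced published test sets.

## Problem sizes and determinism

Tests and the acceptance script run two both-ears sessions per condition
(a mid-grid flat listener, ~70 trials each), giving ~290 epochs before
balancing and ~160 after — enough for the high-signal condition to sit
far above its 0.80 accuracy bar and for the null condition's 99% binomial
band around 0.5 to be meaningfully narrow. One global seed fans out to
every stochastic stage through a stage-name hash (`derive_seed`), so any
stage can be reproduced in isolation; identical configuration and seed
give byte-identical session files, recordings and reports.

## Known limitations

* The generator's evoked response is an additive, jitter-free template;
  real single-trial P300 detection is substantially harder.
* Bag-of-values features cannot represent latency information; methods
  that exploit timing are out of scope.
* The BrainVision writer emits the FLOAT_32 multiplexed dialect only
  (INT_16 and vectorized files are read, not written); segmented files
  and non-EEG channel types are unsupported.
* The audiogram is the raw minimum heard level; clinical masking,
  bone conduction and retest reliability are not modeled.
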