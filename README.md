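# eegaudiometry

Automatic pure-tone audiometry decoded from EEG. The package simulates an
adaptive random hearing test — tones drawn at random from an 8-frequency
(125 Hz–12 kHz) × 12-level (10–120 dB HL) grid per ear, with pruning rules
that remove levels a response has already settled — while a synchronized
16-channel, 2000 Hz EEG stream records the brain's reaction. A heard tone
evokes a P300-like deflection ~300 ms after onset; the pipeline decides
heard-versus-unheard from the EEG alone and recovers the audiogram.

It is aimed at researchers prototyping EEG-based (button-free) audiometry
pipelines: the protocol, a synthetic P300 generator (no public recordings
accompany this design), BrainVision (.vhdr/.vmrk/.eeg) I/O, conditioning,
epoch labeling from the S1–S5 marker scheme, the signal-to-text feature
encoding, and a seven-classifier evaluation harness with channel ablation.

## The method in brief

Each stimulus-locked (or silence) window of conditioned EEG — 50 Hz notch,
1–12 Hz band-pass, per-channel min-max normalization, rounding to three
decimals — is rendered as a *document* whose words are the rounded sample
values ("0.000"…"1.000"), channel by channel. Documents are
count-vectorized over the sorted vocabulary and weighted by smoothed
TF-IDF,

    TFIDF(t, d) = TF(t, d) · IDF(t),    IDF(t) = ln((n + 1)/(DF_t + 1)) + 1,

with raw counts as TF, `n` documents and `DF_t` the document frequency,
then L2-normalized per document. Seven classifier families (naive Bayes,
gradient-boosted trees, SVC, decision tree, k-NN, ridge logistic
regression, random forest) are trained on a stratified 70/30 split and
scored by confusion-matrix metrics — error, accuracy, recall, precision,
specificity, F1, MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)) —
plus log loss and trapezoidal ROC AUC, with channel-ablation runs on
channels 1–16, 1–13 and 1–8. Undefined metrics (e.g. precision with no
positive prediction) render as "-".

See `vignettes/eeg-audiometry-methods.Rmd` for models, assumptions,
parameter choices and limitations.

## Worked example

```r
library(eegaudiometry)

# a listener with a sloping high-frequency loss
lst <- listener_model(data.frame(
  ear = rep(c("left", "right"), each = 8),
  frequency_hz = rep(audiometry_frequencies(), 2),
  threshold_db = c(20,20,30,40,50,60,80,100, 20,20,20,30,40,50,70,90)))

trials <- run_session(lst, seed = 42)      # adaptive random test, both ears
nrow(trials); sum(trials$heard)
#> 76 trials, 46 heard (pruning settles 192 candidates in 76 presentations)

compute_audiogram(trials)                  # recovers the exact thresholds
#>      ear frequency_hz threshold_db
#> 1   left          125           20
#> 2   left          250           20
#> 3   left          500           30
#> ...                                      (all 16 cells match the listener)

rec <- generate_recording(trials, synth_config(), seed = 43)
rec
#> <eeg_recording> 16 channels x 308700 samples @ 2000 Hz (154.3 s), 198 markers

pre <- preprocess_recording(rec)           # notch, band-pass, normalize, round
ev  <- label_events(pre$markers)           # S1/S3 ± S2/S4 -> heard/unheard; S5 -> silence
rep <- run_ablation(pre, ev, subsets = "1-13",
                    families = c("gradient_boosted_trees", "naive_bayes",
                                 "support_vector"),
                    seed = 42)
print(format_report(rep), row.names = FALSE)
#>  channels              algorithm tn fp fn tp accuracy mse recall precision
#>      1-13 gradient_boosted_trees 14  0  1 13     96.4 3.6   92.9     100.0
#>      1-13            naive_bayes 14  0  0 14    100.0 0.0  100.0     100.0
#>      1-13         support_vector 14  0  0 14    100.0 0.0  100.0     100.0
#>     f1 specificity   mcc log_loss   auc cv_accuracy
#>   96.3       100.0 0.931    0.154  96.4           -
#>  100.0       100.0 1.000    0.000 100.0           -
#>  100.0       100.0 1.000    0.032 100.0           -
```

Accuracy/MSE/recall/… are percentages of the held-out test epochs; `tn fp
fn tp` are the confusion counts with *heard* as the positive class. At the
generator's default signal-to-noise ratio (5 µV evoked peak over 1 µV
noise) the task is easy by construction; lower `erp_amplitude_uV` in
`synth_config()` to make it hard, or set it to 0 for a true null.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/eegaudiometry.R simulate --seed 42 --out runs/demo
Rscript inst/cli/eegaudiometry.R evaluate --seed 42 \
        --recording runs/demo/recording --subset 1-8 --out runs/demo
```

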