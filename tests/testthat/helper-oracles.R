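# Independent brute-force TF-IDF oracle: plain dictionary loops over
# terms and documents, no sharing with the package's vectorized path.
naive_tfidf <- function(corpus, l2_normalize = TRUE) {
  vocab <- sort(unique(unlist(corpus)))
  n <- length(corpus)
  counts <- matrix(0L, nrow = n, ncol = length(vocab),
                   dimnames = list(NULL, vocab))
  for (d in seq_len(n)) {
    for (tok in corpus[[d]]) {
      counts[d, tok] <- counts[d, tok] + 1L
    }
  }
  df <- numeric(length(vocab))
  for (t in seq_along(vocab)) {
    for (d in seq_len(n)) {
      if (counts[d, t] > 0) df[t] <- df[t] + 1
    }
  }
  idf <- numeric(length(vocab))
  for (t in seq_along(vocab)) idf[t] <- log((n + 1) / (df[t] + 1)) + 1
  w <- matrix(0, nrow = n, ncol = length(vocab), dimnames = list(NULL, vocab))
  for (d in seq_len(n)) {
    for (t in seq_along(vocab)) w[d, t] <- counts[d, t] * idf[t]
    if (l2_normalize) {
      nrm <- sqrt(sum(w[d, ]^2))
      if (nrm > 0) w[d, ] <- w[d, ] / nrm
    }
  }
  list(vocab = vocab, counts = counts, doc_freq = df, idf = idf, weights = w)
}

random_token_corpus <- function(n_docs, n_terms, max_len = 30) {
  alphabet <- formatC(sample(0:1000, n_terms), width = 5, flag = "0")
  lapply(seq_len(n_docs), function(i) {
    sample(alphabet, sample.int(max_len, 1), replace = TRUE)
  })
}

# Tiny deterministic recording: known sinusoids per channel plus markers.
toy_recording <- function(n_channels = 3, fs = 500, dur_s = 4,
                          markers = NULL) {
  n <- fs * dur_s
  t <- (seq_len(n) - 1) / fs
  data <- t(vapply(seq_len(n_channels),
                   function(c) sin(2 * pi * c * t) * c, numeric(n)))
  if (is.null(markers)) {
    markers <- data.frame(label = c("S1", "S2", "S5"),
                          position = as.integer(round(n * c(0.1, 0.3, 0.9))))
  }
  eeg_recording(data, fs, markers = markers)
}

rms <- function(x) sqrt(mean(x^2))
db_ratio <- function(after, before) 20 * log10(rms(after) / rms(before))

# Small but realistic end-to-end dataset: one both-ears session of a
# mid-grid listener, synthesized, preprocessed, labeled.
simulate_dataset <- function(seed, erp_amplitude_uV = 5, noise_sigma_uV = 1,
                             isi_s = 2.0) {
  listener <- flat_listener(60)
  trials <- run_session(listener, seed = seed, isi_s = isi_s)
  cfg <- synth_config(erp_amplitude_uV = erp_amplitude_uV,
                      noise_sigma_uV = noise_sigma_uV,
                      window_s = 0.7)
  rec <- generate_recording(trials, cfg, seed = seed + 1000)
  pre <- preprocess_recording(rec)
  list(trials = trials, recording = pre,
       events = label_events(pre$markers))
}
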