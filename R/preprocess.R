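#' Filter settings of the conditioning pipeline
#'
#' The conditioning chain is a 50 Hz power-line notch followed by a
#' 1-12 Hz band-pass (the conventional band for P300 detection), applied
#' per channel and, by default, forward-backward for zero phase shift.
#'
#' @param notch_freq_hz notch centre frequency.
#' @param notch_q notch quality factor (centre / -3 dB bandwidth).
#' @param band_lo_hz,band_hi_hz band-pass corner frequencies.
#' @param order band-pass design order (Butterworth; even).
#' @param zero_phase apply filters forward-backward.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(notch_freq_hz = 50, notch_q = 30,
                        band_lo_hz = 1, band_hi_hz = 12,
                        order = 4, zero_phase = TRUE) {
  stopifnot(notch_freq_hz > 0, notch_q > 0,
            band_lo_hz > 0, band_hi_hz > band_lo_hz,
            order >= 2, order %% 2 == 0)
  structure(list(notch_freq_hz = notch_freq_hz, notch_q = notch_q,
                 band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 order = order, zero_phase = zero_phase),
            class = "filter_spec")
}

apply_channelwise <- function(rec, b, a, zero_phase) {
  filt <- signal::Arma(b = b, a = a)
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    rec$data[i, ] <- if (zero_phase) signal::filtfilt(filt, x)
                     else as.numeric(signal::filter(filt, x))
  }
  rec
}

#' 50 Hz notch filter
#'
#' Second-order IIR (biquad) notch at `notch_freq_hz`, per channel.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  if (spec$notch_freq_hz >= rec$fs_hz / 2) {
    stop("notch frequency must be below the Nyquist frequency")
  }
  w0 <- 2 * pi * spec$notch_freq_hz / rec$fs_hz
  alpha <- sin(w0) / (2 * spec$notch_q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  apply_channelwise(rec, b / a[1], a / a[1], spec$zero_phase)
}

#' 1-12 Hz band-pass filter
#'
#' Butterworth band-pass of the configured order, per channel.
#'
#' @inheritParams notch_filter
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs_hz / 2
  if (spec$band_hi_hz >= nyq) stop("band edge must be below Nyquist")
  bt <- signal::butter(spec$order / 2,
                       c(spec$band_lo_hz, spec$band_hi_hz) / nyq,
                       type = "pass")
  apply_channelwise(rec, bt$b, bt$a, spec$zero_phase)
}

#' Per-channel min-max normalization to [0, 1]
#'
#' Each channel is mapped over the whole recording by
#' `(x - min) / (max - min)`; a constant channel maps to all zeros.
#'
#' @param rec an [eeg_recording()].
#' @return The normalized recording.
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$data) > 0)
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    rng <- range(x)
    rec$data[i, ] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1])
                     else rep(0, length(x))
  }
  rec
}

#' Round samples to three decimals
#'
#' Round-half-even to 3 decimals, putting every sample on the 0.000-1.000
#' grid of at most 1001 distinct values — the token alphabet of the
#' downstream count vectorizer.
#'
#' @param rec an [eeg_recording()] with values in [0, 1].
#' @return The rounded recording.
#' @export
round3_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$data <- round(rec$data, 3)
  rec
}

#' Full conditioning pipeline
#'
#' Fixed order: notch, band-pass, normalize, round to three decimals.
#'
#' @inheritParams notch_filter
#' @return The conditioned recording, samples on the 3-decimal grid.
#' @export
preprocess_recording <- function(rec, spec = filter_spec()) {
  rec <- notch_filter(rec, spec)
  rec <- bandpass_filter(rec, spec)
  rec <- normalize_recording(rec)
  round3_recording(rec)
}
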