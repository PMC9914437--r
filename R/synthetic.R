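#' Configuration of the synthetic P300 EEG generator
#'
#' The generator emulates a 16-channel recording at 2000 Hz in which every
#' heard tone evokes a P300-like positive deflection peaking ~300 ms after
#' onset, superimposed on background noise. The deflection strength varies
#' across the montage: full amplitude on channels 1-8, half on 9-13, and
#' none on 14-16, so that channel-ablation experiments have a known ground
#' truth.
#'
#' @param n_channels number of channels.
#' @param fs_hz sampling rate in Hz.
#' @param noise_sigma_uV background noise standard deviation, microvolts.
#' @param noise_kind `"white"` (Gaussian) or `"pink"` (1/f-shaped).
#' @param erp_amplitude_uV peak amplitude of the evoked deflection before
#'   the per-channel profile is applied.
#' @param erp_latency_s peak latency after stimulus onset.
#' @param erp_width_s Gaussian standard deviation of the deflection.
#' @param channel_profile per-channel amplitude multipliers (length
#'   `n_channels`, all >= 0).
#' @param window_s post-stimulus window reserved for the evoked response;
#'   the silence marker is centred between the end of this window and the
#'   next stimulus onset.
#' @param response_latency_mean_s,response_latency_sd_s button-press delay
#'   used when trials carry no response times of their own.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 16,
                         fs_hz = 2000,
                         noise_sigma_uV = 1.0,
                         noise_kind = c("white", "pink"),
                         erp_amplitude_uV = 5.0,
                         erp_latency_s = 0.300,
                         erp_width_s = 0.060,
                         channel_profile = default_channel_profile(n_channels),
                         window_s = 0.7,
                         response_latency_mean_s = 0.45,
                         response_latency_sd_s = 0.08) {
  noise_kind <- match.arg(noise_kind)
  stopifnot(n_channels >= 1, fs_hz > 100, noise_sigma_uV >= 0,
            erp_latency_s > 0, erp_width_s > 0,
            length(channel_profile) == n_channels,
            all(channel_profile >= 0), window_s > 0)
  structure(list(n_channels = n_channels, fs_hz = fs_hz,
                 noise_sigma_uV = noise_sigma_uV, noise_kind = noise_kind,
                 erp_amplitude_uV = erp_amplitude_uV,
                 erp_latency_s = erp_latency_s, erp_width_s = erp_width_s,
                 channel_profile = channel_profile, window_s = window_s,
                 response_latency_mean_s = response_latency_mean_s,
                 response_latency_sd_s = response_latency_sd_s),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_channel_profile <- function(n_channels = 16) {
  prof <- rep(0, n_channels)
  prof[seq_len(min(8, n_channels))] <- 1.0
  if (n_channels >= 9) prof[9:min(13, n_channels)] <- 0.5
  prof
}

#' Evoked-response template of the generator
#'
#' A positive Gaussian bump peaking `erp_latency_s` after stimulus onset,
#' scaled per channel by `erp_amplitude_uV * channel_profile`.
#'
#' @param config a [synth_config()].
#' @return An `erp_template`: `latency_s`, `width_s`, `amplitudes_uV`
#'   (per channel), and `waveform` — a channels x samples matrix covering
#'   `window_s` seconds after onset.
#' @export
make_erp_template <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  amps <- config$erp_amplitude_uV * config$channel_profile
  n <- round(config$window_s * config$fs_hz)
  t <- (seq_len(n) - 1) / config$fs_hz
  bump <- exp(-0.5 * ((t - config$erp_latency_s) / config$erp_width_s)^2)
  structure(list(latency_s = config$erp_latency_s,
                 width_s = config$erp_width_s,
                 amplitudes_uV = amps,
                 waveform = outer(amps, bump)),
            class = "erp_template")
}

#' Multi-channel EEG recording container
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param fs_hz sampling rate.
#' @param channel_labels character vector, one per channel.
#' @param markers data frame with columns `label` (one of S1..S5) and
#'   `position` (0-based sample index), sorted by position.
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, channel_labels = NULL,
                          markers = empty_markers()) {
  stopifnot(is.matrix(data), fs_hz > 0)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("Ch%d", seq_len(nrow(data)))
  }
  stopifnot(length(channel_labels) == nrow(data))
  if (nrow(markers) > 0) {
    stopifnot(all(markers$label %in% paste0("S", 1:5)),
              all(markers$position >= 0),
              all(markers$position < ncol(data)),
              !is.unsorted(markers$position))
  }
  structure(list(data = data, fs_hz = fs_hz,
                 channel_labels = channel_labels, markers = markers),
            class = "eeg_recording")
}

empty_markers <- function() {
  data.frame(label = character(), position = integer())
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              ncol(x$data) / x$fs_hz, nrow(x$markers)))
  invisible(x)
}

pink_noise <- function(n) {
  # 1/f spectral shaping of white Gaussian noise, unit variance
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))  # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)    # mirror for the negative-frequency half
  shaped <- spec / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic EEG recording for a hearing-test session
#'
#' Background noise plus, for each heard trial, the evoked-response
#' template added at the trial's onset sample. The marker stream follows
#' the hearing-test convention: S1/S3 at each left/right stimulus onset,
#' S2/S4 at the button press of heard trials, and S5 in the middle of the
#' pause between one trial's response window and the next onset (and after
#' the final trial).
#'
#' @param trials trial data frame from [run_session()] (columns `ear`,
#'   `heard`, `onset_s`, `response_s`).
#' @param config a [synth_config()].
#' @param seed RNG seed; identical seeds give bit-identical recordings.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(trials, config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"), nrow(trials) >= 1)
  if (nrow(trials) > 1) {
    isi <- diff(trials$onset_s)
    if (any(isi < config$window_s)) {
      stop("inter-stimulus interval shorter than the response window: ",
           "epochs would overlap")
    }
  }
  set.seed(seed)
  fs <- config$fs_hz
  # room after the last onset for its response window, the trailing S5
  # pause marker and that marker's own epoch window
  isi_med <- if (nrow(trials) > 1) stats::median(diff(trials$onset_s))
             else 2 * config$window_s
  tail_s <- isi_med + config$window_s / 2
  n_samp <- ceiling((max(trials$onset_s) + tail_s) * fs)
  nc <- config$n_channels

  if (config$noise_sigma_uV > 0) {
    data <- if (config$noise_kind == "white") {
      matrix(stats::rnorm(nc * n_samp, sd = config$noise_sigma_uV),
             nrow = nc)
    } else {
      t(vapply(seq_len(nc),
               function(i) config$noise_sigma_uV * pink_noise(n_samp),
               numeric(n_samp)))
    }
  } else {
    data <- matrix(0, nrow = nc, ncol = n_samp)
  }

  template <- make_erp_template(config)
  wf <- template$waveform
  wlen <- ncol(wf)

  labels <- character(0)
  positions <- numeric(0)
  onset_samples <- round(trials$onset_s * fs)
  for (i in seq_len(nrow(trials))) {
    pos <- onset_samples[i]
    labels <- c(labels, if (trials$ear[i] == "left") "S1" else "S3")
    positions <- c(positions, pos)
    if (trials$heard[i]) {
      span <- pos + seq_len(min(wlen, n_samp - pos)) # clipped at record end
      data[, span] <- data[, span] + wf[, seq_along(span), drop = FALSE]
      resp <- trials$response_s[i]
      if (is.na(resp)) {
        resp <- trials$onset_s[i] +
          max(0.05, stats::rnorm(1, config$response_latency_mean_s,
                                 config$response_latency_sd_s))
      }
      labels <- c(labels, if (trials$ear[i] == "left") "S2" else "S4")
      positions <- c(positions, round(resp * fs))
    }
    next_onset <- if (i < nrow(trials)) trials$onset_s[i + 1] else
      trials$onset_s[i] + tail_s
    pause_mid <- (trials$onset_s[i] + config$window_s + next_onset) / 2
    labels <- c(labels, "S5")
    positions <- c(positions, round(pause_mid * fs))
  }
  ord <- order(positions)
  markers <- data.frame(label = labels[ord],
                        position = as.integer(positions[ord]))
  markers <- markers[markers$position < n_samp, , drop = FALSE]
  eeg_recording(data, fs, markers = markers)
}
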