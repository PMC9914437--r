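#' Label the marker stream as heard / unheard events
#'
#' Each stimulus marker (S1 left, S3 right) becomes a stimulus event,
#' labeled `heard` iff the matching response marker (S2 for S1, S4 for S3)
#' occurs after it and before the next S1/S3/S5 marker. Each S5 pause
#' marker becomes a `silence` event, always labeled `unheard` — no sound
#' was playing, so nothing was heard.
#'
#' @param markers marker data frame (`label`, `position`), sorted by
#'   position, e.g. from an [eeg_recording()].
#' @return Data frame of events: `kind` (`left_stimulus`, `right_stimulus`,
#'   `silence`), `position` (0-based sample index), `label` (`heard`,
#'   `unheard`).
#' @export
label_events <- function(markers) {
  stopifnot(all(c("label", "position") %in% names(markers)),
            !is.unsorted(markers$position))
  kinds <- character(0)
  positions <- integer(0)
  labels <- character(0)
  open_stim <- NA_character_  # "S1"/"S3" awaiting a response, else NA
  open_idx <- NA_integer_
  for (i in seq_len(nrow(markers))) {
    lab <- markers$label[i]
    if (lab %in% c("S1", "S3")) {
      kinds <- c(kinds, if (lab == "S1") "left_stimulus" else "right_stimulus")
      positions <- c(positions, markers$position[i])
      labels <- c(labels, "unheard")
      open_stim <- lab
      open_idx <- length(labels)
    } else if (lab == "S5") {
      kinds <- c(kinds, "silence")
      positions <- c(positions, markers$position[i])
      labels <- c(labels, "unheard")
      open_stim <- NA_character_
    } else if (lab %in% c("S2", "S4")) {
      want <- if (lab == "S2") "S1" else "S3"
      if (is.na(open_stim) || open_stim != want) {
        stop("malformed marker stream: ", lab,
             " without a preceding open ", want, " stimulus")
      }
      labels[open_idx] <- "heard"
      open_stim <- NA_character_
    } else {
      stop("unknown marker label: ", lab)
    }
  }
  data.frame(kind = kinds, position = positions, label = labels)
}

#' Named channel-subset presets of the ablation design
#'
#' @param name `"1-16"`, `"1-13"` or `"1-8"`, or an integer vector of
#'   channel indices (returned as-is).
#' @return Integer vector of channel indices.
#' @export
channel_subset <- function(name = "1-16") {
  if (is.numeric(name)) return(as.integer(name))
  switch(name,
         "1-16" = 1:16,
         "1-13" = 1:13,
         "1-8"  = 1:8,
         stop("unknown channel subset: ", name,
              " (use \"1-16\", \"1-13\", \"1-8\" or an index vector)"))
}

#' Cut labeled epochs out of a recording
#'
#' An epoch is the window `[position, position + window_s)` of the chosen
#' channels, time-locked to an event. Events whose window would run past
#' the end of the recording are dropped with a warning.
#'
#' @param rec an [eeg_recording()] (normally already preprocessed).
#' @param events event data frame from [label_events()].
#' @param window_s epoch duration in seconds.
#' @param channels channel indices or a [channel_subset()] preset name.
#' @return An `epoch_set`: list with `data` (channels x samples x epochs
#'   array), `labels` (character), `kinds`, `positions`, `window_s`,
#'   `fs_hz`.
#' @export
extract_epochs <- function(rec, events, window_s = 0.7, channels = "1-16") {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0)
  chans <- channel_subset(channels)
  stopifnot(all(chans >= 1), all(chans <= nrow(rec$data)))
  wlen <- round(window_s * rec$fs_hz)
  n_samp <- ncol(rec$data)
  ok <- events$position + wlen <= n_samp
  if (any(!ok)) {
    warning(sum(!ok), " event(s) dropped: window exceeds the recording end")
    events <- events[ok, , drop = FALSE]
  }
  n <- nrow(events)
  data <- array(NA_real_, dim = c(length(chans), wlen, n))
  for (i in seq_len(n)) {
    at <- events$position[i]
    data[, , i] <- rec$data[chans, (at + 1):(at + wlen), drop = FALSE]
  }
  structure(list(data = data, labels = events$label, kinds = events$kind,
                 positions = events$position, window_s = window_s,
                 fs_hz = rec$fs_hz, channels = chans),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d heard / %d unheard), %d channels x %d samples\n",
              dim(x$data)[3], sum(x$labels == "heard"),
              sum(x$labels == "unheard"), dim(x$data)[1], dim(x$data)[2]))
  invisible(x)
}
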