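#' Frequency and intensity grids of the hearing test
#'
#' The test presents pure tones on a fixed grid of eight frequencies
#' (125 Hz to 12 kHz) crossed with twelve hearing levels (10 to 120 dB HL
#' in 10 dB steps), giving 96 candidate stimuli per ear.
#'
#' @name test_grid
NULL

#' @rdname test_grid
#' @export
audiometry_frequencies <- function() {
  c(125, 250, 500, 1000, 2000, 4000, 8000, 12000)
}

#' @rdname test_grid
#' @export
audiometry_intensities <- function() {
  seq(10, 120, by = 10)
}

#' Sentinel intensity encoding "never hears" (above the grid maximum)
#' @export
NO_RESPONSE_DB <- 130

#' Build the stimulus grid for a hearing-test session
#'
#' Constructs the initial test state: the full Cartesian product of the
#' frequency and intensity grids for each requested ear, an empty trial
#' log, and the current ear. When both ears are requested the left ear is
#' tested first and the right ear only after the left set is exhausted.
#'
#' @param ears character vector, nonempty subset of `c("left", "right")`.
#' @param frequencies_hz,intensities_db optional reduced grids (defaults:
#'   the full audiometric grids).
#' @return A `test_state` list with elements `remaining` (data frame of
#'   candidate stimuli: `ear`, `frequency_hz`, `intensity_db`), `trials`
#'   (data frame of presented trials, initially empty) and `current_ear`.
#' @export
build_grid <- function(ears = c("left", "right"),
                       frequencies_hz = audiometry_frequencies(),
                       intensities_db = audiometry_intensities()) {
  ears <- unique(as.character(ears))
  if (length(ears) == 0 || !all(ears %in% c("left", "right"))) {
    stop("`ears` must be a nonempty subset of c(\"left\", \"right\")")
  }
  ord <- c("left", "right")
  ears <- ord[ord %in% ears]
  remaining <- do.call(rbind, lapply(ears, function(e) {
    expand.grid(ear = e, frequency_hz = frequencies_hz,
                intensity_db = intensities_db,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(remaining) <- NULL
  structure(list(remaining = remaining,
                 trials = empty_trials(),
                 current_ear = ears[[1]],
                 ears = ears),
            class = "test_state")
}

empty_trials <- function() {
  data.frame(ear = character(), frequency_hz = numeric(),
             intensity_db = numeric(), heard = logical(),
             onset_s = numeric(), response_s = numeric())
}

#' Draw the next stimulus of a session
#'
#' Uniform random draw from the remaining stimuli of the current ear.
#' The ear switches only once the current ear's candidate set is empty;
#' `NULL` is returned when every requested ear is exhausted.
#'
#' @param state a `test_state`.
#' @return A one-row data frame (`ear`, `frequency_hz`, `intensity_db`),
#'   or `NULL` when the session is complete. Uses the R RNG stream; seed
#'   with [set.seed()] for reproducibility.
#' @export
next_stimulus <- function(state) {
  stopifnot(inherits(state, "test_state"))
  rem <- state$remaining
  for (ear in state$ears[match(state$current_ear, state$ears):length(state$ears)]) {
    idx <- which(rem$ear == ear)
    if (length(idx) > 0) {
      pick <- idx[sample.int(length(idx), 1)]
      return(rem[pick, , drop = FALSE])
    }
  }
  NULL
}

#' Record a response and prune the candidate set
#'
#' Removes the presented stimulus, appends a trial record, and applies the
#' pruning rules of the adaptive protocol: a heard tone removes all
#' not-yet-presented same-ear, same-frequency tones at higher intensity
#' (they would also be heard); an unheard tone removes all lower-intensity
#' ones (they would not be heard either). The ear advances when its
#' candidate set becomes empty.
#'
#' @param state a `test_state`.
#' @param stimulus one-row data frame as returned by [next_stimulus()].
#' @param heard logical.
#' @param onset_s stimulus onset, seconds from session start.
#' @param response_s button-press time (seconds), required iff `heard`.
#' @return The updated `test_state`.
#' @export
apply_response <- function(state, stimulus, heard, onset_s,
                           response_s = NA_real_) {
  stopifnot(inherits(state, "test_state"), is.logical(heard), length(heard) == 1)
  if (heard && (is.na(response_s) || response_s <= onset_s)) {
    stop("a heard trial requires response_s > onset_s")
  }
  if (!heard) response_s <- NA_real_
  rem <- state$remaining
  at <- rem$ear == stimulus$ear &
    rem$frequency_hz == stimulus$frequency_hz &
    rem$intensity_db == stimulus$intensity_db
  if (sum(at) != 1) {
    stop("protocol violation: stimulus not in the remaining candidate set")
  }
  same <- rem$ear == stimulus$ear & rem$frequency_hz == stimulus$frequency_hz
  drop <- at | (same & if (heard) rem$intensity_db > stimulus$intensity_db
                else rem$intensity_db < stimulus$intensity_db)
  state$remaining <- rem[!drop, , drop = FALSE]
  state$trials <- rbind(state$trials, data.frame(
    ear = stimulus$ear, frequency_hz = stimulus$frequency_hz,
    intensity_db = stimulus$intensity_db, heard = heard,
    onset_s = onset_s, response_s = response_s))
  while (!any(state$remaining$ear == state$current_ear)) {
    pos <- match(state$current_ear, state$ears)
    if (pos >= length(state$ears)) break
    state$current_ear <- state$ears[[pos + 1]]
  }
  state
}

#' Simulated listener with per-frequency hearing thresholds
#'
#' A listener is a per-ear, per-frequency threshold profile plus an
#' optional psychometric slope. With `slope_db = 0` the listener is
#' deterministic: a tone is heard iff its level is at or above threshold
#' (inclusive, so grid thresholds are exactly recoverable). With
#' `slope_db > 0` the tone is heard with probability
#' `plogis((intensity - threshold) / slope_db)`.
#'
#' @param thresholds data frame with columns `ear`, `frequency_hz`,
#'   `threshold_db`; use [NO_RESPONSE_DB] (130) for "never hears".
#' @param slope_db psychometric slope in dB; 0 for deterministic.
#' @return A `listener_model`.
#' @export
listener_model <- function(thresholds, slope_db = 0) {
  stopifnot(all(c("ear", "frequency_hz", "threshold_db") %in% names(thresholds)),
            slope_db >= 0)
  if (any(thresholds$threshold_db < 10 | thresholds$threshold_db > NO_RESPONSE_DB)) {
    stop("thresholds must lie in [10, ", NO_RESPONSE_DB, "]")
  }
  structure(list(thresholds = thresholds, slope_db = slope_db),
            class = "listener_model")
}

#' Uniform-threshold listener helper
#'
#' @param threshold_db single threshold applied at every ear/frequency.
#' @param ears ears to cover.
#' @param slope_db psychometric slope.
#' @export
flat_listener <- function(threshold_db, ears = c("left", "right"), slope_db = 0) {
  grid <- expand.grid(ear = ears, frequency_hz = audiometry_frequencies(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$threshold_db <- threshold_db
  listener_model(grid, slope_db = slope_db)
}

#' Simulate a listener's response to one stimulus
#'
#' @param model a [listener_model()].
#' @param stimulus one-row stimulus data frame.
#' @return Logical: heard or not (stochastic when `slope_db > 0`).
#' @export
simulate_listener <- function(model, stimulus) {
  stopifnot(inherits(model, "listener_model"))
  th <- model$thresholds
  hit <- th$ear == stimulus$ear & th$frequency_hz == stimulus$frequency_hz
  if (sum(hit) != 1) {
    stop("listener has no threshold for ", stimulus$ear, " ear at ",
         stimulus$frequency_hz, " Hz")
  }
  thr <- th$threshold_db[hit]
  if (model$slope_db == 0) {
    stimulus$intensity_db >= thr
  } else {
    stats::runif(1) < stats::plogis((stimulus$intensity_db - thr) / model$slope_db)
  }
}

#' Run a complete adaptive hearing-test session
#'
#' Loops draw / listen / prune until both ears are exhausted. Stimulus
#' onsets are spaced by `isi_s`; on heard trials the button press follows
#' the onset by a truncated-normal latency.
#'
#' @param model a [listener_model()].
#' @param ears ears to test (left first when both).
#' @param seed RNG seed for the whole session (scheduler, psychometric
#'   draws and response latencies).
#' @param isi_s inter-stimulus interval in seconds.
#' @param response_latency_mean_s,response_latency_sd_s button-press delay
#'   distribution (normal, truncated at 0.05 s).
#' @param frequencies_hz,intensities_db optional reduced grids.
#' @return Data frame of trials (`ear`, `frequency_hz`, `intensity_db`,
#'   `heard`, `onset_s`, `response_s`).
#' @export
run_session <- function(model, ears = c("left", "right"), seed = 1,
                        isi_s = 2.0,
                        response_latency_mean_s = 0.45,
                        response_latency_sd_s = 0.08,
                        frequencies_hz = audiometry_frequencies(),
                        intensities_db = audiometry_intensities()) {
  set.seed(seed)
  state <- build_grid(ears, frequencies_hz, intensities_db)
  onset <- isi_s  # leave one ISI of lead-in before the first tone
  repeat {
    stim <- next_stimulus(state)
    if (is.null(stim)) break
    heard <- simulate_listener(model, stim)
    resp <- NA_real_
    if (heard) {
      lat <- max(0.05, stats::rnorm(1, response_latency_mean_s,
                                    response_latency_sd_s))
      resp <- onset + lat
    }
    state <- apply_response(state, stim, heard, onset, resp)
    onset <- onset + isi_s
  }
  state$trials
}

#' Compute the audiogram from a completed session
#'
#' Per ear and frequency, the hearing threshold is the lowest intensity
#' among heard trials; a frequency with no heard trial is reported as
#' no-response (`NA`, exported as "NR").
#'
#' @param trials trial data frame from [run_session()].
#' @param frequencies_hz frequency grid to report.
#' @return Data frame `ear`, `frequency_hz`, `threshold_db` (`NA` = NR).
#' @export
compute_audiogram <- function(trials, frequencies_hz = audiometry_frequencies()) {
  ears <- unique(trials$ear)
  out <- expand.grid(ear = ears, frequency_hz = frequencies_hz,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$threshold_db <- vapply(seq_len(nrow(out)), function(i) {
    sel <- trials$ear == out$ear[i] &
      trials$frequency_hz == out$frequency_hz[i] & trials$heard
    if (any(sel)) min(trials$intensity_db[sel]) else NA_real_
  }, numeric(1))
  out <- out[order(match(out$ear, c("left", "right")), out$frequency_hz), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Session log and audiogram import/export
#'
#' CSV columns: `ear`, `frequency_hz`, `intensity_db`, `heard`, `onset_s`,
#' `response_s`; the JSON mirror holds the same records. Audiogram export
#' renders no-response thresholds as `"NR"`.
#'
#' @param trials,audiogram data frames as produced by [run_session()] and
#'   [compute_audiogram()].
#' @param path file path.
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_session_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$heard <- as.logical(df$heard)
  df$response_s <- as.numeric(df$response_s)
  df
}

#' @rdname session_io
#' @export
write_session_json <- function(trials, path) {
  jsonlite::write_json(trials, path, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname session_io
#' @export
read_session_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  df$response_s <- suppressWarnings(as.numeric(df$response_s))
  df
}

#' @rdname session_io
#' @export
write_audiogram_csv <- function(audiogram, path) {
  out <- audiogram
  out$threshold_db <- ifelse(is.na(out$threshold_db), "NR",
                             format(out$threshold_db, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
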