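#' Derive a per-stage seed from the global run seed
#'
#' One global seed fans out deterministically to every stochastic stage
#' via a polynomial hash of the stage name, so each stage is independently
#' reproducible.
#'
#' @param seed global integer seed.
#' @param stage stage name, e.g. `"session"`, `"eeg"`, `"split"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  h <- seed %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h)
}

#' Full run configuration
#'
#' Bundles every stage's parameters with their standard defaults: the
#' audiometric grids, 16 channels at 2000 Hz, 50 Hz notch, 1-12 Hz
#' band-pass, a 0.7 s epoch window, 70/30 split and 5-fold CV.
#'
#' @param listener a [listener_model()] for the simulated respondent.
#' @param ears ears to test.
#' @param isi_s inter-stimulus interval.
#' @param synth a [synth_config()].
#' @param filters a [filter_spec()].
#' @param window_s epoch window in seconds.
#' @param train_fraction,cv_folds evaluation split parameters.
#' @param subsets ablation channel subsets.
#' @param families classifier families.
#' @param balance class-balance the epoch set before evaluation.
#' @param seed global seed, fanned out with [derive_seed()].
#' @return A `run_config` list.
#' @export
run_config <- function(listener = flat_listener(50),
                       ears = c("left", "right"),
                       isi_s = 2.0,
                       synth = synth_config(),
                       filters = filter_spec(),
                       window_s = 0.7,
                       train_fraction = 0.7,
                       cv_folds = 5,
                       subsets = c("1-16", "1-13", "1-8"),
                       families = classifier_families(),
                       balance = TRUE,
                       seed = 1) {
  structure(list(listener = listener, ears = ears, isi_s = isi_s,
                 synth = synth, filters = filters, window_s = window_s,
                 train_fraction = train_fraction, cv_folds = cv_folds,
                 subsets = subsets, families = families, balance = balance,
                 seed = seed),
            class = "run_config")
}

#' Simulate a session and write its artifacts
#'
#' Runs the adaptive hearing test against the configured listener,
#' generates the synthetic EEG with markers, and writes the session CSV,
#' the audiogram CSV and the BrainVision triplet under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with `trials`, `audiogram`, `recording` and
#'   the written `paths`.
#' @export
cmd_simulate <- function(config = run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- run_session(config$listener, config$ears,
                        seed = derive_seed(config$seed, "session"),
                        isi_s = config$isi_s)
  rec <- generate_recording(trials, config$synth,
                            seed = derive_seed(config$seed, "eeg"))
  audiogram <- compute_audiogram(trials)
  paths <- list(session = file.path(out_dir, "session.csv"),
                audiogram = file.path(out_dir, "audiogram.csv"),
                recording = file.path(out_dir, "recording"))
  write_session_csv(trials, paths$session)
  write_audiogram_csv(audiogram, paths$audiogram)
  write_brainvision(rec, paths$recording)
  message(sprintf("simulated %d trials (%d heard), %d markers",
                  nrow(trials), sum(trials$heard), nrow(rec$markers)))
  invisible(list(trials = trials, audiogram = audiogram, recording = rec,
                 paths = paths))
}

#' Preprocess, epoch, featurize and evaluate a recording
#'
#' The full decoding pipeline: conditioning (notch, band-pass, normalize,
#' round), marker labeling, channel-ablation evaluation of the classifier
#' bank, and report export.
#'
#' @param config a [run_config()].
#' @param rec an [eeg_recording()], or a BrainVision base path to read.
#' @param out_dir optional directory for `report.csv` (formatted) and
#'   `report_raw.csv`.
#' @return The raw report data frame from [run_ablation()].
#' @export
cmd_evaluate <- function(config = run_config(), rec, out_dir = NULL) {
  if (is.character(rec)) rec <- read_brainvision(rec)
  pre <- preprocess_recording(rec, config$filters)
  events <- label_events(pre$markers)
  report <- run_ablation(pre, events, subsets = config$subsets,
                         window_s = config$window_s,
                         families = config$families,
                         train_fraction = config$train_fraction,
                         seed = derive_seed(config$seed, "split"),
                         cv_folds = config$cv_folds,
                         balance = config$balance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(format_report(report),
                     file.path(out_dir, "report.csv"), row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "report_raw.csv"),
                     row.names = FALSE)
  }
  report
}
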