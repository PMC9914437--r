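#' Write a recording as a BrainVision triplet
#'
#' Emits the three-file BrainVision container: `<base>.vhdr` (INI-style
#' header), `<base>.vmrk` (marker list) and `<base>.eeg` (binary samples).
#' Data are written as IEEE_FLOAT_32 in multiplexed orientation, which is
#' lossless for this pipeline at single precision. Marker positions are
#' 0-based in memory and 1-based in the files, per the format convention.
#'
#' @param rec an [eeg_recording()].
#' @param basepath path without extension; the three extensions are added.
#' @return `basepath`, invisibly.
#' @export
write_brainvision <- function(rec, basepath) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eeg  <- paste0(basepath, ".eeg")
  base <- basename(basepath)

  nc <- nrow(rec$data)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nc),
    # microseconds per sample
    sprintf("SamplingInterval=%s", format(1e6 / rec$fs_hz, trim = TRUE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nc), rec$channel_labels)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    sprintf("Mk1=New Segment,,1,1,%d", nc)
  )
  if (nrow(rec$markers) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$markers)) + 1L,
                        rec$markers$label,
                        rec$markers$position + 1L))
  }
  writeLines(mk, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: sample 1 of every channel, then sample 2, ...
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(basepath)
}

parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- character()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      out[[section]][key] <- val
    }
  }
  out
}

#' Read a BrainVision triplet
#'
#' Parses the `.vhdr` header, the `.vmrk` markers and the binary `.eeg`
#' payload. Both IEEE_FLOAT_32 and INT_16 (with per-channel resolution
#' scaling) binary formats are supported, in multiplexed or vectorized
#' orientation. Marker descriptions in the padded Recorder dialect
#' (`"S  1"`) normalize to the compact labels (`"S1"`); file positions are
#' 1-based and are converted to 0-based sample indices.
#'
#' @param basepath path without extension, or the path of the `.vhdr`.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(basepath) {
  basepath <- sub("\\.vhdr$", "", basepath)
  vhdr <- paste0(basepath, ".vhdr")
  if (!file.exists(vhdr)) stop("header file not found: ", vhdr)
  hdr <- parse_ini(readLines(vhdr, warn = FALSE, encoding = "UTF-8"))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  if (!identical(unname(ci["DataFormat"]), "BINARY")) {
    stop("only BINARY DataFormat is supported")
  }
  nc <- as.integer(ci["NumberOfChannels"])
  fs <- 1e6 / as.numeric(ci["SamplingInterval"])
  orientation <- toupper(ci["DataOrientation"])
  fmt <- toupper(bi["BinaryFormat"])

  chan <- hdr[["Channel Infos"]]
  labels <- sprintf("Ch%d", seq_len(nc))
  resolution <- rep(1, nc)
  if (!is.null(chan)) {
    for (i in seq_len(nc)) {
      entry <- chan[sprintf("Ch%d", i)]
      if (!is.na(entry)) {
        parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
        if (length(parts) >= 1 && nzchar(parts[1])) labels[i] <- parts[1]
        if (length(parts) >= 3 && nzchar(parts[3])) {
          resolution[i] <- as.numeric(parts[3])
        }
      }
    }
  }

  eeg <- file.path(paste0(basepath, ".eeg"))
  if (!file.exists(eeg)) {
    alt <- file.path(dirname(vhdr), ci["DataFile"])
    if (file.exists(alt)) eeg <- alt else stop("data file not found: ", eeg)
  }
  sz <- file.info(eeg)$size
  con <- file(eeg, "rb")
  raw <- switch(fmt,
    "IEEE_FLOAT_32" = readBin(con, numeric(), n = sz / 4, size = 4,
                              endian = "little"),
    "INT_16" = readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                       endian = "little"),
    {close(con); stop("unsupported BinaryFormat: ", fmt)})
  close(con)
  if (length(raw) %% nc != 0) {
    stop("data length ", length(raw), " is not a multiple of the ",
         nc, "-channel count")
  }
  ns <- length(raw) %/% nc
  data <- switch(orientation,
    "MULTIPLEXED" = matrix(raw, nrow = nc),
    "VECTORIZED"  = t(matrix(raw, nrow = ns)),
    stop("unsupported DataOrientation: ", orientation))
  if (fmt == "INT_16") data <- data * resolution
  rownames(data) <- NULL

  markers <- read_vmrk(paste0(basepath, ".vmrk"), ns)
  eeg_recording(data, fs, channel_labels = labels, markers = markers)
}

read_vmrk <- function(path, n_samples) {
  if (!file.exists(path)) return(empty_markers())
  mk <- parse_ini(readLines(path, warn = FALSE, encoding = "UTF-8"))
  entries <- mk[["Marker Infos"]]
  if (is.null(entries)) return(empty_markers())
  labels <- character(0)
  positions <- integer(0)
  for (val in entries) {
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (length(parts) < 3 || parts[1] != "Stimulus") next
    desc <- gsub("[[:space:]]+", "", parts[2])  # "S  1" -> "S1"
    labels <- c(labels, desc)
    positions <- c(positions, as.integer(parts[3]) - 1L)  # to 0-based
  }
  keep <- positions >= 0 & positions < n_samples
  markers <- data.frame(label = labels[keep], position = positions[keep])
  markers[order(markers$position), , drop = FALSE]
}

#' Export the marker stream as CSV
#'
#' @param rec an [eeg_recording()].
#' @param path output path; columns `label`, `position` (0-based),
#'   `time_s`.
#' @export
write_markers_csv <- function(rec, path) {
  df <- rec$markers
  df$time_s <- df$position / rec$fs_hz
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
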