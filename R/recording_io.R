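#' Construct a recording object
#'
#' @param signals channels x samples numeric matrix (row names optional).
#' @param fs Sampling rate in Hz.
#' @param channel_regions Character vector, one region name per channel;
#'   the EMG channel (if any) is named `"EMG"`.
#' @param emg_channel Optional 1-based index of the EMG channel.
#' @param subject_id,session_id Identifiers carried through the pipeline.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(signals, fs, channel_regions,
                          emg_channel = NULL,
                          subject_id = "subject", session_id = "session") {
  signals <- as.matrix(signals)
  if (length(channel_regions) != nrow(signals)) {
    stop("channel_regions must name every signal row", call. = FALSE)
  }
  if (is.null(emg_channel) && any(channel_regions == "EMG")) {
    emg_channel <- which(channel_regions == "EMG")[1L]
  }
  rownames(signals) <- make.unique(channel_regions)
  structure(list(signals = signals, fs = fs,
                 channel_regions = channel_regions,
                 emg_channel = emg_channel,
                 subject_id = subject_id, session_id = session_id),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat("LFP recording", x$subject_id, "/", x$session_id, "\n")
  cat(" ", nrow(x$signals), "channels x", ncol(x$signals), "samples at",
      x$fs, "Hz (", round(ncol(x$signals) / x$fs, 1), "s )\n")
  cat("  regions:", paste(unique(setdiff(x$channel_regions, "EMG")),
                          collapse = ", "), "\n")
  if (!is.null(x$emg_channel)) cat("  EMG channel:", x$emg_channel, "\n")
  invisible(x)
}

#' Write a recording as a raw array container plus JSON channel map
#'
#' Signals are stored channel-by-channel as little-endian float64 in
#' `<stem>.bin`; `<stem>.json` holds the sampling rate, channel-to-region
#' map, EMG channel and identifiers.
#'
#' @param rec An `lfp_recording`.
#' @param stem Output path without extension.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "lfp_recording"))
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  # row-major: channel 1's samples, then channel 2's, ...
  writeBin(as.double(t(rec$signals)), con, size = 8L, endian = "little")
  meta <- list(format = "electosleep-recording-v1",
               fs = rec$fs,
               n_channels = nrow(rec$signals),
               n_samples = ncol(rec$signals),
               channel_regions = rec$channel_regions,
               emg_channel = rec$emg_channel,
               subject_id = rec$subject_id,
               session_id = rec$session_id)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#'
#' @param stem Path without extension (expects `<stem>.bin` and
#'   `<stem>.json`).
#' @return An `lfp_recording`.
#' @export
read_recording <- function(stem) {
  jf <- paste0(stem, ".json")
  bf <- paste0(stem, ".bin")
  if (!file.exists(jf) || !file.exists(bf)) {
    stop("recording not found at ", stem, " (.bin/.json pair required)",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(bf, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(x) != n) {
    stop("recording ", stem, ": expected ", n, " samples, read ", length(x),
         call. = FALSE)
  }
  sig <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  lfp_recording(sig, fs = meta$fs, channel_regions = meta$channel_regions,
                emg_channel = meta$emg_channel,
                subject_id = meta$subject_id, session_id = meta$session_id)
}
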