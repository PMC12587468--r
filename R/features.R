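#' Detect outlying samples by a MAD threshold on the high-passed signal
#'
#' Each channel is 30 Hz high-pass filtered; samples whose absolute filtered
#' value exceeds `mad_multiplier` times the filtered signal's median absolute
#' deviation are flagged. Any 2 s window containing a flagged sample in any
#' LFP channel is marked invalid. A constant channel (MAD exactly 0) yields
#' no flags (the strict inequality against a zero threshold never fires) but
#' is reported as suspect.
#'
#' @param rec An `lfp_recording`.
#' @param highpass_hz High-pass cutoff in Hz (default 30).
#' @param mad_multiplier Threshold in MADs (default 20). The MAD here is the
#'   raw median absolute deviation (no normal-consistency constant).
#' @param window_s Window length for the per-window invalid flags.
#' @return An object of class `outlier_mask`: list with `sample_mask`
#'   (channels x samples logical, TRUE = outlier), `window_invalid`
#'   (logical per complete window), `suspect_channels`.
#' @export
detect_outliers <- function(rec, highpass_hz = 30, mad_multiplier = 20,
                            window_s = 2) {
  stopifnot(inherits(rec, "lfp_recording"))
  n <- ncol(rec$signals)
  if (n < 1L) stop("empty recording", call. = FALSE)
  bf <- signal::butter(4, highpass_hz / (rec$fs / 2), type = "high")
  mask <- matrix(FALSE, nrow(rec$signals), n)
  suspect <- character(0)
  for (ch in seq_len(nrow(rec$signals))) {
    hp <- signal::filtfilt(bf, rec$signals[ch, ])
    m <- stats::mad(hp, constant = 1)
    if (m == 0) {
      suspect <- c(suspect, rec$channel_regions[ch])
      next
    }
    mask[ch, ] <- abs(hp) > mad_multiplier * m
  }
  wlen <- as.integer(window_s * rec$fs)
  n_win <- n %/% wlen
  lfp_ch <- setdiff(seq_len(nrow(rec$signals)), rec$emg_channel)
  win_bad <- logical(n_win)
  if (n_win > 0L) {
    any_bad <- colSums(mask[lfp_ch, seq_len(n_win * wlen), drop = FALSE]) > 0
    win_bad <- colSums(matrix(any_bad, nrow = wlen)) > 0
  }
  structure(list(sample_mask = mask, window_invalid = win_bad,
                 suspect_channels = unique(suspect),
                 highpass_hz = highpass_hz, mad_multiplier = mad_multiplier,
                 window_s = window_s),
            class = "outlier_mask")
}

#' Average same-region channels in the time domain
#'
#' Collapses a multi-channel recording to one trace per region by the
#' sample-wise arithmetic mean of that region's non-excluded channels. The
#' EMG channel passes through unaveraged.
#'
#' @param rec An `lfp_recording`.
#' @param exclusions Character vector of channel row names to drop (e.g.
#'   saturated channels).
#' @return An `lfp_recording` with one channel per region (plus EMG).
#' @export
average_regions <- function(rec, exclusions = character(0)) {
  stopifnot(inherits(rec, "lfp_recording"))
  chn <- rownames(rec$signals)
  keep <- !(chn %in% exclusions)
  regions <- unique(setdiff(rec$channel_regions, "EMG"))
  out <- matrix(0, length(regions) + !is.null(rec$emg_channel),
                ncol(rec$signals))
  for (i in seq_along(regions)) {
    rows <- which(rec$channel_regions == regions[i] & keep)
    if (!length(rows)) {
      stop("region ", regions[i], " has no remaining channels after exclusions",
           call. = FALSE)
    }
    out[i, ] <- colMeans(rec$signals[rows, , drop = FALSE])
  }
  ch_regions <- regions
  emg <- NULL
  if (!is.null(rec$emg_channel)) {
    out[length(regions) + 1L, ] <- rec$signals[rec$emg_channel, ]
    ch_regions <- c(regions, "EMG")
    emg <- length(regions) + 1L
  }
  lfp_recording(out, fs = rec$fs, channel_regions = ch_regions,
                emg_channel = emg, subject_id = rec$subject_id,
                session_id = rec$session_id)
}

# Periodic Hann taper.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Per-window Welch cross-power spectral density feature tensor
#'
#' Segments each region trace into non-overlapping `window_s` windows and
#' computes, per window and per ordered region pair, the Welch estimate of
#' the cross-power spectral density over Hann-tapered, 50%-overlapping
#' segments of `segment_samples` samples. The stored feature is the
#' magnitude of the averaged complex cross-spectrum; the diagonal reduces to
#' the Welch power spectral density. Frequencies are the FFT grid multiples
#' of `fs / segment_samples` from 0 up to `f_max` inclusive -- 29 bins
#' spanning 0-54.69 Hz at the defaults (fs = 1000, segment 512,
#' f_max = 54.7). A trailing partial window is dropped.
#'
#' @param rec An `lfp_recording` with one channel per region (see
#'   [average_regions()]); the EMG channel, if present, is ignored.
#' @param mask Optional `outlier_mask`; its per-window invalid flags are
#'   carried into the tensor's `valid_mask`.
#' @param window_s Window length in seconds (default 2).
#' @param segment_samples Welch segment length (default 512).
#' @param overlap_fraction Segment overlap (default 0.5).
#' @param f_max Highest frequency kept, in Hz (default 54.7; must be below
#'   Nyquist).
#' @return An object of class `feature_tensor`: list with `values`
#'   (windows x R x R x F non-negative array, symmetric in the region
#'   indices), `freqs`, `regions`, `valid_mask`, `window_s`,
#'   `normalization_scalar` (NA until [median_normalize()]), and subject /
#'   session identifiers.
#' @export
welch_feature_tensor <- function(rec, mask = NULL, window_s = 2,
                                 segment_samples = 512L,
                                 overlap_fraction = 0.5, f_max = 54.7) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$fs
  if (f_max >= fs / 2) stop("f_max must be below the Nyquist frequency",
                            call. = FALSE)
  if (segment_samples <= 0 || window_s <= 0) {
    stop("segment and window lengths must be positive", call. = FALSE)
  }
  wlen <- as.integer(window_s * fs)
  if (segment_samples > wlen) {
    stop("segment_samples must not exceed the window length", call. = FALSE)
  }
  regions <- setdiff(rec$channel_regions, "EMG")
  Rn <- length(regions)
  traces <- rec$signals[match(regions, rownames(rec$signals)), , drop = FALSE]
  n_win <- ncol(traces) %/% wlen
  if (n_win < 1L) stop("recording shorter than one window", call. = FALSE)

  step <- as.integer(segment_samples * (1 - overlap_fraction))
  seg_starts <- seq(1L, wlen - segment_samples + 1L, by = step)
  n_seg <- length(seg_starts)
  taper <- hann_window(segment_samples)
  scale <- 1 / (fs * sum(taper^2))
  freqs_all <- (seq_len(segment_samples) - 1L) * fs / segment_samples
  fkeep <- which(freqs_all <= f_max + 1e-9 & freqs_all < fs / 2)
  Fb <- length(fkeep)
  freqs <- freqs_all[fkeep]

  vals <- array(0, dim = c(n_win, Rn, Rn, Fb))
  chunk <- max(1L, 512L %/% max(1L, n_seg))  # windows per FFT batch
  for (w0 in seq(1L, n_win, by = chunk)) {
    wins <- w0:min(w0 + chunk - 1L, n_win)
    nw <- length(wins)
    # segment matrix: segment_samples x (n_seg * Rn * nw)
    segmat <- matrix(0, segment_samples, n_seg * Rn * nw)
    col <- 0L
    for (wi in wins) {
      off <- (wi - 1L) * wlen
      for (r in seq_len(Rn)) {
        for (s in seq_len(n_seg)) {
          col <- col + 1L
          segmat[, col] <- traces[r, off + seg_starts[s] +
                                      seq_len(segment_samples) - 1L] * taper
        }
      }
    }
    Z <- stats::mvfft(segmat)[fkeep, , drop = FALSE]
    # A: Fb x n_seg x Rn x nw
    A <- array(Z, dim = c(Fb, n_seg, Rn, nw))
    for (i in seq_len(Rn)) {
      for (j in i:Rn) {
        M <- A[, , i, , drop = FALSE] * Conj(A[, , j, , drop = FALSE])
        dim(M) <- c(Fb, n_seg, nw)
        S <- colMeans(aperm(M, c(2L, 1L, 3L)))        # Fb x nw
        mag <- Mod(S) * scale
        mag[freqs > 0, ] <- 2 * mag[freqs > 0, , drop = FALSE]  # one-sided
        vals[wins, i, j, ] <- t(mag)
        if (j > i) vals[wins, j, i, ] <- t(mag)
      }
    }
  }
  valid <- rep(TRUE, n_win)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "outlier_mask"))
    nv <- min(n_win, length(mask$window_invalid))
    valid[seq_len(nv)] <- !mask$window_invalid[seq_len(nv)]
  }
  structure(list(values = vals, freqs = freqs, regions = regions,
                 valid_mask = valid, window_s = window_s,
                 normalization_scalar = NA_real_,
                 subject_id = rec$subject_id, session_id = rec$session_id),
            class = "feature_tensor")
}

#' Median-normalize a feature tensor
#'
#' Divides every entry by one scalar per (subject, session): the median of
#' all valid-window entries across windows, region pairs and frequencies.
#' This removes between-mouse and between-recording scale differences.
#'
#' @param tensor A `feature_tensor`.
#' @return The tensor, normalized, with the scalar stored in
#'   `normalization_scalar`.
#' @export
median_normalize <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (!any(tensor$valid_mask)) stop("no valid windows", call. = FALSE)
  med <- stats::median(tensor$values[tensor$valid_mask, , , ])
  if (med == 0) stop("degenerate recording: median feature value is 0",
                     call. = FALSE)
  tensor$values <- tensor$values / med
  tensor$normalization_scalar <- med
  tensor
}

#' Feature names for the flattened tensor
#' @param regions Region names.
#' @param freqs Frequency grid in Hz.
#' @return Character vector of length `length(regions)^2 * length(freqs)`.
#' @export
feature_names <- function(regions, freqs) {
  out <- character(length(regions)^2 * length(freqs))
  k <- 0L
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    out[k + seq_along(freqs)] <- sprintf("%s:%s:%.2fHz", regions[i],
                                         regions[j], freqs)
    k <- k + length(freqs)
  }
  out
}

#' Flatten a feature tensor to per-window vectors
#'
#' Row-major flattening of the full R x R x F block (both symmetric copies
#' retained): feature index runs frequency fastest, then the second region,
#' then the first. For the 8-region, 29-bin default this gives d = 1856
#' features per window.
#'
#' @param tensor A `feature_tensor`.
#' @return windows x (R^2 * F) numeric matrix with feature column names;
#'   attributes `regions` and `freqs` carry the grid.
#' @export
flatten_features <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  d <- dim(tensor$values)
  n_win <- d[1L]; Rn <- d[2L]; Fb <- d[4L]
  # aperm so that within a window the order is (i, j, f) with f fastest
  out <- matrix(aperm(tensor$values, c(4L, 3L, 2L, 1L)),
                nrow = n_win, byrow = TRUE)
  colnames(out) <- feature_names(tensor$regions, tensor$freqs)
  attr(out, "regions") <- tensor$regions
  attr(out, "freqs") <- tensor$freqs
  attr(out, "valid_mask") <- tensor$valid_mask
  out
}

#' Reshape a flattened feature vector back to a region x region x frequency
#' array
#'
#' Inverse of the per-window flattening used by [flatten_features()].
#'
#' @param v Numeric vector of length `R^2 * F`.
#' @param regions Region names (length R).
#' @param freqs Frequency grid (length F).
#' @return R x R x F array with dimnames.
#' @export
unflatten_features <- function(v, regions, freqs) {
  Rn <- length(regions); Fb <- length(freqs)
  stopifnot(length(v) == Rn^2 * Fb)
  arr <- aperm(array(v, dim = c(Fb, Rn, Rn)), c(3L, 2L, 1L))
  dimnames(arr) <- list(regions, regions, sprintf("%.2f", freqs))
  arr
}

#' Saturation screen for a channel
#'
#' Automated stand-in for manual inspection of poor channels: a channel is
#' suspect when more than `plateau_frac` of its samples sit at its extreme
#' plateau (within a small tolerance of the running min/max), as a clipped
#' or saturated amplifier produces. The high-frequency PSD slope is
#' reported as a diagnostic but does not by itself flag the channel.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param plateau_frac Plateau fraction threshold (default 0.01).
#' @return List with `saturated` (logical), `plateau_fraction`, and
#'   `psd_slope_highband` (log10-power per log10-Hz above 100 Hz).
#' @export
saturation_screen <- function(x, fs, plateau_frac = 0.01) {
  rng <- range(x)
  tol <- 1e-6 * max(diff(rng), .Machine$double.eps)
  pf <- mean(x >= rng[2L] - tol | x <= rng[1L] + tol)
  # PSD slope above 100 Hz (diagnostic only)
  n <- min(length(x), 2^15)
  sp <- Mod(stats::fft(x[seq_len(n)] - mean(x[seq_len(n)])))^2
  f <- (seq_len(n) - 1L) * fs / n
  band <- f > 100 & f < min(fs / 2, 400)
  slope <- if (sum(band) > 10) {
    stats::coef(stats::lm(log10(sp[band] + 1e-300) ~ log10(f[band])))[[2L]]
  } else NA_real_
  list(saturated = pf > plateau_frac, plateau_fraction = pf,
       psd_slope_highband = slope)
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("Feature tensor:", d[1L], "windows x", d[2L], "x", d[3L], "regions x",
      d[4L], "frequency bins (", x$freqs[1L], "-",
      round(x$freqs[length(x$freqs)], 2), "Hz )\n")
  cat("  subject:", x$subject_id, " valid windows:", sum(x$valid_mask), "/",
      d[1L], "\n")
  if (!is.na(x$normalization_scalar)) {
    cat("  median-normalized (scalar ", signif(x$normalization_scalar, 4),
        ")\n", sep = "")
  }
  invisible(x)
}
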