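#' Spectral profile of one sleep-wake state
#'
#' Describes the oscillatory content the generator gives a state: a set of
#' band-limited components (filtered Gaussian noise, not pure sinusoids, so
#' Welch estimates carry realistic variance), a broadband noise floor, and
#' the EMG tone (RMS of 30-250 Hz band-limited muscle noise) associated with
#' the state.
#'
#' @param state One of `"WAKE"`, `"NREM"`, `"REM"`.
#' @param components Data frame with columns `center` (Hz), `bandwidth` (Hz)
#'   and `amplitude` (a.u., RMS of the component), and optionally a
#'   `region_weights` list-column giving one multiplicative weight per region
#'   (default: all 1, i.e. the component appears equally in every region).
#' @param broadband_noise_sd Standard deviation of the white-noise floor (a.u.).
#' @param emg_tone RMS amplitude of the EMG channel during this state (a.u.).
#' @return An object of class `state_spectrum`.
#' @export
state_spectrum <- function(state, components, broadband_noise_sd, emg_tone) {
  state <- match.arg(state, sleep_states())
  stopifnot(is.data.frame(components),
            all(c("center", "bandwidth", "amplitude") %in% names(components)))
  if (nrow(components) < 1L) {
    stop("at least one band component per state", call. = FALSE)
  }
  if (any(components$amplitude < 0) || broadband_noise_sd < 0 || emg_tone < 0) {
    stop("amplitudes and noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(state = state, components = components,
                 broadband_noise_sd = broadband_noise_sd,
                 emg_tone = emg_tone),
            class = "state_spectrum")
}

#' Default state spectral profiles
#'
#' Wake: low-amplitude mixed-frequency activity with high muscle tone.
#' NREM: dominant high-amplitude 1-4 Hz (delta) activity, stronger in
#' cortical regions and ventral hippocampus, with low muscle tone.
#' REM: 6-12 Hz (theta) plus 18-26 and 42-50 Hz components with muscle
#' atonia. Amplitudes are generator choices, not measurements.
#'
#' @param regions Region names (used to size per-region component weights).
#' @return Named list of [state_spectrum()] objects, one per state.
#' @export
default_state_spectra <- function(regions = default_regions()) {
  R <- length(regions)
  w_all <- rep(1, R)
  # delta loads cortex + ventral hippocampus more than the deep structures
  w_delta <- ifelse(grepl("^Cx|HippV", regions), 1, 0.6)
  list(
    WAKE = state_spectrum(
      "WAKE",
      data.frame(center = 10, bandwidth = 14, amplitude = 0.6,
                 region_weights = I(list(w_all))),
      broadband_noise_sd = 1.0, emg_tone = 2.0),
    NREM = state_spectrum(
      "NREM",
      data.frame(center = 2.5, bandwidth = 3, amplitude = 3.0,
                 region_weights = I(list(w_delta))),
      broadband_noise_sd = 0.5, emg_tone = 0.5),
    REM = state_spectrum(
      "REM",
      data.frame(center = c(9, 22, 46), bandwidth = c(6, 8, 8),
                 amplitude = c(1.6, 0.9, 0.7),
                 region_weights = I(list(w_all, w_all, w_all))),
      broadband_noise_sd = 0.5, emg_tone = 0.1)
  )
}

#' Default sleep-wake transition matrix for the generator
#'
#' Strongly self-transitioning (diagonal near 0.98) with REM entered only
#' from NREM, matching the rule that REM epochs are preceded by NREM.
#'
#' @return 3x3 row-stochastic matrix over (WAKE, NREM, REM).
#' @export
default_transition_matrix <- function() {
  P <- rbind(c(0.980, 0.020, 0.000),
             c(0.015, 0.970, 0.015),
             c(0.030, 0.010, 0.960))
  dimnames(P) <- list(sleep_states(), sleep_states())
  P
}

#' Specification of a synthetic recording cohort
#'
#' Bundles everything the generator needs: cohort size, recording length,
#' sampling rate, the Markov chain over states, the region montage, the gain
#' of the across-region shared component (which creates synchrony), the
#' between-mouse log-normal gain spread, the artifact rate and the seed.
#'
#' @param n_mice Number of subjects (>= 1).
#' @param recording_length_s Recording duration per mouse in seconds.
#' @param fs Sampling rate in Hz (default 1000).
#' @param transition_matrix 3x3 row-stochastic matrix over (WAKE, NREM, REM).
#' @param region_names Ordered region names (default the 8-region montage).
#' @param shared_component_gain Gain of the across-region shared component;
#'   0 makes regions independent, larger values increase synchrony.
#' @param mouse_gain_sd SD of the per-(mouse, region) log-normal gain.
#' @param artifact_rate Expected artifacts per minute per channel.
#' @param window_s Label/window granularity in seconds (default 2).
#' @param seed Integer seed; all generator output is a pure function of
#'   (spec, seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 9L,
                        recording_length_s = 600,
                        fs = 1000,
                        transition_matrix = default_transition_matrix(),
                        region_names = default_regions(),
                        shared_component_gain = 1,
                        mouse_gain_sd = 0.2,
                        artifact_rate = 0.5,
                        window_s = 2,
                        seed = 1L) {
  if (n_mice < 1L) stop("n_mice must be >= 1", call. = FALSE)
  check_transition_matrix(transition_matrix)
  if (fs <= 0 || recording_length_s < window_s) {
    stop("need fs > 0 and recording_length_s >= window_s", call. = FALSE)
  }
  structure(list(n_mice = as.integer(n_mice),
                 recording_length_s = recording_length_s,
                 fs = fs,
                 transition_matrix = transition_matrix,
                 region_names = region_names,
                 shared_component_gain = shared_component_gain,
                 mouse_gain_sd = mouse_gain_sd,
                 artifact_rate = artifact_rate,
                 window_s = window_s,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a Markov state sequence
#'
#' Draws a per-window sleep-wake state sequence from the spec's transition
#' matrix; the initial state is drawn from the chain's stationary
#' distribution. Identical `(spec, n_windows, seed)` give identical output.
#'
#' @param spec A [cohort_spec()].
#' @param n_windows Number of 2 s windows (>= 1).
#' @param seed Integer seed (default: the spec's seed).
#' @return An object of class `ground_truth`: list with `states` (character
#'   vector of length `n_windows`), `onset` (0-based start sample of each
#'   window, half-open), `window_s` and `fs`.
#' @export
sample_state_sequence <- function(spec, n_windows, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_windows < 1L) stop("n_windows must be >= 1", call. = FALSE)
  P <- check_transition_matrix(spec$transition_matrix)
  set.seed(derive_seed(seed, "state-sequence"))
  pi0 <- stationary_distribution(P)
  s <- integer(n_windows)
  s[1L] <- sample.int(3L, 1L, prob = pi0)
  if (n_windows > 1L) {
    u <- stats::runif(n_windows - 1L)
    cumP <- t(apply(P, 1L, cumsum))
    for (t in 2:n_windows) {
      s[t] <- findInterval(u[t - 1L], cumP[s[t - 1L], ], left.open = TRUE) + 1L
    }
  }
  structure(list(states = sleep_states()[s],
                 onset = as.integer((seq_len(n_windows) - 1L) *
                                      spec$window_s * spec$fs),
                 window_s = spec$window_s,
                 fs = spec$fs),
            class = "ground_truth")
}

# Band-limited unit-RMS Gaussian noise via FFT masking.
band_noise <- function(n, fs, f_lo, f_hi) {
  if (f_hi >= fs / 2) stop("band edge must be below Nyquist", call. = FALSE)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) stop("degenerate band (no FFT bins in [", f_lo, ", ", f_hi, "])",
                   call. = FALSE)
  y / r
}

#' Synthesize one multi-channel recording
#'
#' Builds one LFP channel per region plus an EMG channel at the spec's
#' sampling rate. Within each window the region signal is the sum of (i)
#' band-limited oscillatory components of the active state's
#' [state_spectrum()], each a mixture of a region-independent trace and an
#' across-region shared trace weighted by `shared_component_gain`, (ii)
#' white broadband noise, all scaled by a per-(mouse, region) log-normal
#' gain. The EMG channel is 30-250 Hz noise whose RMS follows the active
#' state's `emg_tone`. Isolated high-amplitude artifact samples are injected
#' at `artifact_rate` per minute per channel.
#'
#' @param spec A [cohort_spec()].
#' @param state_specs Named list of [state_spectrum()] per state.
#' @param truth A `ground_truth` from [sample_state_sequence()].
#' @param mouse_index Which mouse of the cohort (1-based, affects seed/gains).
#' @return An object of class `lfp_recording`: list with `signals`
#'   (channels x samples matrix), `fs`, `channel_regions` (region per
#'   channel, `"EMG"` for the EMG channel), `emg_channel`, `subject_id`,
#'   `session_id`.
#' @export
synthesize_recording <- function(spec, state_specs = default_state_spectra(spec$region_names),
                                 truth, mouse_index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  miss <- setdiff(unique(truth$states), names(state_specs))
  if (length(miss)) stop("no state_spectrum for state(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  regions <- spec$region_names
  R <- length(regions)
  fs <- spec$fs
  wlen <- as.integer(spec$window_s * fs)
  n_win <- length(truth$states)
  n <- n_win * wlen
  set.seed(derive_seed(spec$seed, paste0("recording-", mouse_index)))

  state_idx <- match(truth$states, sleep_states())
  # per-(mouse, region) multiplicative gain, log-normal
  gains <- exp(stats::rnorm(R, sd = spec$mouse_gain_sd))

  # component table: one row per (state, component)
  comp <- do.call(rbind, lapply(sleep_states(), function(st) {
    sp <- state_specs[[st]]
    if (is.null(sp)) return(NULL)
    k <- nrow(sp$components)
    data.frame(state = st, idx = seq_len(k),
               center = sp$components$center,
               bandwidth = sp$components$bandwidth,
               amplitude = sp$components$amplitude)
  }))
  g <- spec$shared_component_gain
  mix_norm <- sqrt(1 + g^2)

  sig <- matrix(0, nrow = R + 1L, ncol = n)
  for (ci in seq_len(nrow(comp))) {
    st <- comp$state[ci]
    if (!any(truth$states == st)) next
    f_lo <- max(comp$center[ci] - comp$bandwidth[ci] / 2, 0.25)
    f_hi <- comp$center[ci] + comp$bandwidth[ci] / 2
    # amplitude envelope: the component is on only in its own state's windows
    amp_w <- ifelse(truth$states == st, comp$amplitude[ci], 0)
    env <- rep(amp_w, each = wlen)
    rw <- state_specs[[st]]$components$region_weights
    rw <- if (is.null(rw)) rep(1, R) else rw[[comp$idx[ci]]]
    if (length(rw) != R) stop("region_weights must have one entry per region",
                              call. = FALSE)
    shared <- band_noise(n, fs, f_lo, f_hi)
    for (r in seq_len(R)) {
      if (rw[r] == 0) next
      indep <- band_noise(n, fs, f_lo, f_hi)
      sig[r, ] <- sig[r, ] +
        env * rw[r] * (indep + g * shared) / mix_norm
    }
  }
  # broadband floor, state-dependent SD, independent across regions
  sd_w <- vapply(truth$states, function(st) state_specs[[st]]$broadband_noise_sd,
                 numeric(1))
  sd_env <- rep(sd_w, each = wlen)
  for (r in seq_len(R)) {
    sig[r, ] <- (sig[r, ] + sd_env * stats::rnorm(n)) * gains[r]
  }
  # EMG: band-limited 30-250 Hz noise with state-dependent RMS
  tone_w <- vapply(truth$states, function(st) state_specs[[st]]$emg_tone,
                   numeric(1))
  sig[R + 1L, ] <- band_noise(n, fs, 30, 250) * rep(tone_w, each = wlen)

  # isolated artifact samples, well above 20x the channel MAD
  minutes <- n / fs / 60
  for (ch in seq_len(R + 1L)) {
    n_art <- stats::rpois(1L, spec$artifact_rate * minutes)
    if (n_art > 0L) {
      at <- sample.int(n, n_art)
      amp <- 40 * stats::mad(sig[ch, ], constant = 1)
      sig[ch, at] <- sig[ch, at] + sample(c(-1, 1), n_art, TRUE) * amp
    }
  }
  rownames(sig) <- c(regions, "EMG")
  structure(list(signals = sig, fs = fs,
                 channel_regions = c(regions, "EMG"),
                 emg_channel = R + 1L,
                 subject_id = sprintf("mouse%02d", mouse_index),
                 session_id = "session01"),
            class = "lfp_recording")
}

#' Simulate a full cohort in memory
#'
#' @param spec A [cohort_spec()].
#' @param state_specs Named list of [state_spectrum()] per state.
#' @return List with one element per mouse, each a list
#'   `(recording, truth)`.
#' @export
simulate_cohort <- function(spec, state_specs = default_state_spectra(spec$region_names)) {
  n_win <- floor(spec$recording_length_s / spec$window_s)
  lapply(seq_len(spec$n_mice), function(m) {
    truth <- sample_state_sequence(spec, n_win,
                                   seed = derive_seed(spec$seed, m))
    rec <- synthesize_recording(spec, state_specs, truth, mouse_index = m)
    list(recording = rec, truth = truth)
  })
}

#' Ground truth as a hypnogram
#'
#' @param truth A `ground_truth` object.
#' @return A [hypnogram()] with the true labels.
#' @export
truth_hypnogram <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  hypnogram(truth$states, window_s = truth$window_s)
}

#' Write a fixture cohort to disk
#'
#' Writes, per mouse, a raw float64 signal container plus JSON channel map
#' (see [write_recording()]), a ground-truth hypnogram CSV, and one cohort
#' manifest JSON holding the spec, seeds and per-file MD5 hashes.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if missing).
#' @param state_specs Named list of [state_spectrum()] per state.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_fixture_cohort <- function(spec, out_dir,
                                 state_specs = default_state_spectra(spec$region_names)) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  cohort <- simulate_cohort(spec, state_specs)
  files <- character(0)
  for (m in seq_along(cohort)) {
    stem <- file.path(out_dir, sprintf("mouse%02d", m))
    write_recording(cohort[[m]]$recording, stem)
    hyp <- truth_hypnogram(cohort[[m]]$truth)
    hfile <- paste0(stem, "_hypnogram.csv")
    write_hypnogram(hyp, hfile)
    files <- c(files, paste0(stem, ".bin"), paste0(stem, ".json"), hfile)
  }
  spec_plain <- unclass(spec)
  spec_plain$transition_matrix <- as.vector(spec$transition_matrix)
  manifest <- list(
    package = "electosleep",
    spec = spec_plain,
    spec_hash = unname(digest_string(jsonlite::toJSON(spec_plain, digits = NA,
                                                      auto_unbox = TRUE))),
    seed = spec$seed,
    mouse_seeds = vapply(seq_len(spec$n_mice),
                         function(m) derive_seed(spec$seed, m), integer(1)),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

# md5 of a string (via a temp file; base tools only).
digest_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(s), f)
  unname(tools::md5sum(f))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_mice, "mice,",
      x$recording_length_s, "s at", x$fs, "Hz,",
      length(x$region_names), "regions\n")
  cat("  shared component gain:", x$shared_component_gain,
      " mouse gain SD:", x$mouse_gain_sd,
      " artifacts/min:", x$artifact_rate, "\n")
  invisible(x)
}
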