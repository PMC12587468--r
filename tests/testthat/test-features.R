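make_rec <- function(signals, fs = 1000, regions = NULL, emg = NULL) {
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(signals)))
  lfp_recording(signals, fs = fs, channel_regions = regions,
                emg_channel = emg)
}

test_that("MAD outlier detection flags exactly the planted spike", {
  set.seed(101)
  x <- rnorm(10000)
  x[5000] <- 50
  rec <- make_rec(rbind(x))
  mask <- detect_outliers(rec)
  expect_identical(which(mask$sample_mask[1, ]), 5000L)
  expect_true(mask$window_invalid[3])          # window containing sample 5000
  expect_identical(sum(mask$window_invalid), 1L)

  # threshold is scale-equivariant: scaling the channel changes nothing
  mask10 <- detect_outliers(make_rec(rbind(10 * x)))
  expect_identical(mask$sample_mask, mask10$sample_mask)

  # constant channel: no flags, but reported suspect
  mask0 <- detect_outliers(make_rec(rbind(rep(0, 4000))))
  expect_false(any(mask0$sample_mask))
  expect_identical(mask0$suspect_channels, "R1")
})

test_that("region averaging is the sample-wise mean of retained channels", {
  a <- sin(seq_len(4000) / 50)
  b <- cos(seq_len(4000) / 30)
  rec <- lfp_recording(rbind(a, a, b), fs = 1000,
                       channel_regions = c("CxPrL", "CxPrL", "HippV"))
  avg <- average_regions(rec)
  expect_equal(avg$signals["CxPrL", ], a, ignore_attr = TRUE)

  rec2 <- lfp_recording(rbind(a, b), fs = 1000,
                        channel_regions = c("CxPrL", "CxPrL"))
  avg2 <- average_regions(rec2)
  expect_equal(avg2$signals["CxPrL", ], (a + b) / 2, ignore_attr = TRUE)
  avg3 <- average_regions(rec2, exclusions = "CxPrL")   # first channel out
  expect_equal(avg3$signals["CxPrL", ], b, ignore_attr = TRUE)
  expect_error(average_regions(rec2, exclusions = c("CxPrL", "CxPrL.1")),
               "no remaining channels")
})

test_that("Welch grid has 29 bins to 54.7 Hz and the CSD degenerates to the
           PSD for identical traces", {
  set.seed(11)
  x <- rnorm(8000)
  rec <- make_rec(rbind(x, x), regions = c("A", "B"))
  tens <- welch_feature_tensor(rec)
  expect_identical(length(tens$freqs), 29L)
  expect_identical(tens$freqs, (0:28) * 1000 / 512)
  expect_lte(max(tens$freqs), 54.7)
  expect_equal(tens$values[, 1, 2, ], tens$values[, 1, 1, ], tolerance = 1e-12)
  # symmetry and non-negativity
  expect_identical(tens$values[, 2, 1, ], tens$values[, 1, 2, ])
  expect_true(all(tens$values >= 0))
  expect_error(welch_feature_tensor(rec, f_max = 600), "Nyquist")
})

test_that("independent white-noise regions show low synchrony relative to
           power", {
  set.seed(12)
  x <- rnorm(20000); y <- rnorm(20000)
  rec <- make_rec(rbind(x, y), regions = c("A", "B"))
  tens <- welch_feature_tensor(rec)
  # the averaged cross-spectrum magnitude shrinks toward 0 for independent
  # signals: with m effectively independent segments the residual ratio is
  # about sqrt(pi/4)/sqrt(m); 6 half-overlapping Hann segments give ~0.38
  expect_lt(mean(tens$values[, 1, 2, ]),
            0.45 * mean((tens$values[, 1, 1, ] + tens$values[, 2, 2, ]) / 2))

  # independent oracle: direct Hann-tapered FFT segment averaging on the
  # same data reproduces the implementation bin-for-bin
  oracle_csd <- function(a, b, fs = 1000, nseg = 512, step = 256) {
    taper <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)
    starts <- seq(1, length(a) - nseg + 1, by = step)
    acc <- complex(real = rep(0, nseg))
    for (s in starts) {
      fa <- fft(a[s:(s + nseg - 1)] * taper)
      fb <- fft(b[s:(s + nseg - 1)] * taper)
      acc <- acc + fa * Conj(fb)
    }
    mag <- Mod(acc / length(starts)) / (fs * sum(taper^2))
    mag <- mag[1:29]
    mag[-1] <- 2 * mag[-1]
    mag
  }
  w <- 3  # arbitrary window
  sel <- (w - 1) * 2000 + 1:2000
  expect_equal(tens$values[w, 1, 2, ], oracle_csd(x[sel], y[sel]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tens$values[w, 1, 1, ], oracle_csd(x[sel], x[sel]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("diagonal PSD satisfies Parseval for broadband noise", {
  set.seed(13)
  x <- rnorm(4000)
  rec <- make_rec(rbind(x))
  tens <- welch_feature_tensor(rec, f_max = 499.9)
  df <- 1000 / 512
  for (w in 1:2) {
    seg <- x[(w - 1) * 2000 + 1:2000]
    expect_equal(sum(tens$values[w, 1, 1, ]) * df, var(seg),
                 tolerance = 0.1 * var(seg))
  }
})

test_that("a bin-centered sinusoid concentrates its power within one bin", {
  fs <- 1000; f0 <- 10 * fs / 512              # exactly bin 10
  t <- seq_len(4000) / fs
  rec <- make_rec(rbind(sin(2 * pi * f0 * t)))
  tens <- welch_feature_tensor(rec)
  p <- tens$values[1, 1, 1, ]
  hit <- which.max(p)
  expect_equal(tens$freqs[hit], f0)
  expect_gte(sum(p[(hit - 1):(hit + 1)]) / sum(p), 0.9)
})

test_that("median normalization yields unit median and scale invariance", {
  set.seed(14)
  x <- rnorm(8000); y <- rnorm(8000)
  rec <- make_rec(rbind(x, y), regions = c("A", "B"))
  tens <- median_normalize(welch_feature_tensor(rec))
  expect_equal(median(tens$values[tens$valid_mask, , , ]), 1)
  # scaling the signals by g scales raw features by g^2, normalized unchanged
  recg <- make_rec(rbind(3 * x, 3 * y), regions = c("A", "B"))
  tensg <- median_normalize(welch_feature_tensor(recg))
  expect_equal(tensg$values, tens$values, tolerance = 1e-10)
  expect_equal(tensg$normalization_scalar / tens$normalization_scalar, 9,
               tolerance = 1e-10)

  const <- welch_feature_tensor(make_rec(rbind(rep(0, 4000))))
  expect_error(median_normalize(const), "median")
})

test_that("flattening gives d = R^2 * F and round-trips", {
  fx <- cohort6_fixture()
  flat <- flatten_features(fx$tensors[[1]])
  expect_identical(ncol(flat), 1856L)           # 8^2 x 29, not the 1044
  expect_false(ncol(flat) == 36L * 29L)         # unique-pair count rejected
  arr <- unflatten_features(flat[3, ], fx$tensors[[1]]$regions,
                            fx$tensors[[1]]$freqs)
  expect_equal(arr, fx$tensors[[1]]$values[3, , , ], ignore_attr = TRUE)

  # single-region power-only input is length F = 29
  sr <- single_region_features(fx$tensors[[1]], "Amy")
  expect_identical(ncol(sr), 29L)
})

test_that("saturation screen flags a clipped channel but not noise", {
  set.seed(15)
  clipped <- pmin(pmax(3 * sin(seq_len(8000) / 20), -1), 1)
  expect_true(saturation_screen(clipped, 1000)$saturated)
  expect_false(saturation_screen(rnorm(8000), 1000)$saturated)
})
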