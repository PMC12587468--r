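sine_rec <- function(lfp_hz, emg_hz = NULL, emg_amp = 1, n = 4000,
                     fs = 1000) {
  t <- seq_len(n) / fs
  lfp <- sin(2 * pi * lfp_hz * t)
  emg <- if (is.null(emg_hz)) rnorm(n, sd = 1e-3) else
    emg_amp * sin(2 * pi * emg_hz * t)
  lfp_recording(rbind(lfp, emg), fs = fs,
                channel_regions = c("CxPrL", "EMG"))
}

test_that("state-map features recover band powers of pure tones", {
  rec <- sine_rec(lfp_hz = 2, emg_hz = 100, emg_amp = 2)
  pts <- statemap_features(rec, "CxPrL")
  # 100 Hz sine of amplitude a: power a^2/2, all in the 60-250 Hz term
  expect_equal(pts$emg_power, rep(2, nrow(pts)), tolerance = 1e-6)
  # 2 Hz reference: all 0.5-9 Hz power lies below 4.5 Hz
  expect_equal(pts$ratio_x, rep(1, nrow(pts)), tolerance = 1e-6)
  expect_equal(pts$lfp_rms, rep(sqrt(0.5), nrow(pts)), tolerance = 1e-3)

  pts7 <- statemap_features(sine_rec(lfp_hz = 7), "CxPrL")
  expect_lt(max(pts7$ratio_x), 0.01            # 7 Hz is outside 0.5-4.5
  )
  norec <- lfp_recording(rbind(rnorm(4000)), fs = 1000,
                         channel_regions = "CxPrL")
  expect_error(statemap_features(norec, "CxPrL"), "autoencoder")
})

test_that("polygon assignment follows map-1 membership with map-2 NREM veto", {
  square <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0),
                                           c(y0, y0, y1, y1))
  polys <- polygon_set(list(list(
    unlabelable = FALSE,
    map1 = list(WAKE = square(0, 1, 10, 20),
                NREM = square(5, 7, 0, 1),
                REM = square(0, 1, 0, 1)),
    map2 = list(NREM = square(0.5, 1, 0.5, 1)))), segment_windows = 1800L)
  pts <- data.frame(window_index = 0:4,
                    lfp_rms = c(0.5, 6, 6, 0.5, 3),
                    emg_power = c(15, 0.5, 0.5, 0.5, 5),
                    ratio_x = c(0.1, 0.8, 0.1, 0.1, 0.1),
                    ratio_y = c(0.2, 0.9, 0.2, 0.2, 0.2),
                    window_s = 2)
  class(pts) <- c("statemap_points", "data.frame")
  hyp <- assign_by_polygons(pts, polys)
  expect_identical(hyp$label,
                   c("WAKE",       # in WAKE polygon, map2 irrelevant
                     "NREM",       # NREM polygon + map2 NREM polygon
                     "UNKNOWN",    # NREM polygon but fails map-2 veto
                     "REM",        # REM polygon; map2 not consulted
                     "UNKNOWN"))   # outside every polygon
  # invariant to point order
  perm <- c(3, 1, 5, 2, 4)
  hyp2 <- assign_by_polygons(pts[perm, ], polys)
  expect_identical(hyp2$label, hyp$label[perm])
})

test_that("boundary points count as inside (even-odd rule)", {
  vx <- c(0, 2, 2, 0); vy <- c(0, 0, 2, 2)
  inside <- electosleep:::point_in_polygon(c(1, 0, 2, 3, 1), c(1, 0, 1, 1, 2),
                                           vx, vy)
  expect_identical(inside, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("automatic polygons label the synthetic cohort accurately", {
  fx <- cohort6_fixture()
  pts <- statemap_features(fx$rec1, "CxPrL")
  polys <- auto_polygons(pts, seed = 4)
  hyp <- assign_by_polygons(pts, polys)
  truth <- fx$truth1$states
  unk <- mean(hyp$label == unknown_state())
  expect_lte(unk, 0.20)
  keep <- hyp$label != unknown_state()
  per_state <- vapply(sleep_states(), function(st) {
    n <- sum(truth == st & keep)
    sum(truth == st & hyp$label == st & keep) / n
  }, numeric(1))
  expect_true(all(per_state >= 0.95))
  expect_gte(mean(per_state) * 100, 90)

  # clustering is invariant to duplicating every point
  pts2 <- rbind(pts, pts)
  pts2$window_index <- seq_len(nrow(pts2)) - 1L
  class(pts2) <- c("statemap_points", "data.frame")
  polys2 <- auto_polygons(pts2, segment_windows = nrow(pts2), seed = 4)
  p1 <- auto_polygons(pts, segment_windows = nrow(pts2), seed = 4)
  expect_equal(polys2$segments[[1]]$map1, p1$segments[[1]]$map1,
               tolerance = 1e-8)
})

test_that("segments without three separable clusters are unlabelable", {
  set.seed(31)
  n <- 200
  pts <- data.frame(window_index = 0:(n - 1),
                    lfp_rms = exp(rnorm(n, 0, 0.05)),
                    emg_power = exp(rnorm(n, 0, 0.05)),
                    ratio_x = runif(n, 0.4, 0.6),
                    ratio_y = runif(n, 0.4, 0.6), window_s = 2)
  class(pts) <- c("statemap_points", "data.frame")
  polys <- auto_polygons(pts, seed = 1)
  expect_true(polys$segments[[1]]$unlabelable)
  # and too few points per segment
  polys2 <- auto_polygons(pts[1:50, ], seed = 1)
  expect_true(polys2$segments[[1]]$unlabelable)
})

test_that("stronger EMG contrast shrinks the UNKNOWN fraction", {
  unk_frac <- function(wake_tone) {
    spec <- cohort_spec(n_mice = 1, recording_length_s = 240,
                        artifact_rate = 0, seed = 6)
    sp <- default_state_spectra()
    sp$WAKE$emg_tone <- wake_tone
    truth <- sample_state_sequence(spec, 120, seed = 6)
    rec <- synthesize_recording(spec, sp, truth)
    pts <- statemap_features(rec, "CxPrL")
    hyp <- assign_by_polygons(pts, auto_polygons(pts, seed = 2))
    mean(hyp$label == unknown_state())
  }
  # wake EMG tone barely above NREM's vs the default strong contrast
  expect_gte(unk_frac(0.7), unk_frac(2.0))
})

test_that("Cohen's kappa matches hand and brute-force computation", {
  a <- c("WAKE", "WAKE", "NREM", "NREM", "REM", "REM")
  b <- c("WAKE", "WAKE", "NREM", "NREM", "REM", "NREM")
  expect_equal(cohen_kappa(a, b), 0.75)        # (5/6 - 1/3)/(1 - 1/3)
  expect_equal(cohen_kappa(a, a), 1)
  # one constant sequence has no skill against a balanced one
  expect_lte(cohen_kappa(rep("WAKE", 6), a), 0)
  # random sequences against the enumeration oracle
  set.seed(32)
  for (i in 1:20) {
    x <- sample(sleep_states(), 60, TRUE)
    y <- sample(sleep_states(), 60, TRUE)
    expect_equal(cohen_kappa(x, y), oracle_kappa(x, y))
  }
  # UNKNOWN windows dropped pairwise
  expect_equal(cohen_kappa(c(a, "UNKNOWN"), c(b, "WAKE")),
               cohen_kappa(a, b))
  expect_error(cohen_kappa(rep("UNKNOWN", 3), rep("WAKE", 3)),
               "no overlapping")
})

test_that("polygon sets round-trip through JSON", {
  fx <- cohort6_fixture()
  pts <- statemap_features(fx$rec1, "CxPrL")
  polys <- auto_polygons(pts, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_polygons(polys, path)
  polys2 <- read_polygons(path)
  expect_equal(polys2$segments[[1]]$map1$WAKE,
               unname(polys$segments[[1]]$map1$WAKE),
               ignore_attr = TRUE, tolerance = 1e-12)
  hyp1 <- assign_by_polygons(pts, polys)
  hyp2 <- assign_by_polygons(pts, polys2)
  expect_identical(hyp1$label, hyp2$label)
})
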