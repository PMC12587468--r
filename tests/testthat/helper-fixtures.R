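# Shared fixtures, memoized so expensive synthetic cohorts are built once
# per test run.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# The default synthetic cohort used for classifier validation: 6 mice,
# default spectra/transitions, ground-truth labels; features extracted with
# the default outlier -> average -> Welch -> median-normalize chain.
cohort6_fixture <- function() memo_fixture("cohort6", function() {
  spec <- cohort_spec(n_mice = 6)
  coh <- simulate_cohort(spec)
  tensors <- vector("list", 6L)
  truths <- vector("list", 6L)
  for (m in 1:6) {
    rec <- coh[[m]]$recording
    mask <- detect_outliers(rec)
    tensors[[m]] <- median_normalize(
      welch_feature_tensor(average_regions(rec), mask))
    truths[[m]] <- coh[[m]]$truth
  }
  list(spec = spec, tensors = tensors, truths = truths,
       rec1 = coh[[1]]$recording, truth1 = coh[[1]]$truth)
})

# Stacked training data for mice 1-5 of the cohort fixture.
cohort6_train <- function() memo_fixture("cohort6_train", function() {
  fx <- cohort6_fixture()
  X <- do.call(rbind, lapply(fx$tensors[1:5], flatten_features))
  attr(X, "regions") <- fx$tensors[[1]]$regions
  attr(X, "freqs") <- fx$tensors[[1]]$freqs
  attr(X, "valid_mask") <- unlist(lapply(fx$tensors[1:5], `[[`, "valid_mask"))
  y <- unlist(lapply(fx$truths[1:5], `[[`, "states"))
  truth6 <- fx$truths[[6]]$states
  truth6[!fx$tensors[[6]]$valid_mask] <- unknown_state()
  list(X = X, y = y, test_tensor = fx$tensors[[6]], test_truth = truth6)
})

# Network model trained on mice 1-5 (held-out mouse 6).
sae_model6 <- function() memo_fixture("sae_model6", function() {
  tr <- cohort6_train()
  electome_sae(tr$X, tr$y, mu = 1e-2,
               config = sae_config(epochs = 150, seed = 11))
})

# --- independent oracles -------------------------------------------------

# Brute-force transition frequencies by direct pair counting.
oracle_transition_freqs <- function(labels) {
  s <- match(labels, sleep_states())
  out <- matrix(0, 3, 3)
  for (t in seq_len(length(s) - 1L)) {
    out[s[t], s[t + 1L]] <- out[s[t], s[t + 1L]] + 1
  }
  out / pmax(rowSums(out), 1)
}

# Exhaustive enumeration oracle for the best-scoring state sequences.
oracle_enumerate_paths <- function(probs, trans, k) {
  n <- nrow(probs)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  logpi <- log(stationary_distribution(unclass(trans)))
  logT <- log(unclass(trans))
  scores <- apply(grid, 1L, function(s) {
    v <- logpi[s[1]] + sum(log(probs[cbind(seq_len(n), s)]))
    if (n > 1L) v <- v + sum(logT[cbind(s[-n], s[-1L])])
    v
  })
  ord <- order(scores, decreasing = TRUE)
  list(paths = matrix(sleep_states()[grid[ord[seq_len(k)], , drop = FALSE]],
                      nrow = k),
       scores = scores[ord[seq_len(k)]])
}

# Direct periodogram band power (rectangular taper, full trace).
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  half <- seq_len(n %/% 2 + 1L)
  p <- p[half]
  p[-1L] <- 2 * p[-1L]
  f <- (half - 1L) * fs / n
  sum(p[f >= lo & f <= hi])
}

# Brute-force Cohen's kappa by explicit probability bookkeeping.
oracle_kappa <- function(a, b) {
  lv <- sleep_states()
  po <- mean(a == b)
  pe <- sum(vapply(lv, function(s) mean(a == s) * mean(b == s), numeric(1)))
  (po - pe) / (1 - pe)
}

# Run-length bout decomposition.
oracle_bouts <- function(labels) {
  r <- rle(labels)
  data.frame(state = r$values, length = r$lengths)[r$values %in%
                                                     sleep_states(), ]
}
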