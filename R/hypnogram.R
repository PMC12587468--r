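#' Construct a hypnogram
#'
#' A hypnogram is a per-window sequence of sleep-wake state labels, with
#' optional per-state probabilities (a "hypnodensity") and an optional
#' smoothed label track.
#'
#' @param labels Character vector of `"WAKE"`, `"NREM"`, `"REM"` or
#'   `"UNKNOWN"` per window.
#' @param probs Optional windows x 3 matrix of state probabilities in
#'   (WAKE, NREM, REM) order; rows must be non-negative and sum to 1
#'   (rows for UNKNOWN windows may be NA).
#' @param window_s Window length in seconds (default 2).
#' @return A data frame of class `hypnogram` with columns `window_index`
#'   (0-based), `start_s`, `end_s`, `label` and, when given, `p_wake`,
#'   `p_nrem`, `p_rem`.
#' @export
hypnogram <- function(labels, probs = NULL, window_s = 2) {
  labels <- as_state_labels(labels)
  n <- length(labels)
  out <- data.frame(window_index = seq_len(n) - 1L,
                    start_s = (seq_len(n) - 1L) * window_s,
                    end_s = seq_len(n) * window_s,
                    label = labels,
                    stringsAsFactors = FALSE)
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    stopifnot(nrow(probs) == n, ncol(probs) == 3L)
    ok <- stats::complete.cases(probs)
    if (any(ok)) {
      bad <- ok & (abs(rowSums(probs) - 1) > 1e-6 |
                     apply(probs, 1, function(r) any(r < -1e-12)))
      if (any(bad)) stop("probabilities must be >= 0 and sum to 1 per window",
                         call. = FALSE)
    }
    out$p_wake <- probs[, 1L]
    out$p_nrem <- probs[, 2L]
    out$p_rem <- probs[, 3L]
  }
  class(out) <- c("hypnogram", "data.frame")
  out
}

hypnogram_probs <- function(hyp) {
  if (!all(c("p_wake", "p_nrem", "p_rem") %in% names(hyp))) return(NULL)
  as.matrix(hyp[, c("p_wake", "p_nrem", "p_rem")])
}

#' Write / read hypnogram CSV
#'
#' Plain CSV with columns `window_index`, `start_s`, `end_s`, `label`, and
#' any of `p_wake`, `p_nrem`, `p_rem`, `smoothed_label`, `confidence`
#' present.
#'
#' @param hyp A `hypnogram`.
#' @param path CSV file path.
#' @return `path` (write) or a `hypnogram` (read).
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.csv(as.data.frame(hyp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_index", "start_s", "end_s", "label")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$label <- as_state_labels(df$label)
  class(df) <- c("hypnogram", "data.frame")
  df
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- nrow(x)
  cat("Hypnogram:", n, "windows of",
      if (n) x$end_s[1] - x$start_s[1] else NA, "s\n")
  tab <- table(factor(x$label, levels = c(sleep_states(), unknown_state())))
  cat(" ", paste(sprintf("%s %.1f%%", names(tab), 100 * tab / max(n, 1)),
                 collapse = "  "), "\n")
  if ("smoothed_label" %in% names(x)) cat("  (smoothed track present)\n")
  invisible(x)
}

#' Estimate a sleep-stage transition matrix from labeled hypnograms
#'
#' Counts consecutive labeled (state_t, state_t+1) window pairs, applies
#' add-constant smoothing, and row-normalizes. UNKNOWN windows break
#' adjacency: pairs spanning one are not counted.
#'
#' @param labels A hypnogram, a character label vector, or a list of either
#'   (e.g. several recordings); transitions are pooled.
#' @param smoothing Add-constant applied to every cell before normalizing
#'   (default 1, so rare transitions stay representable).
#' @return 3x3 row-stochastic matrix of class `transition_matrix`, with the
#'   raw pair counts in attribute `counts`.
#' @export
estimate_transitions <- function(labels, smoothing = 1) {
  if (!is.list(labels) || inherits(labels, "hypnogram")) labels <- list(labels)
  counts <- matrix(0, 3L, 3L, dimnames = list(sleep_states(), sleep_states()))
  for (seqi in labels) {
    lab <- as_state_labels(seqi)
    idx <- match(lab, sleep_states())           # NA for UNKNOWN
    a <- idx[-length(idx)]
    b <- idx[-1L]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      counts <- counts + unclass(table(factor(a[ok], levels = 1:3),
                                       factor(b[ok], levels = 1:3)))
    }
  }
  if (sum(counts) == 0) {
    stop("no consecutive labeled window pairs to estimate transitions from",
         call. = FALSE)
  }
  sm <- counts + smoothing
  rs <- rowSums(sm)
  P <- sm / ifelse(rs > 0, rs, 1)
  # a state never observed to leave (and zero smoothing) becomes absorbing
  for (s in which(rs == 0)) P[s, s] <- 1
  structure(P, class = c("transition_matrix", "matrix"),
            counts = counts, smoothing = smoothing)
}

#' Top-k Viterbi decoding of a state-probability sequence
#'
#' Returns the `k` state sequences maximizing
#' `log pi(s_1) + sum_t log p(s_t | window t) + sum_t log T(s_t, s_t+1)`,
#' in non-increasing score order, by k-best list Viterbi. The initial-state
#' prior `pi` is the transition matrix's stationary distribution.
#'
#' @param probs windows x 3 matrix of per-window state probabilities
#'   (WAKE, NREM, REM). Rows that are all-NA are treated as uniform
#'   (uninformative) emissions.
#' @param transitions 3x3 row-stochastic matrix (e.g. from
#'   [estimate_transitions()]).
#' @param k Number of sequences to return (>= 1).
#' @return List with `paths` (k x windows matrix of state labels) and
#'   `scores` (length-k non-increasing log-score vector).
#' @export
viterbi_topk <- function(probs, transitions, k = 10L) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3L, k >= 1L)
  n <- nrow(probs)
  check_transition_matrix(unclass(transitions))
  allna <- !stats::complete.cases(probs)
  probs[allna, ] <- 1 / 3
  if (any(probs < 0)) stop("negative emission probabilities", call. = FALSE)
  logE <- log(probs)
  logT <- log(unclass(transitions))
  logpi <- log(stationary_distribution(unclass(transitions)))

  # delta[[s]]: non-increasing vector of up to k best scores ending in s
  # bp[[t]][[s]]: matrix with rows (prev_state, prev_rank) per kept score
  delta <- lapply(1:3, function(s) logpi[s] + logE[1L, s])
  bp <- vector("list", n)
  for (t in seq_len(n)[-1L]) {
    newdelta <- vector("list", 3L)
    bp[[t]] <- vector("list", 3L)
    for (s in 1:3) {
      cand <- numeric(0); src <- NULL
      for (ps in 1:3) {
        sc <- delta[[ps]] + logT[ps, s]
        cand <- c(cand, sc)
        src <- rbind(src, cbind(ps, seq_along(sc)))
      }
      ord <- order(cand, decreasing = TRUE)[seq_len(min(k, length(cand)))]
      newdelta[[s]] <- cand[ord] + logE[t, s]
      bp[[t]][[s]] <- src[ord, , drop = FALSE]
    }
    delta <- newdelta
  }
  fin <- numeric(0); finsrc <- NULL
  for (s in 1:3) {
    fin <- c(fin, delta[[s]])
    finsrc <- rbind(finsrc, cbind(s, seq_along(delta[[s]])))
  }
  if (all(!is.finite(fin))) {
    stop("all paths have -Inf score (zero-probability deadlock)",
         call. = FALSE)
  }
  ord <- order(fin, decreasing = TRUE)[seq_len(min(k, length(fin)))]
  paths <- matrix(NA_integer_, nrow = length(ord), ncol = n)
  for (r in seq_along(ord)) {
    s <- finsrc[ord[r], 1L]; rank <- finsrc[ord[r], 2L]
    paths[r, n] <- s
    if (n > 1L) for (t in n:2) {
      prev <- bp[[t]][[s]][rank, ]
      s <- prev[1L]; rank <- prev[2L]
      paths[r, t - 1L] <- s
    }
  }
  if (!is.finite(fin[ord[length(ord)]])) {
    keep <- is.finite(fin[ord])
    ord <- ord[keep]
    paths <- paths[keep, , drop = FALSE]
  }
  list(paths = matrix(sleep_states()[paths], nrow = nrow(paths)),
       scores = fin[ord])
}

# Log-score of one label sequence under emissions + transitions + prior.
path_log_score <- function(labels, probs, transitions) {
  idx <- match(as_state_labels(labels), sleep_states())
  probs <- as.matrix(probs)
  probs[!stats::complete.cases(probs), ] <- 1 / 3
  logpi <- log(stationary_distribution(unclass(transitions)))
  logT <- log(unclass(transitions))
  s <- logpi[idx[1L]] + sum(log(probs[cbind(seq_along(idx), idx)]))
  if (length(idx) > 1L) s <- s + sum(logT[cbind(idx[-length(idx)], idx[-1L])])
  s
}

#' Smooth a hypnogram with top-k Viterbi
#'
#' Applies [viterbi_topk()] to the hypnogram's per-window probabilities.
#' The smoothed label at each window is the top-1 path's state; the
#' confidence is the fraction of the top-k paths agreeing with it there.
#' Windows without probabilities (e.g. UNKNOWN) get a uniform emission, so
#' gaps are bridged by the transition model.
#'
#' @param hyp A `hypnogram` carrying `p_wake`, `p_nrem`, `p_rem`.
#' @param transitions 3x3 transition matrix.
#' @param k Number of Viterbi paths (default 10).
#' @return The hypnogram with added `smoothed_label` and `confidence`
#'   columns.
#' @export
smooth_hypnogram <- function(hyp, transitions, k = 10L) {
  stopifnot(inherits(hyp, "hypnogram"))
  probs <- hypnogram_probs(hyp)
  if (is.null(probs)) {
    stop("hypnogram has no per-state probabilities to smooth", call. = FALSE)
  }
  vt <- viterbi_topk(probs, transitions, k = k)
  top1 <- vt$paths[1L, ]
  agree <- colMeans(vt$paths == matrix(top1, nrow = nrow(vt$paths),
                                       ncol = ncol(vt$paths), byrow = TRUE))
  hyp$smoothed_label <- top1
  hyp$confidence <- agree
  attr(hyp, "viterbi_scores") <- vt$scores
  hyp
}

#' Sleep-architecture (bout) statistics
#'
#' Decomposes the labeled portion of a hypnogram into maximal same-state
#' runs ("bouts"; UNKNOWN windows break runs and are excluded) and reports,
#' per state, percent time (of labeled windows), bout count, and mean and
#' median bout duration in seconds.
#'
#' @param hyp A `hypnogram`.
#' @param interval Optional `c(start_s, end_s)` time range to restrict to.
#' @param use_smoothed Use the `smoothed_label` track when present
#'   (default TRUE).
#' @return List with `per_state` (data frame: state, percent_time,
#'   n_bouts, mean_bout_s, median_bout_s) and `bouts` (data frame: state,
#'   start_window, length_windows, duration_s).
#' @export
architecture_stats <- function(hyp, interval = NULL, use_smoothed = TRUE) {
  stopifnot(inherits(hyp, "hypnogram"))
  lab <- if (use_smoothed && "smoothed_label" %in% names(hyp)) {
    hyp$smoothed_label
  } else hyp$label
  keep <- rep(TRUE, nrow(hyp))
  if (!is.null(interval)) {
    keep <- hyp$start_s >= interval[1L] & hyp$end_s <= interval[2L]
  }
  window_s <- if (nrow(hyp)) hyp$end_s[1L] - hyp$start_s[1L] else 2
  lab <- lab[keep]
  widx <- hyp$window_index[keep]
  labeled <- lab %in% sleep_states()
  if (!any(labeled)) {
    warning("no labeled windows in interval; zero bouts")
    per_state <- data.frame(state = sleep_states(), percent_time = 0,
                            n_bouts = 0L, mean_bout_s = NA_real_,
                            median_bout_s = NA_real_)
    return(list(per_state = per_state,
                bouts = data.frame(state = character(0),
                                   start_window = integer(0),
                                   length_windows = integer(0),
                                   duration_s = numeric(0))))
  }
  # break runs at UNKNOWN and at non-adjacent window indices
  grp <- cumsum(c(TRUE, diff(widx) != 1L)) + cumsum(!labeled)
  r <- rle(paste(grp, lab))
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  bout_lab <- lab[starts]
  keep_b <- bout_lab %in% sleep_states()
  bouts <- data.frame(state = bout_lab[keep_b],
                      start_window = widx[starts][keep_b],
                      length_windows = r$lengths[keep_b],
                      duration_s = r$lengths[keep_b] * window_s)
  n_labeled <- sum(labeled)
  per_state <- do.call(rbind, lapply(sleep_states(), function(st) {
    b <- bouts[bouts$state == st, ]
    data.frame(state = st,
               percent_time = 100 * sum(lab == st) / n_labeled,
               n_bouts = nrow(b),
               mean_bout_s = if (nrow(b)) mean(b$duration_s) else NA_real_,
               median_bout_s = if (nrow(b)) stats::median(b$duration_s)
                               else NA_real_)
  }))
  list(per_state = per_state, bouts = bouts)
}

#' Write / read a transition matrix as JSON
#' @param P A `transition_matrix` (or plain 3x3 matrix).
#' @param path JSON file path.
#' @return `path` (write) or a `transition_matrix` (read).
#' @export
write_transitions <- function(P, path) {
  check_transition_matrix(unclass(P))
  jsonlite::write_json(list(states = sleep_states(),
                            matrix = unclass(P),
                            smoothing = attr(P, "smoothing")),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- obj$matrix
  if (is.list(P)) P <- do.call(rbind, lapply(P, unlist))
  dimnames(P) <- list(sleep_states(), sleep_states())
  check_transition_matrix(P)
  structure(P, class = c("transition_matrix", "matrix"),
            smoothing = obj$smoothing)
}
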