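# --- Landau distribution (canonical form: location 0, scale pi/2, i.e. the
# stable law with alpha = 1, beta = 1 whose density is
#   p(x) = (1/pi) Int_0^inf exp(-t log t - x t) sin(pi t) dt )
# used for the asymptotically exact harmonic-mean p-value correction.

landau_pdf <- function(x) {
  vapply(x, function(xi) {
    stats::integrate(function(t) {
      out <- exp(-pi * t / 2) * cos(xi * t + t * log(t))
      out[t == 0] <- 1
      out
    }, 0, Inf, rel.tol = 1e-10, subdivisions = 400L)$value / pi
  }, numeric(1))
}

landau_sf <- function(x) {
  tail_sf <- function(xi) {
    # Int_x^inf p(u) du with the e^{-ut} factor integrated analytically
    stats::integrate(function(t) {
      out <- exp(-t * log(t) - xi * t) * sin(pi * t) / t
      out[t == 0] <- pi
      out
    }, 0, Inf, rel.tol = 1e-10, subdivisions = 400L)$value / pi
  }
  vapply(x, function(xi) {
    s <- if (xi >= 1) {
      tail_sf(xi)
    } else {
      # below the mode region the tail integral loses accuracy; integrate
      # the density up from xi to 1 instead
      tail_sf(1) + stats::integrate(function(u) landau_pdf(u), xi, 1,
                                    rel.tol = 1e-8)$value
    }
    min(max(s, 0), 1)
  }, numeric(1))
}

#' Harmonic mean p-value with asymptotically exact correction
#'
#' The harmonic mean p-value (HMP) of `L` tests is
#' `psi = sum(w) / sum(w / p)`. The raw HMP is slightly anticonservative,
#' so a corrected "headline" p-value is computed from the heavy-tailed
#' Landau law: asymptotically, `1/psi` for `L` null tests follows a Landau
#' distribution with location `log(L) + 0.874` and scale `pi/2`, and the
#' headline p is its upper tail probability at the observed `1/psi`. The
#' combined test is robust to dependence between the component tests and
#' controls the familywise error rate at approximately the chosen level.
#'
#' @param p Vector of p-values, all in (0, 1].
#' @param weights Optional non-negative weights summing to 1 (default
#'   uniform).
#' @param L Number of tests used in the correction (default `length(p)`).
#' @return List with `hmp` (the raw harmonic mean), `headline_p` (the
#'   corrected tail probability) and `L`.
#' @export
harmonic_mean_p <- function(p, weights = NULL, L = length(p)) {
  if (any(p <= 0)) stop("p-values must be > 0 (the HMP reciprocal is ",
                        "undefined at 0)", call. = FALSE)
  if (any(p > 1)) stop("p-values must be <= 1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  if (length(weights) != length(p) || any(weights < 0)) {
    stop("weights must be non-negative, one per p-value", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  psi <- sum(weights) / sum(weights / p)
  # Landau location for L tests (Euler-Mascheroni-derived constant)
  mu_L <- log(L) + 0.874367040387922
  headline <- landau_sf(1 / psi - mu_L)
  list(hmp = psi, headline_p = min(max(headline, .Machine$double.xmin), 1),
       L = L)
}

#' Cosine similarity between two feature vectors
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return Scalar in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero ",
                               "vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Within-subject state-average feature vectors
#'
#' For each requested state, the mean over that state's valid labeled
#' windows of the flattened feature vector -- the per-subject summary the
#' group comparisons operate on.
#'
#' @param tensor A `feature_tensor` for one subject.
#' @param hyp Matching [hypnogram()] (its `smoothed_label` track is used
#'   when present).
#' @param states States to summarize (default all three).
#' @param use_smoothed Use the smoothed track when present (default TRUE).
#' @return An object of class `condition_summary`: list with `means` (named
#'   list of length-d vectors, states with zero windows omitted with a
#'   warning), `n_windows`, `subject_id`, `regions`, `freqs`.
#' @export
state_mean_features <- function(tensor, hyp, states = sleep_states(),
                                use_smoothed = TRUE) {
  stopifnot(inherits(tensor, "feature_tensor"))
  lab <- if (use_smoothed && "smoothed_label" %in% names(hyp)) {
    hyp$smoothed_label
  } else if (inherits(hyp, "hypnogram")) hyp$label else as_state_labels(hyp)
  flat <- flatten_features(tensor)
  n <- min(nrow(flat), length(lab))
  lab <- lab[seq_len(n)]
  valid <- tensor$valid_mask[seq_len(n)]
  means <- list(); counts <- integer(0)
  for (st in states) {
    sel <- which(lab == st & valid)
    if (!length(sel)) {
      warning("state ", st, " has zero valid windows for subject ",
              tensor$subject_id, "; omitted")
      next
    }
    means[[st]] <- colMeans(flat[sel, , drop = FALSE])
    counts[st] <- length(sel)
  }
  structure(list(means = means, n_windows = counts,
                 subject_id = tensor$subject_id,
                 regions = tensor$regions, freqs = tensor$freqs),
            class = "condition_summary")
}

#' Per-feature two-sided Welch t-tests between two groups of subjects
#'
#' Subjects are the statistical unit: each row of the inputs is one
#' subject's state-average feature vector. One unequal-variance two-sided
#' t-test is run per feature (d tests; 1856 for the 8-region, 29-bin
#' grid). Features with zero variance in both groups get t = 0, p = 1 and
#' a flag.
#'
#' @param group_a,group_b Subjects x d numeric matrices (>= 2 rows each).
#' @return Data frame with columns `t`, `p`, `mean_diff` (a minus b),
#'   `sign`, `zero_variance`.
#' @export
feature_ttests <- function(group_a, group_b) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  stopifnot(ncol(A) == ncol(B))
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2L, stats::var); vb <- apply(B, 2L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  data.frame(t = tstat, p = p, mean_diff = ma - mb,
             sign = sign(ma - mb), zero_variance = se2 == 0,
             row.names = colnames(A))
}

#' Compare feature tensors across two experimental conditions
#'
#' The full mass-univariate pipeline: per-subject state-average features
#' ([state_mean_features()]), per-feature Welch t-tests per state
#' ([feature_ttests()]), a corrected harmonic-mean headline p-value per
#' state ([harmonic_mean_p()]), and a per-feature display mask at
#' unadjusted `alpha_display` carrying the sign of the mean difference
#' (the headline HMP plays no role in the mask).
#'
#' @param summaries_a,summaries_b Lists of `condition_summary` objects (one
#'   per subject) for the two conditions.
#' @param alpha_display Unadjusted per-feature display threshold (default
#'   0.01).
#' @return An object of class `group_comparison`: per state, a list with
#'   `tests` (the per-feature table), `hmp`, `headline_p`, `display_mask`
#'   (signed: -1/0/+1), `diff_tensor` (R x R x F signed mean difference)
#'   and group sizes.
#' @export
compare_conditions <- function(summaries_a, summaries_b,
                               alpha_display = 0.01) {
  stopifnot(length(summaries_a) >= 2L, length(summaries_b) >= 2L)
  regions <- summaries_a[[1L]]$regions
  freqs <- summaries_a[[1L]]$freqs
  out <- list()
  for (st in sleep_states()) {
    A <- do.call(rbind, lapply(summaries_a, function(s) s$means[[st]]))
    B <- do.call(rbind, lapply(summaries_b, function(s) s$means[[st]]))
    if (is.null(A) || is.null(B) || nrow(A) < 2L || nrow(B) < 2L) {
      warning("state ", st, " has fewer than 2 subjects per group; skipped")
      next
    }
    tt <- feature_ttests(A, B)
    hp <- harmonic_mean_p(tt$p)
    mask <- ifelse(tt$p < alpha_display, tt$sign, 0)
    diff_tensor <- if (!is.null(regions) && !is.null(freqs) &&
                       length(regions)^2 * length(freqs) == nrow(tt)) {
      unflatten_features(tt$mean_diff, regions, freqs)
    }
    out[[st]] <- list(tests = tt, hmp = hp$hmp, headline_p = hp$headline_p,
                      n_tests = hp$L, display_mask = mask,
                      diff_tensor = diff_tensor,
                      n_a = nrow(A), n_b = nrow(B))
  }
  structure(c(out, list(alpha_display = alpha_display)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of LFP features (per-feature Welch t-tests,\n")
  cat("corrected harmonic-mean headline p per state; display alpha =",
      x$alpha_display, ")\n")
  for (st in intersect(sleep_states(), names(x))) {
    g <- x[[st]]
    cat(sprintf("  %-4s headline p = %.4g (HMP %.4g over %d tests), %d/%d",
                st, g$headline_p, g$hmp, g$n_tests,
                sum(g$display_mask != 0), g$n_tests),
        "features pass display threshold\n")
  }
  invisible(x)
}
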