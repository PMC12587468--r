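#' Sleep-wake state labels
#'
#' The three scored vigilance states, in their canonical order. The order
#' matters: classifier logits, one-hot labels, transition matrices and
#' argmax tie-breaking all follow it (WAKE before NREM before REM).
#'
#' @return Character vector `c("WAKE", "NREM", "REM")`.
#' @export
sleep_states <- function() c("WAKE", "NREM", "REM")

#' Label used for windows that received no state
#' @return The string `"UNKNOWN"`.
#' @export
unknown_state <- function() "UNKNOWN"

#' Default region montage
#'
#' Eight emotion-regulating brain regions recorded in the reference montage:
#' cingulate (CxCg), prelimbic (CxPrL) and infralimbic (CxIL) cortex,
#' nucleus accumbens (NAc), amygdala (Amy), mediodorsal thalamus (ThalMD),
#' ventral hippocampus (HippV) and ventral tegmental area (VTA).
#'
#' @return Character vector of 8 region names, in fixed order.
#' @export
default_regions <- function() {
  c("CxCg", "CxPrL", "CxIL", "NAc", "Amy", "ThalMD", "HippV", "VTA")
}

# Numerically stable softmax over rows of a matrix.
softmax <- function(z) {
  z <- as.matrix(z)
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# Numerically stable softplus log(1 + exp(z)).
softplus <- function(z) {
  out <- z
  idx <- z < 30
  out[idx] <- log1p(exp(z[idx]))
  out
}

# Derivative of softplus: the logistic sigmoid.
sigmoid <- function(z) 1 / (1 + exp(-z))

# Derive a reproducible 31-bit sub-seed from a base seed and a tag.
derive_seed <- function(seed, tag) {
  if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(tag) * 104729) %%
               2147483646) + 1L
}

# Validate a row-stochastic matrix over the three states.
check_transition_matrix <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || any(dim(P) != c(3L, 3L))) {
    stop("transition matrix must be 3x3 over (WAKE, NREM, REM)", call. = FALSE)
  }
  if (any(P < 0)) stop("transition matrix entries must be >= 0", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop("transition matrix rows must sum to 1 (tolerance ", tol, ")",
         call. = FALSE)
  }
  invisible(P)
}

#' Stationary distribution of a 3-state transition matrix
#'
#' @param P 3x3 row-stochastic matrix over (WAKE, NREM, REM).
#' @return Numeric length-3 probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  check_transition_matrix(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) stop("no non-negative stationary distribution found",
                           call. = FALSE)
  pmax(v, 0) / sum(pmax(v, 0))
}

# Coerce labels (factor/character/hypnogram) to a character vector of states.
as_state_labels <- function(x) {
  if (inherits(x, "hypnogram")) x <- x$label
  x <- as.character(x)
  ok <- x %in% c(sleep_states(), unknown_state())
  if (!all(ok)) {
    stop("unrecognised state label(s): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  x
}
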