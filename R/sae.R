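#' Training configuration for the supervised autoencoder
#'
#' Optimizer and initialization settings. The objective and architecture are
#' fixed; these control only how the fit is found, and are exposed because
#' they affect reproducibility.
#'
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Minibatch size (default 256).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience, in epochs without improvement of
#'   validation balanced accuracy (default 20; only used when a validation
#'   set is supplied).
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param init_sd SD of the Gaussian initialization of the encoder and
#'   decoder weights (decoder clamped at 0 after init).
#' @param recon_norm `"l2"` for the plain Euclidean reconstruction norm (the
#'   printed objective), `"l2sq"` for its square (the usual NMF convention).
#' @return An object of class `sae_config`.
#' @export
sae_config <- function(epochs = 200L, batch_size = 256L,
                       learning_rate = 1e-3, patience = 20L, seed = 1L,
                       init_sd = 0.01, recon_norm = c("l2", "l2sq")) {
  recon_norm <- match.arg(recon_norm)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 init_sd = init_sd, recon_norm = recon_norm),
            class = "sae_config")
}

# One-hot encode labels over the three states; UNKNOWN rows are dropped by
# callers before reaching here.
one_hot_states <- function(labels) {
  idx <- match(as_state_labels(labels), sleep_states())
  if (anyNA(idx)) stop("one-hot encoding requires labeled windows only",
                       call. = FALSE)
  Y <- matrix(0, length(idx), 3L)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

# Forward pass; returns intermediates needed by the gradient.
sae_forward <- function(params, X) {
  Z <- X %*% t(params$A) + matrix(params$b, nrow(X), length(params$b),
                                  byrow = TRUE)
  logits <- sweep(Z[, 1:3, drop = FALSE], 2L, params$C_diag, `*`)
  P <- softmax(logits)
  S <- softplus(Z)
  Xhat <- S %*% params$H
  list(Z = Z, logits = logits, P = P, S = S, Xhat = Xhat)
}

#' Supervised-autoencoder objective
#'
#' Evaluates `L(C(Ax+b), y) + mu * ||H softplus(Ax+b) - x||` for a batch,
#' where `L` is cross-entropy with logits, `C` is diagonal with three rows,
#' and `H` is the non-negative decoder. Batch aggregation is the mean of
#' per-window losses.
#'
#' @param params List with `A` (m x d), `b` (m), `C_diag` (3), `H` (m x d,
#'   non-negative), `mu` (> 0).
#' @param X windows x d feature matrix.
#' @param Y windows x 3 one-hot label matrix.
#' @param recon_norm `"l2"` (plain norm, default) or `"l2sq"`.
#' @return List with `total`, `prediction` (cross-entropy term) and
#'   `reconstruction` (the norm term, before multiplying by `mu`).
#' @export
sae_objective <- function(params, X, Y, recon_norm = "l2") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(params$A)) stop("feature dimension mismatch: x has ",
                                      ncol(X), ", model expects ",
                                      ncol(params$A), call. = FALSE)
  if (nrow(Y) != nrow(X) || ncol(Y) != 3L) {
    stop("labels must be one-hot over 3 states, one row per window",
         call. = FALSE)
  }
  fw <- sae_forward(params, X)
  logp <- log(pmax(fw$P, 1e-300))
  ce <- -mean(rowSums(Y * logp))
  rnorm_w <- sqrt(rowSums((fw$Xhat - X)^2))
  rec <- if (recon_norm == "l2") mean(rnorm_w) else mean(rnorm_w^2)
  list(total = ce + params$mu * rec, prediction = ce, reconstruction = rec)
}

# Analytic gradient of the batch-mean objective wrt A, b, C_diag, H.
sae_gradient <- function(params, X, Y, recon_norm = "l2") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fw <- sae_forward(params, X)
  dL <- (fw$P - Y) / n                      # n x 3
  dC <- colSums(dL * fw$Z[, 1:3, drop = FALSE])
  dZ <- matrix(0, n, nrow(params$A))
  dZ[, 1:3] <- sweep(dL, 2L, params$C_diag, `*`)
  Rres <- fw$Xhat - X
  if (recon_norm == "l2") {
    rn <- sqrt(rowSums(Rres^2))
    w <- ifelse(rn > 0, 1 / rn, 0)
    G <- params$mu * Rres * w / n
  } else {
    G <- params$mu * 2 * Rres / n
  }
  dH <- t(fw$S) %*% G
  dS <- G %*% t(params$H)
  dZ <- dZ + dS * sigmoid(fw$Z)
  list(A = t(dZ) %*% X, b = colSums(dZ), C_diag = dC, H = dH)
}

adam_init <- function(params) {
  lapply(params[c("A", "b", "C_diag", "H")],
         function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(state)) {
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * grad[[nm]]
    st$v <- beta2 * st$v + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  params$H[params$H < 0] <- 0               # projection: keep decoder >= 0
  list(params = params, state = state)
}

#' Fit the supervised autoencoder sleep-wake classifier
#'
#' Learns the objective `L(C(Ax+b), y) + mu * ||H softplus(Ax+b) - x||` by
#' minibatch Adam with the decoder `H` kept entrywise non-negative by
#' projection (clamping at zero after every step). The latent dimension is
#' 32: the first 3 "electome scores" feed the state logits through the
#' diagonal matrix `C`, and every row of `H` is a non-negative vectorized
#' region x region x frequency factor ("electome factor"); rows 1-3 are the
#' state-supervised factors.
#'
#' @param x Feature input: a `feature_tensor` (flattened internally; invalid
#'   windows dropped from training) or a windows x d numeric matrix.
#' @param y State labels per window (character vector or [hypnogram()]);
#'   UNKNOWN windows are excluded from the fit.
#' @param mu Reconstruction weight (> 0), default 1e-2.
#' @param n_latent Latent dimension (default 32 = 3 supervised + 29
#'   unsupervised factors).
#' @param config An [sae_config()].
#' @param validation Optional list `(x, y)` in the same formats; when given,
#'   training keeps the parameters with the best validation balanced
#'   accuracy and stops early after `config$patience` epochs without
#'   improvement.
#' @return An object of class `electome_sae` with elements `A`, `b`,
#'   `C_diag`, `H`, `mu`, `states`, `d`, `n_latent`, `regions`, `freqs`
#'   (when known), `loss_trace` and `config`.
#' @export
electome_sae <- function(x, y, mu = 1e-2, n_latent = 32L,
                         config = sae_config(), validation = NULL) {
  stopifnot(mu > 0, n_latent >= 3L)
  xin <- sae_input(x, y)
  X <- xin$X; Y <- xin$Y
  counts <- colSums(Y)
  if (any(counts == 0)) {
    stop("every state must appear in the training labels; counts: ",
         paste(sprintf("%s=%d", sleep_states(), counts), collapse = ", "),
         call. = FALSE)
  }
  d <- ncol(X)
  set.seed(config$seed)
  params <- list(
    A = matrix(stats::rnorm(n_latent * d, sd = config$init_sd), n_latent, d),
    b = rep(0, n_latent),
    C_diag = rep(1, 3L),
    H = pmax(matrix(stats::rnorm(n_latent * d, sd = config$init_sd),
                    n_latent, d), 0),
    mu = mu)
  st <- adam_init(params)
  n <- nrow(X)
  vset <- if (!is.null(validation)) sae_input(validation$x, validation$y)
  best <- list(score = -Inf, params = params, epoch = 0L)
  trace <- numeric(config$epochs)
  t_global <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      g <- sae_gradient(params, X[idx, , drop = FALSE],
                        Y[idx, , drop = FALSE], config$recon_norm)
      t_global <- t_global + 1L
      upd <- adam_step(params, g, st, config$learning_rate, t_global)
      params <- upd$params; st <- upd$state
      ob <- sae_objective(params, X[idx, , drop = FALSE],
                          Y[idx, , drop = FALSE], config$recon_norm)
      ep_loss <- ep_loss + ob$total
      nb <- nb + 1L
    }
    trace[ep] <- ep_loss / nb
    if (!is.null(vset)) {
      acc <- balanced_accuracy(
        sleep_states()[max.col(vset$Y, ties.method = "first")],
        sae_predict_labels(params, vset$X))
      if (acc > best$score + 1e-9) {
        best <- list(score = acc, params = params, epoch = ep)
      } else if (ep - best$epoch >= config$patience) {
        trace <- trace[seq_len(ep)]
        break
      }
    }
  }
  if (!is.null(vset) && is.finite(best$score)) params <- best$params
  structure(c(params,
              list(states = sleep_states(), d = d,
                   n_latent = as.integer(n_latent),
                   regions = xin$regions, freqs = xin$freqs,
                   feature_names = colnames(X),
                   loss_trace = trace, config = config,
                   validation_score = if (!is.null(vset)) best$score)),
            class = "electome_sae")
}

# Normalize the (x, y) input formats to a clean matrix + one-hot pair.
sae_input <- function(x, y) {
  regions <- NULL; freqs <- NULL; valid <- NULL
  if (inherits(x, "feature_tensor")) {
    regions <- x$regions; freqs <- x$freqs; valid <- x$valid_mask
    x <- flatten_features(x)
  } else {
    regions <- attr(x, "regions"); freqs <- attr(x, "freqs")
    valid <- attr(x, "valid_mask")
    x <- as.matrix(x)
  }
  lab <- as_state_labels(y)
  if (length(lab) != nrow(x)) stop("features and labels disagree in length",
                                   call. = FALSE)
  keep <- lab %in% sleep_states()
  if (!is.null(valid)) keep <- keep & valid
  list(X = x[keep, , drop = FALSE], Y = one_hot_states(lab[keep]),
       regions = regions, freqs = freqs, keep = keep)
}

sae_predict_probs <- function(params, X) {
  Z <- X %*% t(params$A) + matrix(params$b, nrow(X), length(params$b),
                                  byrow = TRUE)
  softmax(sweep(Z[, 1:3, drop = FALSE], 2L, params$C_diag, `*`))
}

sae_predict_labels <- function(params, X) {
  P <- sae_predict_probs(params, X)
  sleep_states()[max.col(P, ties.method = "first")]
}

#' Predict per-window state probabilities and labels
#'
#' Probabilities are `softmax(C(Ax+b))`; the label is the argmax, ties
#' broken by state order (WAKE before NREM before REM). Invalid windows
#' (from a feature tensor's `valid_mask`) become UNKNOWN with NA
#' probabilities.
#'
#' @param object A fitted `electome_sae`.
#' @param newdata A `feature_tensor` or windows x d matrix.
#' @param ... Unused.
#' @return A [hypnogram()] with probability columns.
#' @export
predict.electome_sae <- function(object, newdata, ...) {
  valid <- NULL
  if (inherits(newdata, "feature_tensor")) {
    valid <- newdata$valid_mask
    newdata <- flatten_features(newdata)
  } else {
    valid <- attr(newdata, "valid_mask")
  }
  X <- as.matrix(newdata)
  if (ncol(X) != object$d) stop("feature dimension mismatch: newdata has ",
                                ncol(X), " features, model expects ",
                                object$d, call. = FALSE)
  P <- sae_predict_probs(object, X)
  lab <- sleep_states()[max.col(P, ties.method = "first")]
  if (!is.null(valid)) {
    lab[!valid] <- unknown_state()
    P[!valid, ] <- NA_real_
  }
  hypnogram(lab, probs = P)
}

#' Balanced accuracy of a sleep-wake classification
#'
#' The mean of the three per-state recalls, in percent, weighting the
#' states equally regardless of time spent in each. UNKNOWN truth windows
#' are excluded; a state absent from the truth is dropped from the average
#' with a warning. Predicted UNKNOWN windows count as misses.
#'
#' @param truth,predicted Hypnograms or character label vectors.
#' @return Balanced accuracy in percent.
#' @export
balanced_accuracy <- function(truth, predicted) {
  tr <- as_state_labels(truth)
  pr <- as_state_labels(predicted)
  if (length(tr) != length(pr)) stop("label sequences differ in length",
                                     call. = FALSE)
  keep <- tr != unknown_state()
  tr <- tr[keep]; pr <- pr[keep]
  recalls <- vapply(sleep_states(), function(st) {
    n_st <- sum(tr == st)
    if (n_st == 0) return(NA_real_)
    sum(tr == st & pr == st) / n_st
  }, numeric(1))
  if (anyNA(recalls)) {
    warning("state(s) absent from truth dropped from balanced accuracy: ",
            paste(sleep_states()[is.na(recalls)], collapse = ", "))
  }
  100 * mean(recalls, na.rm = TRUE)
}

#' Leave-one-mouse-out nested cross-validation
#'
#' Outer loop: each mouse in turn is the test subject. Inner loop: three
#' seeded shuffled splits of the remaining mice into training and
#' validation subjects (the 6/2 geometry when 8 remain, otherwise all but
#' one vs one) score every `mu` on the grid by mean validation balanced
#' accuracy. The best `mu` is refit on all outer-training mice and scored
#' on the test mouse. After all folds the grid value with the best pooled
#' inner score is refit on every mouse to give the final model.
#'
#' @param x_by_mouse List (one element per mouse) of feature tensors or
#'   matrices.
#' @param y_by_mouse List of matching label vectors / hypnograms.
#' @param mu_grid Candidate reconstruction weights
#'   (default `c(1e-1, 1e-2, 1e-3)`).
#' @param config An [sae_config()].
#' @param n_inner Number of inner shuffled splits (default 3).
#' @return An object of class `sae_cv`: list with `folds` (data frame of
#'   per-fold test balanced accuracy, per-state recalls and chosen mu),
#'   `inner_scores` (mu x fold matrix of mean inner validation scores),
#'   `chosen_mu`, and `final_model` trained on all mice.
#' @export
nested_cv <- function(x_by_mouse, y_by_mouse,
                      mu_grid = c(1e-1, 1e-2, 1e-3),
                      config = sae_config(), n_inner = 3L) {
  m <- length(x_by_mouse)
  stopifnot(length(y_by_mouse) == m, length(mu_grid) >= 1L)
  if (m < 4L) {
    stop("nested CV needs >= 4 mice (leave-one-out outer fold plus an ",
         "inner train/validation split); got ", m, call. = FALSE)
  }
  n_val <- if (m - 1L >= 8L) 2L else 1L
  if (m - 1L - n_val < 2L) {
    stop("inner split infeasible: ", m - 1L, " mice left after holding out ",
         "the test mouse, need >= ", n_val + 2L, call. = FALSE)
  }
  xin <- lapply(seq_len(m), function(i) sae_input(x_by_mouse[[i]],
                                                  y_by_mouse[[i]]))
  fit_on <- function(mice, mu, validation = NULL) {
    X <- do.call(rbind, lapply(xin[mice], `[[`, "X"))
    Yl <- unlist(lapply(xin[mice], function(z)
      sleep_states()[max.col(z$Y, ties.method = "first")]))
    attr(X, "regions") <- xin[[1L]]$regions
    attr(X, "freqs") <- xin[[1L]]$freqs
    electome_sae(X, Yl, mu = mu, config = config, validation = validation)
  }
  score_on <- function(model, mouse) {
    truth <- sleep_states()[max.col(xin[[mouse]]$Y, ties.method = "first")]
    pred <- predict(model, xin[[mouse]]$X)
    balanced_accuracy(truth, pred$label)
  }
  inner_scores <- matrix(NA_real_, length(mu_grid), m,
                         dimnames = list(paste0("mu=", mu_grid), NULL))
  folds <- data.frame()
  for (o in seq_len(m)) {
    rest <- setdiff(seq_len(m), o)
    splits <- lapply(seq_len(n_inner), function(s) {
      set.seed(derive_seed(config$seed, paste0("cv-fold", o, "-split", s)))
      val <- sample(rest, n_val)
      list(train = setdiff(rest, val), val = val)
    })
    mu_scores <- vapply(mu_grid, function(mu) {
      mean(vapply(splits, function(sp) {
        mod <- fit_on(sp$train, mu)
        mean(vapply(sp$val, function(v) score_on(mod, v), numeric(1)))
      }, numeric(1)))
    }, numeric(1))
    inner_scores[, o] <- mu_scores
    best_mu <- mu_grid[which.max(mu_scores)]
    outer_model <- fit_on(rest, best_mu)
    truth <- sleep_states()[max.col(xin[[o]]$Y, ties.method = "first")]
    pred <- predict(outer_model, xin[[o]]$X)$label
    recalls <- vapply(sleep_states(), function(st) {
      n_st <- sum(truth == st)
      if (n_st == 0) NA_real_ else sum(truth == st & pred == st) / n_st
    }, numeric(1))
    folds <- rbind(folds, data.frame(
      test_mouse = o, chosen_mu = best_mu,
      balanced_accuracy = balanced_accuracy(truth, pred),
      recall_wake = recalls[1L], recall_nrem = recalls[2L],
      recall_rem = recalls[3L]))
  }
  pooled <- rowMeans(inner_scores)
  chosen_mu <- mu_grid[which.max(pooled)]
  final_model <- fit_on(seq_len(m), chosen_mu)
  structure(list(folds = folds, inner_scores = inner_scores,
                 chosen_mu = chosen_mu, final_model = final_model,
                 n_inner = n_inner, n_val = n_val),
            class = "sae_cv")
}

#' @export
print.sae_cv <- function(x, ...) {
  cat("Nested leave-one-mouse-out CV:", nrow(x$folds), "outer folds,",
      x$n_inner, "inner splits (", nrow(x$folds) - 1L - x$n_val, "train /",
      x$n_val, "validation )\n")
  cat("  mean outer balanced accuracy:",
      sprintf("%.1f%%", mean(x$folds$balanced_accuracy)), "\n")
  cat("  chosen mu:", x$chosen_mu, "\n")
  invisible(x)
}

#' Single-region power features
#'
#' Restricts a feature tensor to one region's power spectrum (the tensor
#' diagonal), giving the d = F (29-bin) input of a single-region
#' classifier.
#'
#' @param tensor A `feature_tensor`.
#' @param region Region name.
#' @return windows x F matrix with `regions`/`freqs`/`valid_mask`
#'   attributes, ready for [electome_sae()].
#' @export
single_region_features <- function(tensor, region) {
  stopifnot(inherits(tensor, "feature_tensor"))
  r <- match(region, tensor$regions)
  if (is.na(r)) stop("region ", region, " not in tensor", call. = FALSE)
  out <- tensor$values[, r, r, , drop = TRUE]
  out <- matrix(out, nrow = dim(tensor$values)[1L])
  colnames(out) <- sprintf("%s:%s:%.2fHz", region, region, tensor$freqs)
  attr(out, "regions") <- region
  attr(out, "freqs") <- tensor$freqs
  attr(out, "valid_mask") <- tensor$valid_mask
  out
}

#' Electome factors of a fitted model
#'
#' Un-flattens every row of the non-negative decoder `H` to a
#' region x region x frequency array. Rows 1-3 are the supervised factors
#' (tagged by their state); the remainder are unsupervised.
#'
#' @param model A fitted `electome_sae` whose feature metadata (`regions`,
#'   `freqs`) is known.
#' @return List with `supervised` (named list WAKE/NREM/REM of R x R x F
#'   arrays) and `unsupervised` (list of the remaining factors).
#' @export
electome_factors <- function(model) {
  stopifnot(inherits(model, "electome_sae"))
  regions <- model$regions; freqs <- model$freqs
  if (is.null(regions) || is.null(freqs) ||
      length(regions)^2 * length(freqs) != model$d) {
    stop("model lacks region/frequency metadata consistent with d = ",
         model$d, call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(model$H)), function(i)
    unflatten_features(model$H[i, ], regions, freqs))
  sup <- rows[1:3]
  names(sup) <- sleep_states()
  list(supervised = sup, unsupervised = rows[-(1:3)])
}

#' @export
print.electome_sae <- function(x, ...) {
  cat("Supervised autoencoder sleep-wake classifier\n")
  cat("  features d =", x$d, " latent =", x$n_latent,
      "( 3 supervised + ", x$n_latent - 3L, "unsupervised factors )\n")
  cat("  mu =", x$mu, " reconstruction norm:", x$config$recon_norm, "\n")
  if (!is.null(x$regions)) {
    cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  }
  cat("  trained", length(x$loss_trace), "epochs; final batch loss",
      signif(utils::tail(x$loss_trace, 1L), 4), "\n")
  invisible(x)
}

#' @export
summary.electome_sae <- function(object, ...) {
  fw_c <- object$C_diag
  cat("Supervised autoencoder (electome) model\n")
  print(object)
  cat("  C diagonal (state logit scales):",
      paste(signif(fw_c, 3), collapse = ", "), "\n")
  cat("  H: ", nrow(object$H), "x", ncol(object$H),
      " non-negative; min =", min(object$H),
      " mean =", signif(mean(object$H), 4), "\n")
  invisible(object)
}

#' @export
coef.electome_sae <- function(object, ...) {
  list(A = object$A, b = object$b, C_diag = object$C_diag, H = object$H,
       mu = object$mu)
}

#' Residual reconstruction errors
#'
#' Per-window Euclidean norm of `H softplus(Ax+b) - x`.
#'
#' @param object A fitted `electome_sae`.
#' @param newdata A `feature_tensor` or matrix (required).
#' @param ... Unused.
#' @return Numeric vector of per-window reconstruction norms.
#' @export
residuals.electome_sae <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_tensor")) newdata <- flatten_features(newdata)
  X <- as.matrix(newdata)
  fw <- sae_forward(object, X)
  sqrt(rowSums((fw$Xhat - X)^2))
}

#' Plot the supervised electome factors
#'
#' Heatmaps of the three supervised factors' within-region power (tensor
#' diagonal, regions x frequencies).
#'
#' @param x A fitted `electome_sae` with region/frequency metadata.
#' @param ... Passed to [graphics::image()].
#' @export
plot.electome_sae <- function(x, ...) {
  fac <- electome_factors(x)
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 6, 2, 1))
  on.exit(graphics::par(old))
  for (st in sleep_states()) {
    arr <- fac$supervised[[st]]
    diagpow <- t(vapply(seq_along(x$regions),
                        function(r) arr[r, r, ], numeric(length(x$freqs))))
    graphics::image(x$freqs, seq_along(x$regions), t(diagpow),
                    xlab = "frequency (Hz)", ylab = "", yaxt = "n",
                    main = paste(st, "factor"), ...)
    graphics::axis(2, at = seq_along(x$regions), labels = x$regions,
                   las = 1, cex.axis = 0.7)
  }
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' All parameters and metadata as plain JSON (text, portable, diffable).
#'
#' @param model A fitted `electome_sae`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_sae <- function(model, path) {
  stopifnot(inherits(model, "electome_sae"))
  obj <- list(format = "electosleep-sae-v1",
              A = model$A, b = model$b, C_diag = model$C_diag, H = model$H,
              mu = model$mu, d = model$d, n_latent = model$n_latent,
              states = model$states, regions = model$regions,
              freqs = model$freqs, config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_sae
#' @export
read_sae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tomat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  model <- list(A = tomat(obj$A), b = as.numeric(obj$b),
                C_diag = as.numeric(obj$C_diag), H = tomat(obj$H),
                mu = obj$mu, states = obj$states, d = obj$d,
                n_latent = obj$n_latent,
                regions = obj$regions, freqs = obj$freqs,
                feature_names = NULL, loss_trace = numeric(0),
                config = do.call(sae_config, obj$config))
  class(model) <- "electome_sae"
  model
}
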