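zero_params <- function(d = 5, m = 4, mu = 0.1) {
  list(A = matrix(0, m, d), b = rep(0, m), C_diag = rep(1, 3),
       H = matrix(0, m, d), mu = mu)
}

test_that("objective equals its closed forms on degenerate models", {
  p <- zero_params()
  x <- matrix(0, 1, 5)
  y <- matrix(c(1, 0, 0), 1)
  ob <- sae_objective(p, x, y)
  expect_equal(ob$prediction, log(3))          # uniform softmax over 3 states
  expect_equal(ob$reconstruction, 0)           # zero residual
  expect_equal(ob$total, log(3))

  # perfect autoencoder: H softplus(Ax+b) = x exactly
  set.seed(41)
  d <- 6; m <- 4
  H <- matrix(abs(rnorm(m * d)), m, d)
  s <- abs(rnorm(m)) + 0.5
  xvec <- drop(s %*% H)
  # choose b so softplus(b) = s with A = 0
  p2 <- list(A = matrix(0, m, d), b = log(exp(s) - 1), C_diag = rep(1, 3),
             H = H, mu = 2)
  ob2 <- sae_objective(p2, matrix(xvec, 1), matrix(c(0, 1, 0), 1))
  expect_equal(ob2$reconstruction, 0, tolerance = 1e-10)
  expect_error(sae_objective(p2, matrix(0, 1, 3), matrix(c(1, 0, 0), 1)),
               "dimension mismatch")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  d <- 11; m <- 6; n <- 9
  params <- list(A = matrix(rnorm(m * d, sd = 0.4), m, d),
                 b = rnorm(m, sd = 0.2),
                 C_diag = rnorm(3, 1, 0.3),
                 H = pmax(matrix(rnorm(m * d, sd = 0.4), m, d), 0),
                 mu = 0.07)
  X <- matrix(rnorm(n * d), n)
  Y <- diag(3)[sample(1:3, n, TRUE), ]
  for (norm in c("l2", "l2sq")) {
    g <- electosleep:::sae_gradient(params, X, Y, norm)
    eps <- 1e-6
    for (nm in c("A", "b", "C_diag", "H")) {
      idx <- sample(length(params[[nm]]), min(8, length(params[[nm]])))
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (sae_objective(pp, X, Y, norm)$total -
                 sae_objective(pm, X, Y, norm)$total) / (2 * eps)
        expect_lt(abs(fd - g[[nm]][i]) / max(abs(fd), abs(g[[nm]][i]), 1e-8),
                  1e-4)
      }
    }
  }
})

test_that("prediction is a normalized softmax with ordered tie-breaking", {
  p <- zero_params(d = 5, m = 4)
  model <- structure(c(p, list(states = sleep_states(), d = 5L,
                               n_latent = 4L, regions = NULL, freqs = NULL,
                               feature_names = NULL, loss_trace = numeric(0),
                               config = sae_config())),
                     class = "electome_sae")
  hyp <- predict(model, matrix(rnorm(20 * 5), 20))
  P <- as.matrix(hyp[, c("p_wake", "p_nrem", "p_rem")])
  expect_equal(unname(P), matrix(1 / 3, 20, 3))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_true(all(hyp$label == "WAKE"))        # tie broken by state order
  expect_error(predict(model, matrix(0, 2, 4)), "dimension mismatch")
})

test_that("balanced accuracy is the mean per-state recall in percent", {
  tr <- c("WAKE", "WAKE", "NREM", "NREM", "REM", "REM")
  expect_equal(balanced_accuracy(tr, tr), 100)
  # recalls (1.0, 0.5, 0.0) from a constructed confusion table
  pr <- c("WAKE", "WAKE", "NREM", "REM", "WAKE", "NREM")
  expect_equal(balanced_accuracy(tr, pr), 50)
  # UNKNOWN truth windows excluded
  expect_equal(balanced_accuracy(c(tr, "UNKNOWN"), c(pr, "WAKE")), 50)
  # absent state dropped with a warning
  expect_warning(
    ba <- balanced_accuracy(c("WAKE", "NREM"), c("WAKE", "NREM")),
    "absent")
  expect_equal(ba, 100)
})

test_that("training is deterministic and its loss trace decreases", {
  set.seed(43)
  X <- matrix(rnorm(120 * 10), 120)
  X[1:40, 1] <- X[1:40, 1] + 3               # separable classes
  X[41:80, 2] <- X[41:80, 2] + 3
  y <- rep(sleep_states(), each = 40)
  cfg <- sae_config(epochs = 60, batch_size = 40, seed = 7)
  m1 <- electome_sae(X, y, mu = 1e-2, config = cfg)
  m2 <- electome_sae(X, y, mu = 1e-2, config = cfg)
  expect_identical(coef(m1), coef(m2))
  expect_true(all(m1$H >= 0))
  # moving-average loss decreases over training
  tr <- m1$loss_trace
  expect_lt(mean(tail(tr, 10)), mean(head(tr, 10)))
  # a state missing from training labels is an error listing counts
  expect_error(electome_sae(X[1:80, ], y[1:80], mu = 1e-2, config = cfg),
               "REM=0")
})

test_that("held-out prediction on the synthetic cohort is accurate and
           beats chance per state", {
  tr <- cohort6_train()
  model <- sae_model6()
  pred <- predict(model, tr$test_tensor)
  ba <- balanced_accuracy(tr$test_truth, pred$label)
  expect_gte(ba, 85)
  keep <- tr$test_truth != unknown_state()
  for (st in sleep_states()) {
    recall <- mean(pred$label[keep][tr$test_truth[keep] == st] == st)
    expect_gt(recall, 1 / 3)
  }
})

test_that("electome factors are non-negative R x R x F tensors and the NREM
           factor localizes to a planted delta band", {
  model <- sae_model6()
  fac <- electome_factors(model)
  expect_length(fac$supervised, 3L)
  expect_length(fac$unsupervised, 29L)
  expect_identical(dim(fac$supervised$NREM), c(8L, 8L, 29L))
  expect_true(all(vapply(c(fac$supervised, fac$unsupervised),
                         function(a) all(a >= 0), logical(1))))
  # largest diagonal entry of the NREM factor sits in the delta band
  arr <- fac$supervised$NREM
  dg <- vapply(1:8, function(r) arr[r, r, ], numeric(29))
  peak_bin <- which(dg == max(dg), arr.ind = TRUE)[1]
  expect_lte(model$freqs[peak_bin], 4 + 1000 / 512)  # within one bin of 1-4 Hz
  expect_gte(model$freqs[peak_bin], 1 - 1000 / 512)
})

test_that("a single planted region's delta power is recovered in the NREM
           factor's region diagonal", {
  spec <- cohort_spec(n_mice = 2, recording_length_s = 300,
                      region_names = c("CxPrL", "NAc", "VTA"),
                      shared_component_gain = 0, artifact_rate = 0,
                      mouse_gain_sd = 0, seed = 17)
  sp <- default_state_spectra(spec$region_names)
  sp$NREM$components$region_weights <- I(list(c(1, 0, 0)))  # CxPrL only
  coh <- simulate_cohort(spec, sp)
  tens <- lapply(coh, function(cm)
    median_normalize(welch_feature_tensor(average_regions(cm$recording))))
  X <- do.call(rbind, lapply(tens, flatten_features))
  attr(X, "regions") <- tens[[1]]$regions
  attr(X, "freqs") <- tens[[1]]$freqs
  y <- unlist(lapply(coh, function(cm) cm$truth$states))
  model <- electome_sae(X, y, mu = 1e-2,
                        config = sae_config(epochs = 120, seed = 3))
  arr <- electome_factors(model)$supervised$NREM
  dg <- vapply(1:3, function(r) arr[r, r, ], numeric(29))
  peak <- which(dg == max(dg), arr.ind = TRUE)
  expect_identical(model$regions[peak[2]], "CxPrL")
  expect_lte(model$freqs[peak[1]], 4 + 1000 / 512)
})

test_that("nested cross-validation has the leave-one-mouse-out geometry", {
  # small fake per-mouse features keep this structural test fast
  set.seed(44)
  mk <- function(i) {
    X <- matrix(rnorm(60 * 8), 60)
    X[1:20, 1] <- X[1:20, 1] + 4; X[21:40, 2] <- X[21:40, 2] + 4
    list(x = X, y = rep(sleep_states(), each = 20))
  }
  mice <- lapply(1:9, mk)
  cfg <- sae_config(epochs = 40, batch_size = 30, seed = 5)
  cv <- nested_cv(lapply(mice, `[[`, "x"), lapply(mice, `[[`, "y"),
                  mu_grid = c(1e-2), config = cfg)
  expect_identical(nrow(cv$folds), 9L)         # one outer fold per mouse
  expect_identical(cv$n_inner, 3L)
  expect_identical(cv$n_val, 2L)               # 6 train / 2 validation
  expect_identical(cv$chosen_mu, 1e-2)         # single-point grid is trivial
  expect_s3_class(cv$final_model, "electome_sae")
  expect_true(all(cv$folds$balanced_accuracy >= 0 &
                    cv$folds$balanced_accuracy <= 100))
  # no gross overfitting: outer estimate within 5 points of held-in accuracy
  heldin <- mean(vapply(seq_along(mice), function(i) {
    balanced_accuracy(mice[[i]]$y,
                      predict(cv$final_model, mice[[i]]$x)$label)
  }, numeric(1)))
  expect_lte(abs(heldin - mean(cv$folds$balanced_accuracy)), 5)
  expect_gte(mean(cv$folds$balanced_accuracy), 85)
  expect_error(nested_cv(lapply(mice[1:3], `[[`, "x"),
                         lapply(mice[1:3], `[[`, "y"),
                         mu_grid = 1e-2, config = cfg),
               ">= 4 mice")
})

test_that("a large reconstruction weight degrades classification", {
  fx <- cohort6_fixture()
  X <- flatten_features(fx$tensors[[1]])
  attr(X, "valid_mask") <- fx$tensors[[1]]$valid_mask
  y <- fx$truths[[1]]$states
  truth2 <- fx$truths[[2]]$states
  truth2[!fx$tensors[[2]]$valid_mask] <- unknown_state()
  cfg <- sae_config(epochs = 80, seed = 5)
  acc <- vapply(c(1e-2, 1e3), function(mu) {
    m <- electome_sae(X, y, mu = mu, config = cfg)
    balanced_accuracy(truth2, predict(m, fx$tensors[[2]])$label)
  }, numeric(1))
  expect_gt(acc[1], acc[2] + 20)
})

test_that("single-region models on pure noise sit at chance", {
  set.seed(45)
  Xn <- matrix(rnorm(400 * 29), 400)
  yn <- sample(sleep_states(), 400, TRUE)
  Xtest <- matrix(rnorm(600 * 29), 600)
  ytest <- sample(sleep_states(), 600, TRUE)
  m <- electome_sae(Xn, yn, mu = 1e-2, config = sae_config(epochs = 60,
                                                           seed = 2))
  ba <- balanced_accuracy(ytest, predict(m, Xtest)$label)
  expect_gt(ba, 20); expect_lt(ba, 46)
})

test_that("model JSON serialization round-trips predictions exactly", {
  model <- sae_model6()
  path <- withr::local_tempfile(fileext = ".json")
  write_sae(model, path)
  model2 <- read_sae(path)
  tr <- cohort6_train()
  p1 <- predict(model, tr$test_tensor)
  p2 <- predict(model2, tr$test_tensor)
  expect_identical(p1$label, p2$label)
  expect_equal(p1$p_wake, p2$p_wake, tolerance = 1e-12)
})
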