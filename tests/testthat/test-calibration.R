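make_linear_data <- function(n = 40, p = 6, m = 3, seed = 21, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * m), p, m)
  Y <- X %*% B + 5 + noise * matrix(rnorm(n * m), n, m)
  list(X = X, Y = Y, B = B)
}

test_that("full-rank PLS reproduces noiseless linear responses", {
  d <- make_linear_data()
  fit <- pls_calibration(d$X, d$Y, ncomp = 6)
  expect_lt(max(abs(fit$fitted - d$Y)), 1e-8)
  # training-mean X predicts training-mean Y exactly
  pred_mean <- predict(fit, matrix(colMeans(d$X), 1))
  expect_equal(drop(pred_mean), colMeans(d$Y), ignore_attr = TRUE)
})

test_that("PLS at full rank matches multivariate OLS predictions", {
  d <- make_linear_data(noise = 0.3)
  fit <- pls_calibration(d$X, d$Y, ncomp = 6)
  ols <- lm(d$Y ~ d$X)
  Xnew <- matrix(rnorm(30), 5, 6)
  pred_pls <- predict(fit, Xnew)
  pred_ols <- cbind(1, Xnew) %*% coef(ols)
  expect_lt(max(abs(pred_pls - pred_ols)), 1e-6)
})

test_that("the first PLS weight follows the dominant covariance direction", {
  set.seed(9)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- X[, 1, drop = FALSE]
  fit <- pls_calibration(X, y, ncomp = 1)
  w <- fit$weights[, 1]
  # oracle: w maximizes cov(Xw, y) -> proportional to X'y
  w_star <- drop(crossprod(scale(X, scale = FALSE),
                           scale(y, scale = FALSE)))
  w_star <- w_star / sqrt(sum(w_star^2))
  expect_gt(abs(sum(w * w_star)), 0.999)
})

test_that("PLS predictions are invariant to training-sample order", {
  d <- make_linear_data(noise = 0.2)
  set.seed(17)
  perm <- sample(nrow(d$X))
  f1 <- pls_calibration(d$X, d$Y, ncomp = 4)
  f2 <- pls_calibration(d$X[perm, ], d$Y[perm, ], ncomp = 4)
  Xnew <- matrix(rnorm(30), 5, 6)
  expect_equal(predict(f1, Xnew), predict(f2, Xnew), tolerance = 1e-8)
})

test_that("PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_linear_data(n = 30, p = 8, m = 2, noise = 0.5)
  colnames(d$X) <- paste0("v", 1:8)
  fit <- pls_calibration(d$X, d$Y, ncomp = 3)
  ref <- mixOmics::pls(d$X, d$Y, ncomp = 3, scale = FALSE,
                       mode = "regression")
  Xnew <- matrix(rnorm(40), 5, 8, dimnames = list(NULL, paste0("v", 1:8)))
  pred_ref <- predict(ref, Xnew)$predict[, , 3]
  expect_equal(unname(predict(fit, Xnew)), unname(pred_ref),
               tolerance = 1e-6)
})

test_that("component selection tracks the true rank and resists noise", {
  # rank-4 latent structure: CV error flattens at the true rank
  set.seed(33)
  T4 <- matrix(rnorm(60 * 4), 60, 4)
  X <- T4 %*% matrix(rnorm(40), 4, 10) + 0.02 * matrix(rnorm(600), 60, 10)
  Y <- T4 %*% matrix(rnorm(16), 4, 4)
  k <- select_ncomp(X, Y, k_folds = 5, max_ncomp = 8, seed = 2)
  expect_lte(as.integer(k), 4L)

  # pure-noise responses: the smallest model wins
  Yn <- matrix(rnorm(60 * 4), 60, 4)
  kn <- select_ncomp(X, Yn, k_folds = 5, max_ncomp = 8, seed = 2)
  expect_equal(as.integer(kn), 1L)

  # identical fold seeding gives identical selections
  expect_identical(as.integer(select_ncomp(X, Y, 5, 8, seed = 7)),
                   as.integer(select_ncomp(X, Y, 5, 8, seed = 7)))
})

test_that("MLP training is deterministic and reproducible under a seed", {
  d <- make_linear_data(n = 30, p = 5, m = 2, noise = 0.1)
  cfg <- mlp_config(seed = 5, max_epochs = 50)
  f1 <- mlp_calibration(d$X, d$Y, hidden = c(6, 4), config = cfg)
  f2 <- mlp_calibration(d$X, d$Y, hidden = c(6, 4), config = cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("MLP with constant inputs predicts the mean response", {
  set.seed(14)
  X <- matrix(1, 25, 4)  # no information
  Y <- matrix(rnorm(50, mean = 30, sd = 5), 25, 2)
  fit <- mlp_calibration(X, Y, hidden = c(4, 3),
                         config = mlp_config(seed = 3, max_epochs = 100))
  pred <- predict(fit, matrix(1, 3, 4))
  for (j in 1:2)
    expect_equal(unname(pred[, j]), rep(mean(Y[, j]), 3),
                 tolerance = 0.05 * diff(range(Y[, j])))
})

test_that("accepted optimizer steps never increase the training objective", {
  d <- make_linear_data(n = 30, p = 5, m = 2, noise = 0.3)
  fit <- mlp_calibration(d$X, d$Y, hidden = c(6, 4),
                         config = mlp_config(seed = 5, max_epochs = 60))
  h <- fit$history
  expect_true(all(h$accepted))
  expect_true(all(h$F_after <= h$F_before))
})

test_that("MLP Jacobian matches central finite differences", {
  set.seed(3)
  sizes <- c(3L, 4L, 3L, 2L)
  n_par <- 4 * 4 + 3 * 5 + 2 * 4
  theta <- runif(n_par, -0.5, 0.5)
  X <- matrix(rnorm(15), 3, 5)
  Tm <- matrix(rnorm(10), 2, 5)
  wts <- voltacal:::.mlp_unpack(theta, sizes)
  fwd <- voltacal:::.mlp_forward(wts, X)
  J <- voltacal:::.mlp_jacobian(wts, X, fwd)
  ef <- function(th) {
    w <- voltacal:::.mlp_unpack(th, sizes)
    as.numeric(t(Tm - voltacal:::.mlp_forward(w, X)$Yh))
  }
  Jnum <- vapply(seq_len(n_par), function(j) {
    tp <- theta; tp[j] <- tp[j] + 1e-6
    tm <- theta; tm[j] <- tm[j] - 1e-6
    (ef(tp) - ef(tm)) / 2e-6
  }, numeric(10))
  expect_lt(max(abs(J - Jnum)), 1e-7)
})

test_that("single-sample and batch prediction agree", {
  d <- make_linear_data(n = 25, p = 5, m = 2, noise = 0.2)
  pfit <- pls_calibration(d$X, d$Y, ncomp = 3)
  mfit <- mlp_calibration(d$X, d$Y, hidden = c(5, 3),
                          config = mlp_config(seed = 2, max_epochs = 40))
  Xnew <- matrix(rnorm(20), 4, 5)
  for (fit in list(pfit, mfit)) {
    batch <- predict(fit, Xnew)
    rows <- t(sapply(seq_len(4), function(i)
      predict(fit, Xnew[i, , drop = FALSE])))
    expect_equal(unname(batch), unname(rows), tolerance = 1e-12)
  }
})

test_that("calibration datasets keep X and Y aligned", {
  ds <- calibration_dataset(matrix(1, 5, 10), matrix(1, 2, 10))
  expect_s3_class(ds, "calibration_dataset")
  expect_error(calibration_dataset(matrix(1, 5, 10), matrix(1, 2, 9)),
               "same number of samples")
  expect_error(pls_calibration(matrix(1, 10, 5), matrix(1, 9, 2)),
               "same number of samples")
})

test_that("fitted calibrations survive a JSON round-trip", {
  d <- make_linear_data(n = 30, p = 5, m = 2, noise = 0.2)
  Xnew <- matrix(rnorm(25), 5, 5)
  pfit <- pls_calibration(d$X, d$Y, ncomp = 3)
  mfit <- mlp_calibration(d$X, d$Y, hidden = c(5, 3),
                          config = mlp_config(seed = 2, max_epochs = 40))
  for (fit in list(pfit, mfit)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_calibration_json(fit, path)
    restored <- read_calibration_json(path)
    expect_equal(predict(restored, Xnew), predict(fit, Xnew),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("both calibration models recover concentrations on synthetic data", {
  ts <- generate_training_set()
  es <- generate_random_test_set(10, seed = 2,
                                 noise = noise_model(noise_sd = ts$noise_sd))
  ctr <- compress_set(ts$voltammograms)
  cte <- compress_set(es$voltammograms)
  X <- t(ctr$coefficients); Y <- t(ts$concentrations)
  Xt <- t(cte$coefficients); Yt <- t(es$concentrations)

  pfit <- pls_calibration(X, Y, ncomp = 12)
  R_pls <- diag(cor(predict(pfit, Xt), Yt))
  expect_true(all(R_pls[1:2] >= 0.9))  # paracetamol, diclofenac

  mfit <- mlp_calibration(X, Y, config = mlp_config(seed = 1))
  R_mlp <- diag(cor(predict(mfit, Xt), Yt))
  expect_true(all(R_mlp >= 0.9))
  expect_gte(diag(cor(predict(mfit, X), Y))[1] , 0.97)  # training fit
})
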