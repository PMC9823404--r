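test_that("identity predictions give the ideal regression line", {
  x <- c(2, 5, 9, 14, 20)
  cmp <- regression_comparison(x, x)
  expect_equal(cmp$R, 1)
  expect_equal(cmp$m, 1)
  expect_equal(cmp$b, 0, tolerance = 1e-12)
  expect_equal(cmp$sigma_res, 0, tolerance = 1e-12)

  cmp2 <- regression_comparison(2 * x, x)
  expect_equal(cmp2$m, 2)
  expect_equal(cmp2$b, 0, tolerance = 1e-12)
  expect_equal(cmp2$R, 1)
})

test_that("regression matches the closed-form OLS oracle", {
  expected <- 1:5
  obtained <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  cmp <- regression_comparison(obtained, expected, confidence = 0.95)
  o <- ols_oracle(obtained, expected)
  expect_equal(cmp$m, o$m, tolerance = 1e-6)
  expect_equal(cmp$b, o$b, tolerance = 1e-6)
  expect_equal(cmp$R, o$R, tolerance = 1e-6)
  expect_equal(cmp$sigma_res, o$sigma, tolerance = 1e-6)
  tq <- qt(0.975, 3)
  expect_equal(cmp$delta_m, tq * o$se_m, tolerance = 1e-6)
  expect_equal(cmp$delta_b, tq * o$se_b, tolerance = 1e-6)
})

test_that("regression comparison agrees with brute-force squared-error search", {
  set.seed(41)
  for (rep in 1:5) {
    x <- runif(8, 0, 10)
    y <- 2 * x + rnorm(8)
    cmp <- regression_comparison(y, x)
    sse <- function(p) sum((y - p[1] - p[2] * x)^2)
    brute <- optim(c(0, 1), sse, method = "BFGS",
                   control = list(reltol = 1e-14))
    expect_equal(cmp$b, brute$par[1], tolerance = 1e-5)
    expect_equal(cmp$m, brute$par[2], tolerance = 1e-5)
  }
})

test_that("regression preconditions are enforced", {
  expect_error(regression_comparison(1:5, 1:4), "equal length")
  expect_error(regression_comparison(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regression_comparison(1:5, rep(2, 5)), "zero variance")
})

test_that("recovery yield follows the mean-ratio definition", {
  expect_equal(recovery_yield(c(1, 2, 3), c(1, 2, 3))$Ry, 100)
  expect_equal(recovery_yield(2, 1)$Ry, 200)
  expect_equal(recovery_yield(c(8, 12), c(10, 10))$Ry, 100)
  expect_error(recovery_yield(c(1, 2), c(1, 0)), "undefined")

  # scale invariance
  obt <- c(3.2, 7.9, 1.4); expc <- c(3, 8, 1.5)
  expect_equal(recovery_yield(10 * obt, 10 * expc)$Ry,
               recovery_yield(obt, expc)$Ry)
  rr <- recovery_yield(obt, expc)
  expect_equal(rr$Ry, mean(rr$per_sample_recovery))
})

test_that("LOD and LOQ follow 3 and 10 sigma over slope", {
  expect_equal(lod_loq(sigma = 1, m = 1)$LOD, 3)
  expect_equal(lod_loq(sigma = 1, m = 1)$LOQ, 10)
  expect_equal(lod_loq(sigma = 0, m = 2)$LOD, 0)
  sr <- lod_loq(sigma = 1.2, m = 0.8)
  expect_equal(sr$LOD, 4.5)
  expect_equal(sr$LOQ, 15.0)
  expect_error(lod_loq(sigma = 1, m = -1), "positive")

  # exact 10/3 ratio for arbitrary inputs
  set.seed(6)
  for (rep in 1:10) {
    sr <- lod_loq(sigma = runif(1, 0.01, 5), m = runif(1, 0.1, 3))
    expect_equal(sr$LOQ / sr$LOD, 10 / 3)
  }
  # from a regression comparison
  cmp <- regression_comparison(c(1.1, 2.2, 2.9, 4.1), 1:4)
  sr2 <- lod_loq(cmp)
  expect_equal(sr2$sigma, cmp$sigma_res)
  expect_equal(sr2$LOD, 3 * cmp$sigma_res / cmp$m)
})

test_that("a perfect oracle model yields an ideal evaluation report", {
  set.seed(19)
  X <- matrix(rnorm(28 * 15), 28, 15)
  Y <- matrix(runif(4 * 15, 1, 80), 4, 15,
              dimnames = list(paste0("a", 1:4), NULL))
  train <- calibration_dataset(X[, 1:10], Y[, 1:10], "training")
  test <- calibration_dataset(X[, 11:15], Y[, 11:15], "testing")
  oracle <- structure(list(Xall = X, Yall = Y), class = "oracle_model")
  # exact lookup model: returns the true concentrations for known columns
  predict.oracle_model <<- function(object, newdata, ...) {
    idx <- apply(newdata, 1, function(r)
      which(colSums(abs(object$Xall - r)) < 1e-12)[1])
    t(object$Yall[, idx, drop = FALSE])
  }
  on.exit(rm("predict.oracle_model", envir = globalenv()), add = TRUE)
  rep <- evaluate_calibration(oracle, train, test, intercept_units = "umol")
  expect_true(all(abs(rep$regression$R - 1) < 1e-12))
  expect_true(all(abs(rep$recovery$Ry - 100) < 1e-10))
  expect_true(all(rep$sensitivity$LOD < 1e-10))
})

test_that("evaluation reports mirror the validation-table layout", {
  ts <- generate_training_set()
  es <- generate_random_test_set(10, seed = 3,
                                 noise = noise_model(noise_sd = ts$noise_sd))
  ctr <- compress_set(ts$voltammograms)
  cte <- compress_set(es$voltammograms)
  train <- calibration_dataset(ctr$coefficients, ts$concentrations,
                               "training")
  test <- calibration_dataset(cte$coefficients, es$concentrations, "testing")
  fit <- pls_calibration(train, ncomp = 12)
  rep <- evaluate_calibration(fit, train, test)
  analytes <- c("paracetamol", "diclofenac", "naproxen", "aspirin")
  expect_equal(nrow(rep$regression), 8L)  # 4 analytes x 2 stages
  expect_setequal(rep$regression$analyte, analytes)
  expect_setequal(rep$regression$stage, c("training", "testing"))
  expect_named(rep$regression, c("analyte", "stage", "R", "m", "delta_m",
                                 "b", "delta_b", "n", "sigma_res"))
  expect_equal(nrow(rep$sensitivity), 4L)
  # intercepts reported in mol/L by default: umol values scaled by 1e-6
  rep_u <- evaluate_calibration(fit, train, test, intercept_units = "umol")
  expect_equal(rep$regression$b, rep_u$regression$b * 1e-6)
})
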