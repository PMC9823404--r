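test_that("no sources means no signal", {
  v <- simulate_voltammogram(
    mixture_sample(0, 0, 0, 0, ascorbic = 0, glucose = 0, sds = 0),
    noise = noise_model(baseline_intercept = 0, baseline_slope = 0,
                        noise_sd = 0))
  expect_true(all(v$current == 0))
})

test_that("peak-top current is linear in concentration", {
  quiet <- noise_model(baseline_intercept = 0, baseline_slope = 0,
                       noise_sd = 0)
  for (analyte in c("paracetamol", "diclofenac", "naproxen", "aspirin")) {
    s1 <- do.call(mixture_sample,
                  c(stats::setNames(list(10), analyte),
                    list(ascorbic = 0, glucose = 0, sds = 0)))
    s2 <- do.call(mixture_sample,
                  c(stats::setNames(list(20), analyte),
                    list(ascorbic = 0, glucose = 0, sds = 0)))
    v1 <- simulate_voltammogram(s1, noise = quiet)
    v2 <- simulate_voltammogram(s2, noise = quiet)
    i <- which.max(v1$current)
    expect_equal(v2$current[i], 2 * v1$current[i], tolerance = 1e-9)
    # full-trace linearity, not just the peak top
    expect_equal(v2$current, 2 * v1$current, tolerance = 1e-9)
  }
})

test_that("paracetamol peak lands at the grid point nearest 0.446 V", {
  v <- simulate_voltammogram(
    mixture_sample(paracetamol = 80, ascorbic = 0, glucose = 0, sds = 0),
    noise = noise_model(baseline_intercept = 0, baseline_slope = 0,
                        noise_sd = 0))
  grid <- v$grid$potentials
  expect_equal(which.max(v$current), which.min(abs(grid - 0.446)))
})

test_that("mixture trace is the sum of single-analyte traces plus one baseline", {
  quiet0 <- noise_model(noise_sd = 0)
  mix <- simulate_voltammogram(
    mixture_sample(paracetamol = 30, diclofenac = 50, naproxen = 20,
                   aspirin = 70),
    noise = quiet0)
  baseline <- simulate_voltammogram(
    mixture_sample(0, 0, 0, 0, ascorbic = 0), noise = quiet0)
  singles <- lapply(
    list(list(paracetamol = 30, ascorbic = 0),
         list(diclofenac = 50, ascorbic = 0),
         list(naproxen = 20, ascorbic = 0),
         list(aspirin = 70, ascorbic = 0),
         list(ascorbic = 80)),
    function(args) {
      v <- do.call(mixture_sample, args)
      simulate_voltammogram(v, noise = quiet0)$current - baseline$current
    })
  expect_equal(mix$current, baseline$current + Reduce(`+`, singles),
               tolerance = 1e-10)
})

test_that("simulation is deterministic under an identical seed", {
  noisy <- noise_model(noise_sd = 0.3, seed = 11)
  v1 <- simulate_voltammogram(mixture_sample(paracetamol = 5), noise = noisy)
  v2 <- simulate_voltammogram(mixture_sample(paracetamol = 5), noise = noisy)
  expect_identical(v1$current, v2$current)

  ts1 <- generate_training_set(noise = noise_model(seed = 4))
  ts2 <- generate_training_set(noise = noise_model(seed = 4))
  expect_identical(ts1$voltammograms, ts2$voltammograms)
})

test_that("naproxen and aspirin traces are nearly indistinguishable", {
  quiet <- noise_model(baseline_intercept = 0, baseline_slope = 0,
                       noise_sd = 0)
  vn <- simulate_voltammogram(
    mixture_sample(naproxen = 40, ascorbic = 0, glucose = 0, sds = 0),
    noise = quiet)
  va <- simulate_voltammogram(
    mixture_sample(aspirin = 40, ascorbic = 0, glucose = 0, sds = 0),
    noise = quiet)
  expect_gt(cor(vn$current, va$current), 0.9)
})

test_that("training-set generation follows the design", {
  ts <- generate_training_set()
  expect_equal(dim(ts$voltammograms), c(177L, 81L))
  expect_equal(dim(ts$concentrations), c(4L, 81L))
  # column order matches design rows: first row is all -1 (0.5 uM each)
  expect_equal(unname(ts$concentrations[, 1]), rep(0.5, 4))
  expect_equal(unname(ts$concentrations[, 81]), rep(80, 4))
  # toy 2-level, 1-factor-per-analyte design
  toy <- matrix(c(-1, 1), 2, 4)
  ts2 <- generate_training_set(toy, noise = noise_model(noise_sd = 0))
  expect_equal(ncol(ts2$voltammograms), 2L)
  # out-of-domain design rejected
  expect_error(generate_training_set(matrix(2, 1, 4)), "domain")
})

test_that("random test sets are reproducible and uniform over the domain", {
  es1 <- generate_random_test_set(10, seed = 5)
  es2 <- generate_random_test_set(10, seed = 5)
  expect_identical(es1$voltammograms, es2$voltammograms)
  expect_equal(ncol(es1$voltammograms), 10L)
  expect_error(generate_random_test_set(0), "positive")

  conc <- sample_random_concentrations(100000, seed = 1)
  means <- rowMeans(conc[1:4, ])
  expect_true(all(abs(means - 40.25) < 0.01 * 40.25))
  expect_true(all(conc[1:4, ] >= 0.5 & conc[1:4, ] <= 80))
  expect_equal(unname(conc[5:7, 1]), c(80, 18.5, 22))
})

test_that("unknown peak owners and malformed samples are rejected", {
  bad <- default_peak_table()
  bad$owner[1] <- "ibuprofen"
  expect_error(
    simulate_voltammogram(mixture_sample(paracetamol = 1), peaks = bad),
    "unknown peak owner")
  expect_error(mixture_sample(paracetamol = -1), "non-negative")
})

test_that("saturation bends the concentration response smoothly", {
  quiet <- noise_model(baseline_intercept = 0, baseline_slope = 0,
                       noise_sd = 0)
  lin <- simulate_voltammogram(
    mixture_sample(paracetamol = 80, ascorbic = 0, glucose = 0, sds = 0),
    noise = quiet)
  sat <- simulate_voltammogram(
    mixture_sample(paracetamol = 80, ascorbic = 0, glucose = 0, sds = 0),
    noise = quiet, saturation = 40)
  i <- which.max(lin$current)
  expect_lt(sat$current[i], lin$current[i])
  expect_equal(sat$current[i] / lin$current[i], 40 * (1 - exp(-2)) / 80,
               tolerance = 1e-9)
})
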