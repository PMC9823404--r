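#' Potential grid for a differential-pulse scan
#'
#' The anodic scan used throughout the package: 177 equally spaced potentials
#' starting at 0 V with the optimized step potential of 0.00585 V, covering
#' the 0--1.05 V oxidation window of the four NSAIDs.
#'
#' @param start first potential (V).
#' @param step potential increment (V); must be positive.
#' @param n_points number of current samples per scan.
#' @return An object of class `potential_grid` with elements `start`, `step`,
#'   `n_points` and the evaluated `potentials` vector.
#' @examples
#' g <- potential_grid()
#' range(g$potentials)
#' @export
potential_grid <- function(start = 0, step = 0.00585, n_points = 177L) {
  stopifnot(is.numeric(start), length(start) == 1L, is.finite(start))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a single positive number")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("'n_points' must be an integer >= 2")
  structure(
    list(start = start, step = step, n_points = n_points,
         potentials = start + step * (seq_len(n_points) - 1)),
    class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("Potential grid: %d points, %.4f to %.4f V (step %.5f V)\n",
              x$n_points, x$potentials[1], x$potentials[x$n_points], x$step))
  invisible(x)
}

# Relative sensitivities anchored to the pH-10 anodic peak currents of the
# equimolar four-drug mix (7.26 : 8.81 : 18.10 uA for paracetamol :
# diclofenac : the merged naproxen+aspirin peak), absolute scale 0.1 uA per
# umol/L for paracetamol.  Naproxen and aspirin split the merged peak evenly.
.default_sens <- local({
  s_par <- 0.1
  c(par = s_par,
    dic = s_par * 8.81 / 7.26,
    nap = 0.5 * s_par * 18.10 / 7.26,
    asp = 0.5 * s_par * 18.10 / 7.26)
})

#' Default oxidation-peak table
#'
#' Gaussian peak parameters for the four NSAIDs and ascorbic acid on the
#' anodic scan.  Centers follow the observed oxidation potentials:
#' paracetamol 0.446 V, diclofenac 0.629 V with a secondary peak at 1.02 V
#' (40% of the primary sensitivity), naproxen 0.888 V and aspirin 0.880 V
#' (the strongly overlapped pair).  Glucose and sodium dodecyl sulfate are
#' not redox-active and carry no peak; they act on the baseline (see
#' [simulate_voltammogram()]).
#'
#' @return A data frame with columns `owner`, `center` (V), `width`
#'   (Gaussian sigma, V) and `sensitivity` (uA per umol/L).
#' @export
default_peak_table <- function() {
  data.frame(
    owner = c("paracetamol", "diclofenac", "diclofenac",
              "naproxen", "aspirin", "ascorbic"),
    center = c(0.446, 0.629, 1.02, 0.888, 0.880, 0.30),
    width = 0.05,
    sensitivity = c(.default_sens[["par"]], .default_sens[["dic"]],
                    0.4 * .default_sens[["dic"]], .default_sens[["nap"]],
                    .default_sens[["asp"]], 0.03),
    stringsAsFactors = FALSE)
}

.analytes <- c("paracetamol", "diclofenac", "naproxen", "aspirin")
.interferents <- c("ascorbic", "glucose", "sds")
.default_interferents <- c(ascorbic = 80, glucose = 18.5, sds = 22)

#' Mixture sample: four analytes plus fixed interferents
#'
#' @param paracetamol,diclofenac,naproxen,aspirin analyte concentrations
#'   (umol/L), non-negative.
#' @param ascorbic,glucose,sds interferent concentrations (umol/L); the
#'   defaults are the fixed levels used for every designed sample.
#' @return Named numeric vector of the seven concentrations.
#' @export
mixture_sample <- function(paracetamol = 0, diclofenac = 0, naproxen = 0,
                           aspirin = 0, ascorbic = 80, glucose = 18.5,
                           sds = 22) {
  conc <- c(paracetamol = paracetamol, diclofenac = diclofenac,
            naproxen = naproxen, aspirin = aspirin, ascorbic = ascorbic,
            glucose = glucose, sds = sds)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("all concentrations must be finite and non-negative")
  conc
}

#' Baseline and noise model for simulated scans
#'
#' The baseline is affine in potential; additive measurement noise is
#' i.i.d. Gaussian.  `noise_sd = NULL` requests the default calibration:
#' 1% of the maximum clean current of the generated sample set (resolved by
#' [generate_training_set()] and [generate_random_test_set()]).
#'
#' @param baseline_intercept baseline current at 0 V (uA).
#' @param baseline_slope baseline slope (uA per V) before interferent scaling.
#' @param noise_sd noise standard deviation (uA), or `NULL` for the 1% rule.
#' @param seed integer seed controlling the noise draws.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_intercept = 0.5, baseline_slope = 2,
                        noise_sd = NULL, seed = 1L) {
  if (!is.null(noise_sd) && (!is.numeric(noise_sd) || noise_sd < 0))
    stop("'noise_sd' must be NULL or a non-negative number")
  structure(list(baseline_intercept = baseline_intercept,
                 baseline_slope = baseline_slope,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# Clean (noise-free) current matrix for a 7 x n concentration matrix.
# Glucose and SDS scale the baseline slope multiplicatively by
# (1 + 0.001 * conc) each; redox peaks are Gaussian in potential with
# amplitude sensitivity * concentration (optionally saturating).
.clean_currents <- function(conc, peaks, grid, noise, saturation = Inf) {
  stopifnot(is.matrix(conc), nrow(conc) == 7L)
  unknown <- setdiff(peaks$owner, c(.analytes, .interferents))
  if (length(unknown))
    stop("unknown peak owner label(s): ", paste(unknown, collapse = ", "))
  E <- grid$potentials
  slope_scale <- (1 + 0.001 * conc["glucose", ]) * (1 + 0.001 * conc["sds", ])
  baseline <- outer(rep(noise$baseline_intercept, grid$n_points),
                    rep(1, ncol(conc))) +
    outer(E, slope_scale) * noise$baseline_slope
  eff <- conc[peaks$owner, , drop = FALSE]
  if (is.finite(saturation)) {
    if (saturation <= 0) stop("'saturation' must be positive")
    eff <- saturation * (1 - exp(-eff / saturation))
  }
  shapes <- exp(-outer(E, peaks$center, "-")^2 / (2 * peaks$width^2))
  baseline + shapes %*% (peaks$sensitivity * eff)
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate one differential-pulse voltammogram
#'
#' Builds the anodic current trace of a mixture as an affine baseline plus
#' one Gaussian oxidation peak per table row, each with amplitude
#' `sensitivity * concentration(owner)`, plus i.i.d. Gaussian noise.  The
#' trace is strictly additive in the peak sources, making the simulated data
#' linear in concentration by construction; the optional `saturation` term
#' (umol/L) replaces each peak's concentration by
#' `sat * (1 - exp(-c / sat))`, injecting the mild nonlinearity seen when
#' electrode response flattens at high analyte load.
#'
#' @param sample named concentrations from [mixture_sample()].
#' @param peaks peak table as from [default_peak_table()].
#' @param grid a [potential_grid()].
#' @param noise a [noise_model()]; `noise_sd = NULL` is treated as 0 for a
#'   single scan (the 1% rule needs a sample set to refer to).
#' @param saturation saturation scale in umol/L; `Inf` (default) disables it.
#' @return An object of class `voltammogram`: list with `grid` and `current`
#'   (uA, length `grid$n_points`).
#' @examples
#' v <- simulate_voltammogram(mixture_sample(paracetamol = 40))
#' v$grid$potentials[which.max(v$current)]
#' @export
simulate_voltammogram <- function(sample, peaks = default_peak_table(),
                                  grid = potential_grid(),
                                  noise = noise_model(noise_sd = 0),
                                  saturation = Inf) {
  if (!all(c(.analytes, .interferents) %in% names(sample)))
    stop("'sample' must name all seven species; see mixture_sample()")
  conc <- matrix(sample[c(.analytes, .interferents)], ncol = 1,
                 dimnames = list(c(.analytes, .interferents), NULL))
  clean <- .clean_currents(conc, peaks, grid, noise, saturation)
  sdv <- if (is.null(noise$noise_sd)) 0 else noise$noise_sd
  eps <- if (sdv > 0)
    .with_seed(noise$seed, rnorm(grid$n_points, sd = sdv)) else 0
  structure(list(grid = grid, current = drop(clean) + eps),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("Voltammogram: %d points, current %.3f to %.3f uA\n",
              x$grid$n_points, min(x$current), max(x$current)))
  invisible(x)
}

#' @export
plot.voltammogram <- function(x, ...) {
  plot(x$grid$potentials, x$current, type = "l",
       xlab = "Potential (V)", ylab = "Current (uA)", ...)
  invisible(x)
}

#' Draw random mixture concentrations inside the calibration domain
#'
#' Analyte concentrations are i.i.d. uniform on `[lo, hi]` per analyte;
#' interferents stay at their fixed levels.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param lo,hi analyte concentration bounds (umol/L).
#' @return 7 x n concentration matrix (species as rows).
#' @export
sample_random_concentrations <- function(n, seed = 1L, lo = 0.5, hi = 80) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  analyte <- .with_seed(seed, matrix(runif(4L * n, lo, hi), nrow = 4L))
  conc <- rbind(analyte, matrix(.default_interferents, nrow = 3L, ncol = n))
  rownames(conc) <- c(.analytes, .interferents)
  conc
}

.conc_from_design <- function(design, levels = c(0.5, 40.25, 80)) {
  coded <- if (inherits(design, "design_table")) design$coded else
    as.matrix(design)
  if (ncol(coded) != 4L)
    stop("the calibration design must have 4 factors (one per analyte)")
  actual <- levels[1] + (coded + 1) / 2 * (levels[3] - levels[1])
  if (any(actual < 0.5 - 1e-9) || any(actual > 80 + 1e-9))
    stop("design concentrations outside the calibration domain [0.5, 80]")
  conc <- t(actual)
  rownames(conc) <- .analytes
  rbind(conc, matrix(.default_interferents, nrow = 3L, ncol = ncol(conc),
                     dimnames = list(.interferents, NULL)))
}

.finish_set <- function(conc, peaks, grid, noise, saturation, seed) {
  clean <- .clean_currents(conc, peaks, grid, noise, saturation)
  sdv <- noise$noise_sd
  if (is.null(sdv)) sdv <- 0.01 * max(clean)
  eps <- if (sdv > 0)
    .with_seed(seed, matrix(rnorm(length(clean), sd = sdv), nrow(clean)))
  else 0
  V <- clean + eps
  colnames(V) <- sprintf("s%03d", seq_len(ncol(V)))
  conc_out <- conc
  colnames(conc_out) <- colnames(V)
  list(voltammograms = V,
       concentrations = conc_out[.analytes, , drop = FALSE],
       all_concentrations = conc_out, grid = grid, noise_sd = sdv)
}

#' Generate the designed calibration set of voltammograms
#'
#' Simulates one scan per row of the 3^4 factorial design (81 mixtures by
#' default), with factor levels mapped to the analyte concentrations
#' 0.5 / 40.25 / 80 umol/L (range minimum, arithmetic midpoint, maximum)
#' and the interferents fixed at their standard levels.
#'
#' @param design a [full_factorial()] design (or coded matrix) with one
#'   factor per analyte; `NULL` builds the default 3^4 design.
#' @param peaks,grid,noise,saturation as in [simulate_voltammogram()];
#'   `noise_sd = NULL` resolves to 1% of the maximum clean current of the set.
#' @param levels physical concentrations (umol/L) for coded -1/0/+1.
#' @return List with `voltammograms` (n_points x n, columns in design-row
#'   order), `concentrations` (4 x n, analytes as rows),
#'   `all_concentrations` (7 x n), `grid` and the resolved `noise_sd`.
#' @examples
#' ts <- generate_training_set()
#' dim(ts$voltammograms)
#' @export
generate_training_set <- function(design = NULL,
                                  peaks = default_peak_table(),
                                  grid = potential_grid(),
                                  noise = noise_model(),
                                  levels = c(0.5, 40.25, 80),
                                  saturation = Inf) {
  if (is.null(design)) design <- full_factorial(3L, 4L)
  conc <- .conc_from_design(design, levels)
  .finish_set(conc, peaks, grid, noise, saturation, noise$seed)
}

#' Generate a random external test set
#'
#' Analyte concentrations are drawn i.i.d. uniform over the calibration
#' domain (0.5--80 umol/L); scans are then simulated as for the training set.
#'
#' @param n number of test mixtures (the external validation set size).
#' @param seed integer seed for both the concentration draws and the noise.
#' @inheritParams generate_training_set
#' @return Same structure as [generate_training_set()].
#' @export
generate_random_test_set <- function(n = 10L, seed = 1L,
                                     peaks = default_peak_table(),
                                     grid = potential_grid(),
                                     noise = noise_model(),
                                     saturation = Inf) {
  conc <- sample_random_concentrations(n, seed = seed)
  .finish_set(conc, peaks, grid, noise, saturation, seed + 1L)
}
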