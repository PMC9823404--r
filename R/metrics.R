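#' Obtained-versus-expected linear regression
#'
#' Ordinary least squares of the obtained (predicted) concentrations on the
#' expected (true) ones.  An ideal calibration yields the identity line:
#' slope 1, intercept 0, correlation 1.  The slope and intercept half-widths
#' are two-sided t-based confidence bounds at the requested level.
#'
#' @param obtained predicted concentrations.
#' @param expected reference concentrations (same length, same units).
#' @param confidence confidence level for the half-widths (default 0.95).
#' @return Object of class `regression_comparison`: `R` (Pearson
#'   correlation), `m`, `delta_m`, `b`, `delta_b`, `n`, `sigma_res`
#'   (residual standard deviation), `confidence`.
#' @examples
#' regression_comparison(c(1.1, 1.9, 3.2, 3.8, 5.1), 1:5)
#' @export
regression_comparison <- function(obtained, expected, confidence = 0.95) {
  if (length(obtained) != length(expected))
    stop("'obtained' and 'expected' must have equal length")
  n <- length(obtained)
  if (n < 3L) stop("need at least 3 points for the comparison regression")
  if (var(expected) == 0)
    stop("'expected' has zero variance; the regression is undefined")
  fit <- lm(obtained ~ expected)
  # a perfect calibration line triggers R's "essentially perfect fit"
  # warning in summary.lm; zero residual scatter is a legitimate input here
  sm_full <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- sm_full$coefficients
  tq <- qt(1 - (1 - confidence) / 2, df = n - 2L)
  structure(list(R = cor(obtained, expected),
                 m = unname(coef(fit)[2]), delta_m = tq * sm[2, 2],
                 b = unname(coef(fit)[1]), delta_b = tq * sm[1, 2],
                 n = n, sigma_res = sm_full$sigma,
                 confidence = confidence),
            class = "regression_comparison")
}

#' @export
print.regression_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Obtained vs expected (n = %d): R = %.4f, m = %.4f +/- %.4f, b = %.4g +/- %.4g\n",
    x$n, x$R, x$m, x$delta_m, x$b, x$delta_b))
  cat(sprintf("residual SD: %.4g (%.0f%% confidence half-widths)\n",
              x$sigma_res, 100 * x$confidence))
  invisible(x)
}

#' Recovery yield of a prediction set
#'
#' Mean of the per-sample percentage recoveries
#' `100 * (1 + (y_i - y_exp_i) / y_exp_i) = 100 * y_i / y_exp_i`;
#' 100% is ideal.
#'
#' @param obtained predicted concentrations.
#' @param expected reference concentrations; must all be nonzero.
#' @return Object of class `recovery_report`: `per_sample_recovery` (%),
#'   `Ry` (mean %), `N`.
#' @examples
#' recovery_yield(c(8, 12), c(10, 10))$Ry  # symmetric errors average to 100
#' @export
recovery_yield <- function(obtained, expected) {
  if (length(obtained) != length(expected))
    stop("'obtained' and 'expected' must have equal length")
  if (any(expected == 0))
    stop("recovery yield is undefined for expected values of 0")
  per <- 100 * obtained / expected
  structure(list(per_sample_recovery = per, Ry = mean(per),
                 N = length(per)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery yield: Ry = %.1f%% over %d samples\n", x$Ry, x$N))
  invisible(x)
}

#' Limits of detection and quantification
#'
#' `LOD = 3 sigma / m` and `LOQ = 10 sigma / m`, with `m` the slope of the
#' obtained-versus-expected calibration line and `sigma` the residual
#' standard deviation of that regression (the response scatter around the
#' line).
#'
#' @param comparison a [regression_comparison()]; alternatively supply
#'   `sigma` and `m` directly.
#' @param sigma response standard deviation (same units as the
#'   concentrations).
#' @param m calibration slope; must be positive.
#' @return Object of class `sensitivity_report`: `LOD`, `LOQ` (umol/L),
#'   `sigma`, `m`.
#' @examples
#' lod_loq(sigma = 1.2, m = 0.8)
#' @export
lod_loq <- function(comparison = NULL, sigma = NULL, m = NULL) {
  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "regression_comparison"))
    sigma <- comparison$sigma_res
    m <- comparison$m
  }
  if (is.null(sigma) || is.null(m))
    stop("supply either a regression_comparison or both 'sigma' and 'm'")
  if (m <= 0) stop("'m' must be positive: the calibration slope")
  if (sigma < 0) stop("'sigma' must be non-negative")
  structure(list(LOD = 3 * sigma / m, LOQ = 10 * sigma / m,
                 sigma = sigma, m = m),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("LOD = %.4g, LOQ = %.4g (sigma = %.4g, m = %.4g)\n",
              x$LOD, x$LOQ, x$sigma, x$m))
  invisible(x)
}

#' Full per-analyte evaluation of a calibration model
#'
#' For each analyte: the obtained-versus-expected regression on the training
#' and testing sets, the recovery yields, and the detection/quantification
#' limits from the testing regression.  Mirrors the standard validation
#' table layout (R, m, delta m, b, delta b per stage; Ry per stage;
#' LOD/LOQ).
#'
#' @param model a fitted calibration model with a `predict` method accepting
#'   a samples x features matrix.
#' @param train,test [calibration_dataset()] objects (features x samples).
#' @param confidence confidence level for the regression half-widths.
#' @param intercept_units `"mol"` (default) reports the intercept and its
#'   half-width in mol/L; `"umol"` keeps umol/L.
#' @return Object of class `calibration_report` with data frames
#'   `regression` (analyte x stage rows), `recovery` and `sensitivity`.
#' @export
evaluate_calibration <- function(model, train, test, confidence = 0.95,
                                 intercept_units = c("mol", "umol")) {
  stopifnot(inherits(train, "calibration_dataset"),
            inherits(test, "calibration_dataset"))
  intercept_units <- match.arg(intercept_units)
  b_scale <- if (intercept_units == "mol") 1e-6 else 1
  analytes <- rownames(train$Y)
  if (is.null(analytes)) analytes <- paste0("analyte", seq_len(nrow(train$Y)))
  pred <- list(training = predict(model, t(train$X)),
               testing = predict(model, t(test$X)))
  truth <- list(training = t(train$Y), testing = t(test$Y))
  reg <- list(); rec <- list(); sens <- list()
  for (a in seq_along(analytes)) {
    for (stage in c("training", "testing")) {
      cmp <- regression_comparison(pred[[stage]][, a], truth[[stage]][, a],
                                   confidence)
      reg[[length(reg) + 1L]] <- data.frame(
        analyte = analytes[a], stage = stage, R = cmp$R,
        m = cmp$m, delta_m = cmp$delta_m,
        b = cmp$b * b_scale, delta_b = cmp$delta_b * b_scale,
        n = cmp$n, sigma_res = cmp$sigma_res)
      ry <- recovery_yield(pred[[stage]][, a], truth[[stage]][, a])
      rec[[length(rec) + 1L]] <- data.frame(
        analyte = analytes[a], stage = stage, Ry = ry$Ry, N = ry$N)
      if (stage == "testing") {
        sr <- lod_loq(cmp)
        sens[[length(sens) + 1L]] <- data.frame(
          analyte = analytes[a], sigma = sr$sigma, m = sr$m,
          LOD = sr$LOD, LOQ = sr$LOQ)
      }
    }
  }
  structure(list(regression = do.call(rbind, reg),
                 recovery = do.call(rbind, rec),
                 sensitivity = do.call(rbind, sens),
                 confidence = confidence,
                 intercept_units = intercept_units),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, digits = 4, ...) {
  cat("Obtained vs expected regression (b in",
      if (x$intercept_units == "mol") "mol/L" else "umol/L", "):\n")
  print(format(x$regression, digits = digits), row.names = FALSE)
  cat("\nRecovery yield (%):\n")
  print(format(x$recovery, digits = digits), row.names = FALSE)
  cat("\nDetection limits (umol/L, from the testing regression):\n")
  print(format(x$sensitivity, digits = digits), row.names = FALSE)
  invisible(x)
}
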