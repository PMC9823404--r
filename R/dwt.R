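# Daubechies orthonormal scaling (low-pass decomposition) filters, standard
# extremal-phase coefficients.  db1 is the Haar wavelet.
.db_dec_lo <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965))

.wavelet_filters <- function(wavelet) {
  if (identical(wavelet, "haar")) wavelet <- "db1"
  dec_lo <- .db_dec_lo[[wavelet]]
  if (is.null(dec_lo))
    stop("unsupported wavelet '", wavelet, "'; available: ",
         paste(c(names(.db_dec_lo), "haar"), collapse = ", "))
  rec_lo <- rev(dec_lo)
  dec_hi <- (-1)^seq_along(rec_lo) * rec_lo  # quadrature mirror
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rev(dec_hi), length = length(dec_lo))
}

.conv_full <- function(x, f) {
  n <- length(x); L <- length(f)
  y <- numeric(n + L - 1)
  for (j in seq_len(L)) {
    idx <- j:(j + n - 1)
    y[idx] <- y[idx] + f[j] * x
  }
  y
}

# Half-point symmetric extension by k samples on each side
# (... x3 x2 x1 | x1 x2 ... xn | xn x(n-1) ...).
.sym_ext <- function(x, k) {
  n <- length(x)
  c(x[pmin(k:1, n)], x, x[pmax(n:(n - k + 1), 1)])
}

# One analysis step: symmetric extension, filtering, dyadic decimation.
# Output length floor((n + L - 1) / 2).
.dwt_step <- function(x, f) {
  L <- length(f)
  y <- .conv_full(.sym_ext(x, L - 1), f)
  y <- y[L:(length(y) - L + 1)]
  y[seq(2L, length(y), by = 2L)]
}

# One synthesis step: dyadic upsampling, filtering, boundary trim to
# 2 * n_coeff - L + 2 samples, then cut to the pre-analysis length.
.idwt_step <- function(cA, cD, filters, out_len) {
  n <- length(cA)
  up <- function(cv) {
    u <- numeric(2 * n)
    u[seq(1L, 2 * n, by = 2L)] <- cv
    u
  }
  y <- .conv_full(up(cA), filters$rec_lo) + .conv_full(up(cD), filters$rec_hi)
  L <- filters$length
  y <- y[(L - 1):(2 * n)]
  y[seq_len(out_len)]
}

#' Approximation-coefficient length after one analysis step
#'
#' The cascade recurrence for symmetric-extension filtering with an
#' `filter_length`-tap filter: `floor((n + filter_length - 1) / 2)` per
#' level.  For 177 samples and the 8-tap db4 filter this gives
#' 177 -> 92 -> 49 -> 28 over three levels.
#'
#' @param n signal length entering the step (or original length if
#'   `level > 1`).
#' @param wavelet wavelet name (`"db1"`...`"db4"` or `"haar"`).
#' @param level number of cascade levels to apply.
#' @return Integer coefficient length after `level` steps.
#' @export
dwt_coeff_length <- function(n, wavelet = "db4", level = 1L) {
  L <- .wavelet_filters(wavelet)$length
  for (i in seq_len(level)) n <- (n + L - 1) %/% 2
  as.integer(n)
}

#' Multi-level discrete wavelet decomposition
#'
#' Iterated two-channel analysis filter bank with half-point symmetric
#' boundary extension.  Both the approximation (low-pass) and detail
#' (high-pass) branches are kept so the transform is exactly invertible by
#' [dwt_reconstruct()].
#'
#' @param signal numeric vector.
#' @param wavelet wavelet name (see [dwt_coeff_length()]).
#' @param level decomposition depth (>= 1).
#' @return List of class `dwt_decomposition`: `approximation` (deepest-level
#'   coefficients), `details` (list, level 1 first), `lengths` (input length
#'   at each level), `wavelet`, `level`, `original_length`.
#' @export
dwt_decompose <- function(signal, wavelet = "db4", level = 3L) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("'level' must be an integer >= 1")
  if (!all(is.finite(signal))) stop("'signal' must be finite")
  filters <- .wavelet_filters(wavelet)
  x <- as.numeric(signal)
  details <- vector("list", level)
  lengths <- integer(level)
  for (l in seq_len(level)) {
    if (length(x) < filters$length)
      stop(sprintf(
        "signal too short for level %d with the %d-tap '%s' filter", l,
        filters$length, wavelet))
    lengths[l] <- length(x)
    details[[l]] <- .dwt_step(x, filters$dec_hi)
    x <- .dwt_step(x, filters$dec_lo)
  }
  structure(list(approximation = x, details = details, lengths = lengths,
                 wavelet = wavelet, level = level,
                 original_length = length(signal)),
            class = "dwt_decomposition")
}

#' Compress a signal to its approximation coefficients
#'
#' Runs [dwt_decompose()] and discards the detail branches: the standard
#' voltammogram pretreatment that reduces a 177-point scan to 28 smooth
#' db4 level-3 coefficients.
#'
#' @inheritParams dwt_decompose
#' @return Numeric vector of deepest-level approximation coefficients.
#' @examples
#' length(dwt_compress(sin(seq(0, 3, length.out = 177)), "db4", 3))  # 28
#' @export
dwt_compress <- function(signal, wavelet = "db4", level = 3L) {
  dwt_decompose(signal, wavelet, level)$approximation
}

#' Reconstruct a signal from wavelet coefficients
#'
#' Inverse cascade.  Given a full `dwt_decomposition` the reconstruction is
#' exact (perfect-reconstruction filter bank); given bare approximation
#' coefficients the detail branches are taken as zero, yielding the
#' smooth approximation-only signal used for compression.
#'
#' @param coefficients a `dwt_decomposition`, or a numeric vector of
#'   approximation coefficients.
#' @param wavelet,level,original_length required when `coefficients` is a
#'   bare vector; ignored otherwise.
#' @return Numeric vector of length `original_length`.
#' @export
dwt_reconstruct <- function(coefficients, wavelet = "db4", level = 3L,
                            original_length = NULL) {
  if (inherits(coefficients, "dwt_decomposition")) {
    dec <- coefficients
  } else {
    if (is.null(original_length))
      stop("'original_length' is required to reconstruct from bare ",
           "approximation coefficients")
    lengths <- integer(level)
    n <- original_length
    L <- .wavelet_filters(wavelet)$length
    for (l in seq_len(level)) {
      lengths[l] <- n
      n <- (n + L - 1) %/% 2
    }
    if (n != length(coefficients))
      stop(sprintf(
        "coefficient length %d is inconsistent with original_length %d at level %d (expected %d)",
        length(coefficients), original_length, level, n))
    dec <- list(approximation = coefficients,
                details = lapply(lengths, function(m)
                  numeric(dwt_coeff_length(m, wavelet, 1L))),
                lengths = lengths, wavelet = wavelet, level = level,
                original_length = original_length)
  }
  filters <- .wavelet_filters(dec$wavelet)
  x <- dec$approximation
  for (l in rev(seq_len(dec$level)))
    x <- .idwt_step(x, dec$details[[l]], filters, dec$lengths[l])
  x
}

#' Similarity between an original trace and its reconstruction
#'
#' Pearson correlation coefficient between the two traces, the bounded
#' similarity score used to judge how much signal shape survives
#' approximation-only compression.
#'
#' @param original,recovered equal-length numeric vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
comparison_factor <- function(original, recovered) {
  if (length(original) != length(recovered))
    stop("'original' and 'recovered' must have equal length")
  if (sd(original) == 0 || sd(recovered) == 0)
    stop("comparison factor undefined for zero-variance traces")
  cor(original, recovered)
}

#' Compress a set of voltammograms
#'
#' Applies [dwt_compress()] column-wise to a signals x samples matrix and
#' scores each sample by the comparison factor between the original trace
#' and its approximation-only reconstruction.
#'
#' @param signals numeric matrix, one voltammogram per column (e.g. 177 x 81).
#' @inheritParams dwt_decompose
#' @return Object of class `compressed_set`: `coefficients`
#'   (n_coeff x n_samples), `wavelet`, `level`, `original_length`,
#'   `comparison_factors` (per sample) and `mean_comparison_factor`.
#' @export
compress_set <- function(signals, wavelet = "db4", level = 3L) {
  signals <- as.matrix(signals)
  n <- nrow(signals)
  coeffs <- apply(signals, 2, dwt_compress, wavelet = wavelet, level = level)
  if (!is.matrix(coeffs)) coeffs <- matrix(coeffs, ncol = ncol(signals))
  colnames(coeffs) <- colnames(signals)
  cf <- vapply(seq_len(ncol(signals)), function(j)
    comparison_factor(signals[, j],
                      dwt_reconstruct(coeffs[, j], wavelet, level, n)),
    numeric(1))
  structure(list(coefficients = coeffs, wavelet = wavelet,
                 level = as.integer(level), original_length = n,
                 comparison_factors = cf,
                 mean_comparison_factor = mean(cf)),
            class = "compressed_set")
}

#' @export
print.compressed_set <- function(x, ...) {
  cat(sprintf(
    "Compressed set: %d x %d (%s, level %d, from %d points)\n",
    nrow(x$coefficients), ncol(x$coefficients), x$wavelet, x$level,
    x$original_length))
  cat(sprintf("mean comparison factor: %.4f\n", x$mean_comparison_factor))
  invisible(x)
}
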