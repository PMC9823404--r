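#' Full factorial design in coded levels
#'
#' All `levels^factors` combinations of equally spaced coded levels on
#' `[-1, 1]` (for three levels: -1, 0, +1), in lexicographic row order with
#' the first factor varying slowest.
#'
#' @param levels number of levels per factor (>= 2).
#' @param factors number of factors (>= 1).
#' @param factor_names optional character vector of factor labels.
#' @return A `design_table` with the coded matrix and `kind = "full_factorial"`.
#' @examples
#' nrow(full_factorial(3, 4)$coded)  # 81 calibration mixtures
#' @export
full_factorial <- function(levels, factors, factor_names = NULL) {
  levels <- as.integer(levels); factors <- as.integer(factors)
  if (is.na(levels) || levels < 2L) stop("'levels' must be an integer >= 2")
  if (is.na(factors) || factors < 1L) stop("'factors' must be an integer >= 1")
  lv <- seq(-1, 1, length.out = levels)
  grids <- rev(expand.grid(rep(list(lv), factors)))  # first factor slowest
  coded <- as.matrix(grids)
  dimnames(coded) <- NULL
  new_design_table(coded, kind = "full_factorial", factor_names = factor_names)
}

#' Box-Behnken design in coded levels
#'
#' Edge-midpoint construction: for every pair of factors the four
#' `(+/-1, +/-1)` combinations with all remaining factors at 0, followed by
#' `center_points` all-zero rows.  With 4 factors and 3 center points this
#' gives the 27-run plan used to optimize the four pulse-voltammetry
#' parameters (step potential, interval time, modulation time, modulation
#' amplitude).
#'
#' @param factors number of factors; 3, 4 or 5.
#' @param center_points number of center replicates (>= 1).
#' @param factor_names optional factor labels.
#' @return A `design_table` with `kind = "box_behnken"`.
#' @examples
#' nrow(box_behnken(4, 3)$coded)  # 27 runs
#' @export
box_behnken <- function(factors = 4L, center_points = 3L,
                        factor_names = NULL) {
  factors <- as.integer(factors)
  if (!factors %in% 3:5)
    stop("'factors' must be 3, 4 or 5 for the edge-midpoint construction")
  center_points <- as.integer(center_points)
  if (is.na(center_points) || center_points < 1L)
    stop("'center_points' must be an integer >= 1")
  pairs <- utils::combn(factors, 2L)
  combos <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    block <- matrix(0, 4L, factors)
    block[, pairs[, k]] <- combos
    block
  })
  coded <- rbind(do.call(rbind, rows), matrix(0, center_points, factors))
  new_design_table(coded, kind = "box_behnken", factor_names = factor_names)
}

new_design_table <- function(coded, kind, factor_names = NULL,
                             actual = NULL, ranges = NULL) {
  if (is.null(factor_names))
    factor_names <- paste0("X", seq_len(ncol(coded)))
  stopifnot(length(factor_names) == ncol(coded))
  colnames(coded) <- factor_names
  structure(list(coded = coded, actual = actual, ranges = ranges,
                 factor_names = factor_names, kind = kind),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("%s design: %d runs x %d factors (%s)\n",
              x$kind, nrow(x$coded), ncol(x$coded),
              paste(x$factor_names, collapse = ", ")))
  if (!is.null(x$actual)) cat("physical levels attached\n")
  invisible(x)
}

#' Physical range of one design factor
#'
#' @param name factor label.
#' @param low,high physical bounds mapped to coded -1 and +1; `low < high`.
#' @param units unit string (informational).
#' @return An object of class `factor_range`.
#' @export
factor_range <- function(name, low, high, units = "") {
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stop("'low' must be strictly less than 'high'")
  structure(list(name = name, low = low, high = high, units = units),
            class = "factor_range")
}

#' Default physical ranges of the four DPV factors
#'
#' The instrument ranges are not part of the published optimization, so these
#' defaults simply bracket the reported optimal settings (step potential
#' 0.00585 V, interval time 0.75 s, modulation time 0.05 s, modulation
#' amplitude 0.05 V) symmetrically enough that the optimum is representable
#' inside the coded cube.
#'
#' @return List of four [factor_range()] objects.
#' @export
dpv_factor_ranges <- function() {
  list(factor_range("step_potential", 0.002, 0.01, "V"),
       factor_range("interval_time", 0.25, 1.25, "s"),
       factor_range("modulation_time", 0.05, 0.25, "s"),
       factor_range("modulation_amplitude", 0.025, 0.125, "V"))
}

.range_bounds <- function(ranges, k) {
  if (length(ranges) != k)
    stop("need exactly one factor range per design factor")
  ok <- vapply(ranges, inherits, logical(1), "factor_range")
  if (!all(ok)) stop("'ranges' must be a list of factor_range objects")
  list(low = vapply(ranges, `[[`, numeric(1), "low"),
       high = vapply(ranges, `[[`, numeric(1), "high"))
}

#' Map a coded design to physical units
#'
#' Affine per-factor map: `actual = low + (coded + 1)/2 * (high - low)`, so
#' coded 0 is the physical midpoint.
#'
#' @param design a `design_table`.
#' @param ranges list of [factor_range()], one per factor.
#' @return The design with the `actual` matrix (and ranges) attached.
#' @export
to_actual <- function(design, ranges) {
  stopifnot(inherits(design, "design_table"))
  b <- .range_bounds(ranges, ncol(design$coded))
  actual <- sweep(sweep(design$coded + 1, 2, (b$high - b$low) / 2, "*"),
                  2, b$low, "+")
  colnames(actual) <- vapply(ranges, `[[`, character(1), "name")
  design$actual <- actual
  design$ranges <- ranges
  design$factor_names <- colnames(actual)
  colnames(design$coded) <- colnames(actual)
  design
}

#' Invert the physical-unit map back to coded levels
#'
#' @param actual matrix of physical settings (runs x factors).
#' @param ranges list of [factor_range()], one per column.
#' @return Matrix of coded levels.
#' @export
to_coded <- function(actual, ranges) {
  actual <- as.matrix(actual)
  b <- .range_bounds(ranges, ncol(actual))
  sweep(sweep(actual, 2, b$low, "-"), 2, (b$high - b$low) / 2, "/") - 1
}
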