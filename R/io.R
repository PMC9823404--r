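#' Read and write voltammogram matrices as CSV
#'
#' On disk the matrix keeps the chemometric orientation (samples as
#' columns): the first column is `potential_V`, followed by one current
#' column per sample (`s001`, `s002`, ...) in uA.
#'
#' @param path file path.
#' @param grid a [potential_grid()].
#' @param currents n_points x n_samples matrix (uA).
#' @return `read_voltammogram_csv()`: list with `grid` (potentials vector)
#'   and `currents` matrix.
#' @export
write_voltammogram_csv <- function(path, grid, currents) {
  currents <- as.matrix(currents)
  stopifnot(nrow(currents) == grid$n_points)
  if (is.null(colnames(currents)))
    colnames(currents) <- sprintf("s%03d", seq_len(ncol(currents)))
  df <- data.frame(potential_V = grid$potentials, currents,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltammogram_csv
#' @export
read_voltammogram_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "potential_V")
    stop("not a voltammogram CSV: first column must be 'potential_V'")
  list(potentials = df[[1]],
       currents = as.matrix(df[, -1, drop = FALSE]))
}

#' Read and write concentration tables as CSV
#'
#' One row per sample, with the seven standard columns `paracetamol_uM`,
#' `diclofenac_uM`, `naproxen_uM`, `aspirin_uM`, `ascorbic_uM`,
#' `glucose_uM`, `sds_uM`.
#'
#' @param path file path.
#' @param conc 7 x n (or 4 x n analyte-only) concentration matrix with
#'   species as rows, as produced by the generators.
#' @return `read_concentration_csv()`: species x samples matrix.
#' @export
write_concentration_csv <- function(path, conc) {
  conc <- as.matrix(conc)
  species <- rownames(conc)
  if (is.null(species))
    species <- c(.analytes, .interferents)[seq_len(nrow(conc))]
  df <- as.data.frame(t(conc))
  names(df) <- paste0(species, "_uM")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentration_csv
#' @export
read_concentration_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  conc <- t(as.matrix(df))
  rownames(conc) <- sub("_uM$", "", rownames(conc))
  colnames(conc) <- sprintf("s%03d", seq_len(ncol(conc)))
  conc
}

#' Write a compressed coefficient set as CSV plus JSON sidecar
#'
#' The CSV holds the coefficient matrix (coefficients as rows, samples as
#' columns); the sidecar `<path>.json` records the wavelet, level and
#' original signal length needed to reconstruct.
#'
#' @param path CSV file path.
#' @param cs a [compress_set()] result.
#' @return `read_compressed_csv()`: a `compressed_set`-like list (without
#'   comparison factors, which require the original signals).
#' @export
write_compressed_csv <- function(path, cs) {
  stopifnot(inherits(cs, "compressed_set"))
  df <- as.data.frame(cs$coefficients)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(wavelet = cs$wavelet, level = cs$level,
         original_length = cs$original_length,
         mean_comparison_factor = cs$mean_comparison_factor),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_compressed_csv
#' @export
read_compressed_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  coeffs <- as.matrix(read.csv(path, check.names = FALSE))
  list(coefficients = coeffs, wavelet = meta$wavelet,
       level = meta$level, original_length = meta$original_length)
}

#' Write a design table as CSV
#'
#' Columns: `run`, one `<factor>_coded` column per factor and, when physical
#' levels are attached, one `<factor>_actual` column per factor.
#'
#' @param path file path.
#' @param design a `design_table`.
#' @export
write_design_csv <- function(path, design) {
  stopifnot(inherits(design, "design_table"))
  df <- data.frame(run = seq_len(nrow(design$coded)))
  coded <- design$coded
  colnames(coded) <- paste0(design$factor_names, "_coded")
  df <- cbind(df, coded)
  if (!is.null(design$actual)) {
    actual <- design$actual
    colnames(actual) <- paste0(design$factor_names, "_actual")
    df <- cbind(df, actual)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize calibration models as JSON
#'
#' Round-trip storage of fitted PLS and MLP calibrations: predictions from
#' a reloaded model match the original.
#'
#' @param model a `pls_cal` or `mlp_cal` fit.
#' @param path file path.
#' @return `read_calibration_json()`: the restored model object.
#' @export
write_calibration_json <- function(model, path) {
  if (inherits(model, "pls_cal")) {
    payload <- list(
      type = "pls", n_components = model$n_components,
      x_mean = model$x_mean, y_mean = model$y_mean,
      weights = model$weights, x_loadings = model$x_loadings,
      y_loadings = model$y_loadings,
      regression_coefficients = model$regression_coefficients,
      n = model$n, y_names = model$y_names)
  } else if (inherits(model, "mlp_cal")) {
    w <- model$weights
    payload <- list(
      type = "mlp", layer_sizes = model$layer_sizes,
      W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2, W3 = w$W3, b3 = w$b3,
      input_scaling = model$input_scaling,
      output_scaling = model$output_scaling,
      config = unclass(model$config), epochs = model$epochs,
      training_mse = model$training_mse, y_names = model$y_names)
  } else stop("unsupported model class")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(x) if (is.matrix(x)) x else as.matrix(x)
  if (identical(p$type, "pls")) {
    fit <- structure(
      list(n_components = p$n_components, x_mean = p$x_mean,
           y_mean = p$y_mean, weights = mat(p$weights),
           x_loadings = mat(p$x_loadings), y_loadings = mat(p$y_loadings),
           rotation = NULL,
           regression_coefficients = mat(p$regression_coefficients),
           zero_variance_columns = integer(0), n = p$n,
           y_names = p$y_names),
      class = "pls_cal")
    return(fit)
  }
  if (identical(p$type, "mlp")) {
    cfg <- do.call(mlp_config, p$config[intersect(
      c("target_error", "learning_rate", "momentum", "max_epochs", "seed",
        "algorithm", "br_burn_in"), names(p$config))])
    fit <- structure(
      list(layer_sizes = p$layer_sizes,
           weights = list(W1 = mat(p$W1), b1 = p$b1, W2 = mat(p$W2),
                          b2 = p$b2, W3 = mat(p$W3), b3 = p$b3),
           input_scaling = p$input_scaling,
           output_scaling = p$output_scaling, config = cfg,
           epochs = p$epochs, training_mse = p$training_mse,
           y_names = p$y_names),
      class = "mlp_cal")
    return(fit)
  }
  stop("unknown calibration model type in ", path)
}
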