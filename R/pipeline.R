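#' Derive a per-stage seed from the global pipeline seed
#'
#' Deterministic polynomial hash of the stage name folded into the global
#' seed, reduced modulo 2^31 - 1 so every derived seed is a valid R
#' integer.  Distinct stage names give distinct, uncorrelated streams.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

#' Pipeline configuration
#'
#' One plain, JSON-serializable list holding every stage's settings.  Each
#' stage of [run_full_pipeline()] reads only its own section.
#'
#' @param seed global seed; per-stage seeds are derived via [stage_seed()].
#' @param output_dir where artifacts are written.
#' @param simulator list: `grid` (start, step, n_points), `noise`
#'   (baseline_intercept, baseline_slope, noise_sd or NULL), `n_test`,
#'   `saturation`.
#' @param design list: `levels`, `factors`, `conc_levels` (umol/L for coded
#'   -1/0/+1).
#' @param compression list: `wavelet`, `level`.
#' @param calibration list: `pls_ncomp`, `mlp_hidden`, `mlp_target_error`,
#'   `mlp_max_epochs`, `mlp_algorithm`.
#' @param metrics list: `confidence`, `intercept_units`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            output_dir = "voltacal_output",
                            simulator = list(),
                            design = list(),
                            compression = list(),
                            calibration = list(),
                            metrics = list()) {
  merge <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = seed,
    output_dir = output_dir,
    simulator = merge(list(grid = list(start = 0, step = 0.00585,
                                       n_points = 177),
                           noise = list(baseline_intercept = 0.5,
                                        baseline_slope = 2,
                                        noise_sd = NULL),
                           n_test = 10, saturation = NULL), simulator),
    design = merge(list(levels = 3, factors = 4,
                        conc_levels = c(0.5, 40.25, 80)), design),
    compression = merge(list(wavelet = "db4", level = 3), compression),
    calibration = merge(list(pls_ncomp = 12, mlp_hidden = c(16, 8),
                             mlp_target_error = 0.015,
                             mlp_max_epochs = 2000,
                             mlp_algorithm = "br"), calibration),
    metrics = merge(list(confidence = 0.95, intercept_units = "mol"),
                    metrics))
  structure(cfg, class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#'
#' `load_config(save_config(cfg, path))` restores an equivalent
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `load_config()`: the restored `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(seed = raw$seed, output_dir = raw$output_dir,
                  simulator = raw$simulator, design = raw$design,
                  compression = raw$compression,
                  calibration = raw$calibration, metrics = raw$metrics)
}

.write_artifact <- function(path, manifest, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  new_hash <- unname(tools::md5sum(tmp))
  rel <- basename(path)
  if (file.exists(path) && identical(manifest$artifacts[[rel]], new_hash)) {
    file.remove(tmp)  # up to date; keep existing artifact
  } else {
    file.rename(tmp, path)
  }
  manifest$artifacts[[rel]] <- new_hash
  manifest
}

.stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the complete calibration workflow
#'
#' Executes, in order: design generation, voltammogram simulation (designed
#' training set plus random external test set), wavelet compression, PLS and
#' MLP calibration, and per-analyte evaluation.  All artifacts are written
#' to `output_dir` together with a manifest listing each file's MD5 hash;
#' re-running with the same configuration reproduces the PLS artifacts
#' bit-identically and the MLP artifacts identically under the same seed,
#' and files that are already up to date are not rewritten.
#'
#' @param config a [pipeline_config()].
#' @param output_dir overrides `config$output_dir`.
#' @return (invisibly) list with the design, datasets, compressed sets,
#'   fitted models, evaluation reports and artifact paths.
#' @export
run_full_pipeline <- function(config = pipeline_config(),
                              output_dir = config$output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, artifacts = list())
  pth <- function(f) file.path(output_dir, f)

  design <- .stage("design", {
    d <- full_factorial(config$design$levels, config$design$factors)
    manifest <- .write_artifact(pth("design.csv"), manifest,
                                 function(p) write_design_csv(p, d))
    d
  })

  grid <- do.call(potential_grid, config$simulator$grid)
  sat <- config$simulator$saturation
  if (is.null(sat)) sat <- Inf
  train <- .stage("simulate-train", {
    noise <- noise_model(config$simulator$noise$baseline_intercept,
                         config$simulator$noise$baseline_slope,
                         config$simulator$noise$noise_sd,
                         seed = stage_seed(config$seed, "simulate-train"))
    ts <- generate_training_set(design, grid = grid, noise = noise,
                                levels = config$design$conc_levels,
                                saturation = sat)
    manifest <- .write_artifact(
      pth("train_voltammograms.csv"), manifest,
      function(p) write_voltammogram_csv(p, grid, ts$voltammograms))
    manifest <- .write_artifact(
      pth("train_concentrations.csv"), manifest,
      function(p) write_concentration_csv(p, ts$all_concentrations))
    ts
  })

  test <- .stage("simulate-test", {
    noise <- noise_model(config$simulator$noise$baseline_intercept,
                         config$simulator$noise$baseline_slope,
                         train$noise_sd)  # reuse the resolved training noise
    es <- generate_random_test_set(config$simulator$n_test,
                                   seed = stage_seed(config$seed,
                                                     "simulate-test"),
                                   grid = grid, noise = noise,
                                   saturation = sat)
    manifest <- .write_artifact(
      pth("test_voltammograms.csv"), manifest,
      function(p) write_voltammogram_csv(p, grid, es$voltammograms))
    manifest <- .write_artifact(
      pth("test_concentrations.csv"), manifest,
      function(p) write_concentration_csv(p, es$all_concentrations))
    es
  })

  comp <- .stage("compress", {
    ctr <- compress_set(train$voltammograms, config$compression$wavelet,
                        config$compression$level)
    cte <- compress_set(test$voltammograms, config$compression$wavelet,
                        config$compression$level)
    manifest <- .write_artifact(pth("train_compressed.csv"), manifest,
                                 function(p) write_compressed_csv(p, ctr))
    manifest <- .write_artifact(pth("test_compressed.csv"), manifest,
                                 function(p) write_compressed_csv(p, cte))
    list(train = ctr, test = cte)
  })

  train_ds <- calibration_dataset(comp$train$coefficients,
                                  train$concentrations, "training")
  test_ds <- calibration_dataset(comp$test$coefficients,
                                 test$concentrations, "testing")

  pls <- .stage("train-pls", {
    fit <- pls_calibration(train_ds, ncomp = config$calibration$pls_ncomp)
    manifest <- .write_artifact(pth("pls_model.json"), manifest,
                                 function(p) write_calibration_json(fit, p))
    fit
  })

  mlp <- .stage("train-mlp", {
    cfg <- mlp_config(target_error = config$calibration$mlp_target_error,
                      max_epochs = config$calibration$mlp_max_epochs,
                      seed = stage_seed(config$seed, "train-mlp"),
                      algorithm = config$calibration$mlp_algorithm)
    fit <- mlp_calibration(train_ds, hidden = config$calibration$mlp_hidden,
                           config = cfg)
    manifest <- .write_artifact(pth("mlp_model.json"), manifest,
                                 function(p) write_calibration_json(fit, p))
    fit
  })

  reports <- .stage("evaluate", {
    rep_pls <- evaluate_calibration(
      pls, train_ds, test_ds, confidence = config$metrics$confidence,
      intercept_units = config$metrics$intercept_units)
    rep_mlp <- evaluate_calibration(
      mlp, train_ds, test_ds, confidence = config$metrics$confidence,
      intercept_units = config$metrics$intercept_units)
    for (nm in c("pls", "mlp")) {
      rp <- if (nm == "pls") rep_pls else rep_mlp
      manifest <- .write_artifact(
        pth(sprintf("evaluation_%s_regression.csv", nm)), manifest,
        function(p) write.csv(rp$regression, p, row.names = FALSE))
      manifest <- .write_artifact(
        pth(sprintf("evaluation_%s_recovery.csv", nm)), manifest,
        function(p) write.csv(rp$recovery, p, row.names = FALSE))
      manifest <- .write_artifact(
        pth(sprintf("evaluation_%s_sensitivity.csv", nm)), manifest,
        function(p) write.csv(rp$sensitivity, p, row.names = FALSE))
    }
    list(pls = rep_pls, mlp = rep_mlp)
  })

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = config, design = design, train = train,
                 test = test, compressed = comp, train_dataset = train_ds,
                 test_dataset = test_ds, pls = pls, mlp = mlp,
                 reports = reports, output_dir = output_dir,
                 manifest = manifest))
}
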