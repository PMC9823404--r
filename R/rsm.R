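# Second-order polynomial term expansion in coded factors.
# Column order: intercept, x1..xk, x1^2..xk^2, then pairwise products in
# lexicographic pair order (x1x2, x1x3, ..., x(k-1)xk).
.quad_expand <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  pairs <- if (k >= 2L) utils::combn(k, 2L) else matrix(numeric(0), 2, 0)
  inter <- if (ncol(pairs))
    sapply(seq_len(ncol(pairs)),
           function(j) X[, pairs[1, j]] * X[, pairs[2, j]])
  else NULL
  if (!is.null(inter) && !is.matrix(inter)) inter <- matrix(inter, nrow = 1)
  cbind(intercept = 1, X, X^2, inter)
}

.pair_labels <- function(k) {
  if (k < 2L) return(character(0))
  pairs <- utils::combn(k, 2L)
  sprintf("X%dX%d", pairs[1, ], pairs[2, ])
}

#' Second-order response-surface model in coded factors
#'
#' A full quadratic polynomial (intercept, linear, pure quadratic, two-way
#' interactions) mapping coded settings on `[-1, 1]^k` to a predicted
#' response, here the anodic peak current in uA.
#'
#' @param intercept scalar intercept (response units).
#' @param linear length-`k` vector of linear coefficients.
#' @param quadratic length-`k` vector of pure quadratic coefficients.
#' @param interaction length-`choose(k, 2)` vector of pairwise interaction
#'   coefficients in lexicographic pair order (X1X2, X1X3, ..., X3X4 for
#'   k = 4).
#' @param response_name label of the modeled response.
#' @return An object of class `rsm`.
#' @examples
#' m <- nsaid_rsm_models()$Y1
#' predict(m, c(0, 0, 0, 0))  # peak current at the design center
#' @export
rsm_model <- function(intercept, linear, quadratic, interaction,
                      response_name = "") {
  k <- length(linear)
  if (length(quadratic) != k || length(interaction) != choose(k, 2))
    stop("coefficient blocks are inconsistent: need k linear, k quadratic ",
         "and choose(k, 2) interaction terms")
  cf <- c(intercept, linear, quadratic, interaction)
  if (!all(is.finite(cf))) stop("all coefficients must be finite")
  structure(list(intercept = intercept, linear = linear,
                 quadratic = quadratic, interaction = interaction,
                 k = k, response_name = response_name),
            class = "rsm")
}

#' @export
coef.rsm <- function(object, ...) {
  k <- object$k
  stats::setNames(
    c(object$intercept, object$linear, object$quadratic, object$interaction),
    c("intercept", paste0("X", seq_len(k)), paste0("X", seq_len(k), "^2"),
      .pair_labels(k)))
}

#' @export
print.rsm <- function(x, digits = 4, ...) {
  cat(sprintf("Second-order response surface%s (%d coded factors)\n",
              if (nzchar(x$response_name))
                paste0(" for ", x$response_name) else "", x$k))
  print(round(coef(x), digits))
  invisible(x)
}

#' Evaluate a response-surface model
#'
#' @param object an [rsm_model()] or [fit_quadratic()] result.
#' @param newdata coded settings: length-`k` vector or runs x `k` matrix.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$k)
    stop(sprintf("'newdata' must have %d columns of coded factors", object$k))
  if (!all(is.finite(newdata))) stop("coded settings must be finite")
  drop(.quad_expand(newdata) %*% coef(object))
}

#' Fit a second-order response surface by least squares
#'
#' Ordinary least squares on the full 14-term quadratic expansion (for four
#' factors).  On noiseless polynomial responses the fit recovers the
#' generating coefficients exactly (up to numerical tolerance) whenever the
#' expanded design has full rank, which the 27-run Box-Behnken plan does.
#'
#' @param design a `design_table` (its coded matrix is used) or a coded
#'   matrix of runs x factors.
#' @param response numeric response vector, one value per run (uA).
#' @param response_name label for the fitted response.
#' @return An `rsm` model with `fitted`, `residuals` and `design` attached.
#' @export
fit_quadratic <- function(design, response, response_name = "") {
  coded <- if (inherits(design, "design_table")) design$coded else
    as.matrix(design)
  k <- ncol(coded)
  n_par <- 1 + 2 * k + choose(k, 2)
  if (nrow(coded) < n_par + 1)
    stop(sprintf("need at least %d runs to fit %d coefficients", n_par + 1,
                 n_par))
  if (length(response) != nrow(coded))
    stop("'response' length must equal the number of design runs")
  M <- .quad_expand(coded)
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop("rank-deficient expanded design: the quadratic model is not ",
         "estimable on this plan")
  cf <- qr.coef(qrM, response)
  model <- rsm_model(cf[1], cf[2:(k + 1)], cf[(k + 2):(2 * k + 1)],
                     cf[(2 * k + 2):n_par], response_name = response_name)
  model$fitted <- drop(M %*% cf)
  model$residuals <- response - model$fitted
  model
}

#' The three printed NSAID response-surface models
#'
#' Loads the packaged coefficient sets of the three second-order models that
#' relate the coded DPV parameters (X1 step potential, X2 interval time,
#' X3 modulation time, X4 modulation amplitude) to the anodic peak currents:
#' Y1 paracetamol, Y2 diclofenac, Y3 the merged naproxen/aspirin peak.
#'
#' @return Named list of three `rsm` models (`Y1`, `Y2`, `Y3`).
#' @export
nsaid_rsm_models <- function() {
  path <- system.file("extdata", "rsm_nsaid_models.json",
                      package = "voltacal", mustWork = TRUE)
  read_rsm_json(path)
}

#' Read / write response-surface models as JSON
#'
#' The file holds one object per model: `{response, intercept, linear[k],
#' quadratic[k], interaction[choose(k,2)]}`.
#'
#' @param path file path.
#' @return `read_rsm_json()`: named list of `rsm` models.
#' @export
read_rsm_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  models <- lapply(raw, function(m)
    rsm_model(m$intercept, m$linear, m$quadratic, m$interaction,
              response_name = m$response))
  names(models) <- vapply(raw, `[[`, character(1), "response")
  models
}

#' @rdname read_rsm_json
#' @param models named list of `rsm` models.
#' @export
write_rsm_json <- function(models, path) {
  out <- lapply(models, function(m)
    list(response = m$response_name, intercept = m$intercept,
         linear = m$linear, quadratic = m$quadratic,
         interaction = m$interaction))
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Multi-response optimization over the coded cube
#'
#' Maximizes a weighted sum of min-max normalized model responses over
#' `[-1, 1]^k` by dense grid search followed by local polish
#' (box-constrained quasi-Newton from the best grid point).  Normalization
#' bounds are frozen from the grid sweep so the polished score is comparable
#' to every evaluated grid point; the polished point is only kept if it does
#' not score below the best grid point.  Grid ties are broken in favor of
#' the lexicographically lowest coded coordinates.
#'
#' @param models list of `rsm` models sharing one factor space.
#' @param weights non-negative weight per model (default equal).
#' @param n_grid grid points per axis for the dense sweep.
#' @param ranges optional list of [factor_range()] to report the optimum in
#'   physical units.
#' @return An object of class `rsm_optimum`: `coded_optimum`,
#'   `actual_optimum` (or `NULL`), `predicted_responses`, `composite_score`,
#'   and the normalization bounds used.
#' @export
optimize_rsm <- function(models, weights = NULL, n_grid = 41L,
                         ranges = NULL) {
  if (!length(models)) stop("'models' must contain at least one rsm model")
  stopifnot(all(vapply(models, inherits, logical(1), "rsm")))
  k <- models[[1]]$k
  if (!all(vapply(models, `[[`, numeric(1), "k") == k))
    stop("all models must share the same factor space")
  if (is.null(weights)) weights <- rep(1, length(models))
  if (length(weights) != length(models) || any(weights < 0))
    stop("'weights' must be non-negative, one per model")
  axis <- seq(-1, 1, length.out = n_grid)
  grid <- as.matrix(rev(expand.grid(rep(list(axis), k))))  # lexicographic
  dimnames(grid) <- NULL

  n <- nrow(grid)
  chunk <- 200000L
  y <- matrix(NA_real_, n, length(models))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    M <- .quad_expand(grid[idx, , drop = FALSE])
    for (j in seq_along(models)) y[idx, j] <- M %*% coef(models[[j]])
  }
  lo <- apply(y, 2, min); hi <- apply(y, 2, max)
  scale <- ifelse(hi > lo, hi - lo, 1)
  composite_at <- function(X) {
    v <- vapply(seq_along(models),
                function(j) (predict(models[[j]], X) - lo[j]) / scale[j],
                numeric(if (is.null(dim(X))) 1L else nrow(X)))
    if (is.null(dim(v))) sum(weights * v) else drop(v %*% weights)
  }
  score <- drop(sweep(y, 2, lo) %*% (weights / scale))
  best <- which.max(score)  # first max = lexicographically lowest tie
  x_best <- grid[best, ]
  s_best <- score[best]

  pol <- optim(x_best, fn = function(x) composite_at(matrix(x, 1)),
               method = "L-BFGS-B", lower = rep(-1, k), upper = rep(1, k),
               control = list(fnscale = -1))
  if (pol$value >= s_best) {
    x_best <- pol$par
    s_best <- pol$value
  }
  preds <- vapply(models, function(m) predict(m, matrix(x_best, 1)),
                  numeric(1))
  names(preds) <- vapply(seq_along(models), function(j) {
    nm <- models[[j]]$response_name
    if (nzchar(nm)) nm else paste0("model", j)
  }, character(1))
  actual <- if (!is.null(ranges)) {
    b <- .range_bounds(ranges, k)
    stats::setNames(b$low + (x_best + 1) / 2 * (b$high - b$low),
                    vapply(ranges, `[[`, character(1), "name"))
  } else NULL
  structure(list(coded_optimum = x_best, actual_optimum = actual,
                 predicted_responses = preds, composite_score = s_best,
                 normalization = list(lo = lo, hi = hi),
                 weights = weights, n_grid = n_grid),
            class = "rsm_optimum")
}

#' @export
print.rsm_optimum <- function(x, digits = 4, ...) {
  cat("Multi-response optimum on the coded cube\n")
  cat("  coded: ", paste(round(x$coded_optimum, digits), collapse = ", "),
      "\n")
  if (!is.null(x$actual_optimum)) {
    cat("  physical:\n")
    print(round(x$actual_optimum, 6))
  }
  cat("  predicted responses (uA):\n")
  print(round(x$predicted_responses, digits))
  cat(sprintf("  composite score: %.4f\n", x$composite_score))
  invisible(x)
}
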