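.as_xy <- function(x, y) {
  # Accept a calibration_dataset (features x samples) or plain matrices
  # with samples as rows.
  if (inherits(x, "calibration_dataset")) {
    list(X = t(x$X), Y = t(x$Y))
  } else {
    X <- as.matrix(x)
    Y <- as.matrix(y)
    if (nrow(X) != nrow(Y))
      stop("'x' and 'y' must have the same number of samples (rows)")
    list(X = X, Y = Y)
  }
}

#' Calibration dataset container
#'
#' Stores predictors and responses in the conventional chemometric
#' orientation: features as rows, samples as columns (e.g. the 28 x 81
#' training block of approximation coefficients and its 4 x 81 concentration
#' block).
#'
#' @param X numeric matrix, features x samples.
#' @param Y numeric matrix, responses x samples (umol/L).
#' @param role `"training"` or `"testing"` (informational).
#' @return Object of class `calibration_dataset`.
#' @export
calibration_dataset <- function(X, Y, role = c("training", "testing")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("'X' and 'Y' must have the same number of samples (columns)")
  structure(list(X = X, Y = Y, role = match.arg(role)),
            class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf("Calibration dataset (%s): X %d x %d, Y %d x %d\n", x$role,
              nrow(x$X), ncol(x$X), nrow(x$Y), ncol(x$Y)))
  invisible(x)
}

#' Partial least squares calibration (PLS2, NIPALS)
#'
#' Sequentially extracts latent variables maximizing the covariance between
#' the centered predictor and response blocks, deflating X after each
#' component (regression mode).  The inner iteration is initialized from the
#' response column with the largest variance, making the fit fully
#' deterministic.  At `ncomp = rank(X)` on noiseless linear data the model
#' reproduces the multivariate least-squares solution.
#'
#' @param x predictors: samples x features matrix, or a
#'   [calibration_dataset()] (then `y` is ignored).
#' @param y responses: samples x outputs matrix (umol/L).
#' @param ncomp number of latent components; at most
#'   `min(n_features, n_samples - 1)`.
#' @param tol convergence tolerance of the NIPALS inner loop.
#' @return Object of class `pls_cal` with centering vectors, per-component
#'   `weights`, `x_loadings`, `y_loadings`, scores and the
#'   `regression_coefficients` matrix (features x outputs).
#' @examples
#' ts <- generate_training_set()
#' cs <- compress_set(ts$voltammograms)
#' fit <- pls_calibration(t(cs$coefficients), t(ts$concentrations), ncomp = 12)
#' fit
#' @export
pls_calibration <- function(x, y = NULL, ncomp = 12L, tol = 1e-12) {
  d <- .as_xy(x, y)
  X <- d$X; Y <- d$Y
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  ncomp <- as.integer(ncomp)
  if (is.na(ncomp) || ncomp < 1L || ncomp > min(p, n - 1L))
    stop(sprintf("'ncomp' must be in 1..min(%d, %d)", p, n - 1L))
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  const_cols <- which(apply(Xc, 2, function(v) all(abs(v) < 1e-12)))
  if (length(const_cols))
    message(length(const_cols),
            " zero-variance predictor column(s); they carry no information")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); Tm <- matrix(0, n, ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2, var))]
    if (all(abs(u) < 1e-14)) u <- Yd[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(500L)) {
      w <- drop(crossprod(Xd, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) stop("X block exhausted before component ", a,
                           "; reduce 'ncomp'")
      w <- w / nw
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      u <- drop(Yd %*% q) / sum(q^2)
      if (sum((tt - t_old)^2) < tol^2 * sum(tt^2)) break
      t_old <- tt
    }
    pv <- drop(crossprod(Xd, tt)) / sum(tt^2)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- q; Tm[, a] <- tt
    Xd <- Xd - tcrossprod(tt, pv)
    Yd <- Yd - tcrossprod(tt, q)
  }
  R <- W %*% solve(crossprod(P, W))  # weights in original X space
  B <- R %*% t(Q)
  fit <- structure(
    list(n_components = ncomp, x_mean = x_mean, y_mean = y_mean,
         weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
         rotation = R, regression_coefficients = B,
         zero_variance_columns = const_cols, n = n,
         y_names = colnames(Y)),
    class = "pls_cal")
  fit$fitted <- predict(fit, X)
  fit$residuals <- Y - fit$fitted
  fit
}

#' Regression coefficients of a PLS calibration
#'
#' @param object a `pls_cal` fit.
#' @param ncomp report the coefficients of a model truncated to the first
#'   `ncomp` components (default: all fitted components).
#' @param ... unused.
#' @return features x outputs coefficient matrix (for centered X).
#' @export
coef.pls_cal <- function(object, ncomp = object$n_components, ...) {
  ncomp <- as.integer(ncomp)
  if (ncomp == object$n_components) return(object$regression_coefficients)
  if (ncomp < 1L || ncomp > object$n_components)
    stop("'ncomp' out of the fitted range")
  W <- object$weights[, seq_len(ncomp), drop = FALSE]
  P <- object$x_loadings[, seq_len(ncomp), drop = FALSE]
  Q <- object$y_loadings[, seq_len(ncomp), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

#' Predict concentrations from a PLS calibration
#'
#' @param object a `pls_cal` fit.
#' @param newdata samples x features matrix, a features x samples matrix with
#'   `features_as_rows = TRUE`, or a [calibration_dataset()].
#' @param ncomp number of components to use (default: all fitted).
#' @param features_as_rows set `TRUE` when `newdata` is features x samples.
#' @param ... unused.
#' @return samples x outputs matrix of predicted concentrations (umol/L).
#' @export
predict.pls_cal <- function(object, newdata, ncomp = object$n_components,
                            features_as_rows = FALSE, ...) {
  if (inherits(newdata, "calibration_dataset")) newdata <- t(newdata$X)
  else if (features_as_rows) newdata <- t(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop(sprintf("'newdata' must have %d feature columns",
                 length(object$x_mean)))
  B <- coef(object, ncomp)
  pred <- sweep(newdata, 2, object$x_mean) %*% B
  pred <- sweep(pred, 2, object$y_mean, "+")
  colnames(pred) <- object$y_names
  pred
}

#' @export
print.pls_cal <- function(x, ...) {
  cat(sprintf("PLS calibration: %d predictors -> %d responses, %d components (n = %d)\n",
              nrow(x$regression_coefficients),
              ncol(x$regression_coefficients), x$n_components, x$n))
  invisible(x)
}

#' @export
residuals.pls_cal <- function(object, ...) object$residuals

#' @export
summary.pls_cal <- function(object, ...) {
  rmse <- sqrt(colMeans(object$residuals^2))
  cat(sprintf("PLS calibration with %d components\n", object$n_components))
  cat("training RMSE per response (umol/L):\n")
  print(round(rmse, 4))
  invisible(rmse)
}

#' Cross-validated selection of the number of PLS components
#'
#' k-fold cross-validation over the training set; for each candidate
#' component count the mean root-mean-square prediction error across folds
#' and responses is computed, and the count with the smallest error wins
#' (ties go to the smaller model).
#'
#' @inheritParams pls_calibration
#' @param k_folds number of folds (>= 2).
#' @param max_ncomp largest candidate component count.
#' @param seed integer seed for the fold assignment.
#' @return Integer: selected number of components, with the per-candidate
#'   CV RMSE attached as attribute `"cv_rmse"`.
#' @export
select_ncomp <- function(x, y = NULL, k_folds = 10L, max_ncomp = NULL,
                         seed = 1L) {
  d <- .as_xy(x, y)
  X <- d$X; Y <- d$Y
  n <- nrow(X)
  k_folds <- as.integer(k_folds)
  if (is.na(k_folds) || k_folds < 2L) stop("'k_folds' must be >= 2")
  if (is.null(max_ncomp))
    max_ncomp <- min(ncol(X), n - ceiling(n / k_folds) - 1L)
  max_ncomp <- as.integer(max_ncomp)
  if (max_ncomp < 1L || max_ncomp > min(ncol(X), n - 2L))
    stop("'max_ncomp' out of bounds for this dataset")
  folds <- .with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  sse <- matrix(0, k_folds, max_ncomp)
  cnt <- integer(k_folds)
  for (f in seq_len(k_folds)) {
    hold <- folds == f
    fit <- pls_calibration(X[!hold, , drop = FALSE],
                           Y[!hold, , drop = FALSE], ncomp = max_ncomp)
    for (a in seq_len(max_ncomp)) {
      pred <- predict(fit, X[hold, , drop = FALSE], ncomp = a)
      sse[f, a] <- sum((pred - Y[hold, , drop = FALSE])^2)
    }
    cnt[f] <- sum(hold) * ncol(Y)
  }
  rmse <- sqrt(colSums(sse) / sum(cnt))
  # near-ties (within relative tolerance of the minimum) go to the
  # smallest model, so numerically flat error curves do not inflate ncomp
  best <- which(rmse <= min(rmse) * (1 + 1e-8))[1]
  structure(as.integer(best), cv_rmse = rmse)
}
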