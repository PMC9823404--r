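# Min-max scaling of each variable onto [-1, 1]; constant variables map to 0.
.fit_scaling <- function(M) {
  lo <- apply(M, 2, min)
  hi <- apply(M, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, hi = hi, span = span)
}
.apply_scaling <- function(M, s) {
  sweep(sweep(M, 2, s$lo), 2, s$span / 2, "/") - 1
}
.invert_scaling <- function(M, s) {
  sweep(sweep(M + 1, 2, s$span / 2, "*"), 2, s$lo, "+")
}

#' Training configuration for the neural-network calibration
#'
#' @param target_error stop once the mean squared error on the `[-1, 1]`
#'   scaled targets falls to this value or below.
#' @param learning_rate,momentum gradient-descent hyperparameters; used only
#'   when `algorithm = "gd"`.
#' @param max_epochs iteration cap.
#' @param seed integer seed for the weight initialization.
#' @param algorithm `"br"` for Bayesian-regularized Levenberg-Marquardt
#'   (default) or `"gd"` for plain full-batch gradient descent with momentum.
#' @param br_burn_in number of initial Levenberg-Marquardt epochs run with
#'   the regularization switched off (`alpha = 0`) before the evidence
#'   updates engage.  Re-estimating `(alpha, beta)` from a random network,
#'   before any data fit exists, drives the trade-off towards pure weight
#'   decay when the network has more weights than residuals, while engaging
#'   only after the optimizer has converged lets the network interpolate
#'   measurement noise first; a short warm start sits between the two
#'   degenerate regimes.
#' @param restarts maximum number of seeded weight initializations tried;
#'   the first run reaching `target_error` is kept (otherwise the run with
#'   the lowest final training error).  Restart seeds are derived
#'   deterministically from `seed`.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(target_error = 0.015, learning_rate = 0.05,
                       momentum = 0.5, max_epochs = 2000L, seed = 1L,
                       algorithm = c("br", "gd"), br_burn_in = 3L,
                       restarts = 3L) {
  structure(list(target_error = target_error, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), algorithm = match.arg(algorithm),
                 br_burn_in = as.integer(br_burn_in),
                 restarts = as.integer(restarts)),
            class = "mlp_config")
}

# Forward pass.  X: inputs x samples (already scaled).  Returns activations.
.mlp_forward <- function(wts, X) {
  A1 <- tanh(wts$W1 %*% X + wts$b1)
  A2 <- tanh(wts$W2 %*% A1 + wts$b2)
  Yh <- wts$W3 %*% A2 + wts$b3
  list(A1 = A1, A2 = A2, Yh = Yh)
}

.mlp_unpack <- function(theta, sizes) {
  p <- sizes[1]; h1 <- sizes[2]; h2 <- sizes[3]; m <- sizes[4]
  i <- 0L
  take <- function(k) {
    v <- theta[(i + 1L):(i + k)]
    i <<- i + k
    v
  }
  list(W1 = matrix(take(h1 * p), h1, p), b1 = take(h1),
       W2 = matrix(take(h2 * h1), h2, h1), b2 = take(h2),
       W3 = matrix(take(m * h2), m, h2), b3 = take(m))
}

.mlp_pack <- function(wts) {
  c(wts$W1, wts$b1, wts$W2, wts$b2, wts$W3, wts$b3)
}

# Jacobian of the stacked residual vector e = vec_k(T - Yh) with respect to
# the packed parameter vector.  Rows are ordered output-major: for each
# output unit k, all samples.  J = d e / d theta = -d Yh / d theta.
.mlp_jacobian <- function(wts, X, fwd) {
  p <- nrow(X); n <- ncol(X)
  h1 <- nrow(wts$W1); h2 <- nrow(wts$W2); m <- nrow(wts$W3)
  d1 <- 1 - fwd$A1^2
  d2 <- 1 - fwd$A2^2
  n_par <- length(.mlp_pack(wts))
  J <- matrix(0, m * n, n_par)
  off_W1 <- 0L
  off_b1 <- off_W1 + h1 * p
  off_W2 <- off_b1 + h1
  off_b2 <- off_W2 + h2 * h1
  off_W3 <- off_b2 + h2
  off_b3 <- off_W3 + m * h2
  for (k in seq_len(m)) {
    rows <- (k - 1L) * n + seq_len(n)
    R2 <- wts$W3[k, ] * d2                      # h2 x n
    R1 <- crossprod(wts$W2, R2) * d1            # h1 x n
    # W1 block: column-major vec of R1 x^T -> kron(x, R1) per sample
    J[rows, off_W1 + seq_len(h1 * p)] <-
      -t(X[rep(seq_len(p), each = h1), , drop = FALSE] *
           R1[rep(seq_len(h1), times = p), , drop = FALSE])
    J[rows, off_b1 + seq_len(h1)] <- -t(R1)
    J[rows, off_W2 + seq_len(h2 * h1)] <-
      -t(fwd$A1[rep(seq_len(h1), each = h2), , drop = FALSE] *
           R2[rep(seq_len(h2), times = h1), , drop = FALSE])
    J[rows, off_b2 + seq_len(h2)] <- -t(R2)
    J[rows, off_W3 + k + m * (seq_len(h2) - 1L)] <- -t(fwd$A2)
    J[rows, off_b3 + k] <- -1
  }
  J
}

.mlp_train_br <- function(theta, sizes, X, Tm, config) {
  n_par <- length(theta)
  N <- length(Tm)
  alpha <- 0; beta <- 1; gamma <- NA_real_
  mu <- 0.005; mu_inc <- 10; mu_dec <- 0.1; mu_max <- 1e10
  resid_of <- function(th) {
    wts <- .mlp_unpack(th, sizes)
    fwd <- .mlp_forward(wts, X)
    list(wts = wts, fwd = fwd, e = as.numeric(t(Tm - fwd$Yh)))
  }
  st <- resid_of(theta)
  Ed <- 0.5 * sum(st$e^2)
  Ew <- 0.5 * sum(theta^2)
  history <- list(mse = numeric(0), F_before = numeric(0),
                  F_after = numeric(0), accepted = logical(0))
  epoch <- 0L
  best_mse <- Inf
  since_improve <- 0L
  repeat {
    mse <- 2 * Ed / N
    history$mse <- c(history$mse, mse)
    if (mse < best_mse * (1 - 1e-4)) {
      best_mse <- mse
      since_improve <- 0L
    } else since_improve <- since_improve + 1L
    if (mse <= config$target_error || epoch >= config$max_epochs ||
        mu > mu_max || since_improve >= 50L) break
    epoch <- epoch + 1L
    J <- .mlp_jacobian(st$wts, X, st$fwd)
    JtJ <- crossprod(J)
    g <- beta * drop(crossprod(J, st$e)) + alpha * theta
    F_cur <- beta * Ed + alpha * Ew
    accepted <- FALSE
    while (!accepted && mu <= mu_max) {
      H <- beta * JtJ + diag(alpha + mu, n_par)
      step <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(step)) {
        mu <- mu * mu_inc
        next
      }
      theta_new <- theta + step
      st_new <- resid_of(theta_new)
      Ed_new <- 0.5 * sum(st_new$e^2)
      Ew_new <- 0.5 * sum(theta_new^2)
      F_new <- beta * Ed_new + alpha * Ew_new
      if (is.finite(F_new) && F_new < F_cur) {
        accepted <- TRUE
        history$F_before <- c(history$F_before, F_cur)
        history$F_after <- c(history$F_after, F_new)
        history$accepted <- c(history$accepted, TRUE)
        theta <- theta_new; st <- st_new
        Ed <- Ed_new; Ew <- Ew_new
        mu <- max(mu * mu_dec, 1e-20)
      } else {
        mu <- mu * mu_inc
      }
    }
    if (!accepted) break  # mu exhausted: local minimum reached
    if (epoch < config$br_burn_in) next
    # MacKay evidence update of the regularization trade-off; the number of
    # effective parameters is gamma = sum beta*l_i / (beta*l_i + alpha) over
    # the eigenvalues l_i of J'J, which stays defined when J'J is singular.
    ev <- pmax(eigen(JtJ, symmetric = TRUE, only.values = TRUE)$values, 0)
    gamma <- if (alpha == 0) sum(ev > max(ev) * 1e-9) else
      n_par - sum(alpha / (beta * ev + alpha))
    alpha <- gamma / max(2 * Ew, .Machine$double.eps)
    # With more weights than residuals gamma can reach N, which would send
    # the misfit weight to zero and freeze training; keep a floor on it.
    beta <- max(N - gamma, 0.05 * N) / max(2 * Ed, .Machine$double.eps)
  }
  list(theta = theta, epochs = epoch, mse = 2 * Ed / N,
       alpha = alpha, beta = beta, gamma = gamma, history = history)
}

.mlp_train_gd <- function(theta, sizes, X, Tm, config) {
  N <- length(Tm)
  vel <- numeric(length(theta))
  history <- list(mse = numeric(0), F_before = numeric(0),
                  F_after = numeric(0), accepted = logical(0))
  for (epoch in seq_len(config$max_epochs)) {
    wts <- .mlp_unpack(theta, sizes)
    fwd <- .mlp_forward(wts, X)
    E <- fwd$Yh - Tm                       # m x n
    mse <- mean(E^2)
    history$mse <- c(history$mse, mse)
    if (mse <= config$target_error) break
    D3 <- 2 * E / N
    D2 <- crossprod(wts$W3, D3) * (1 - fwd$A2^2)
    D1 <- crossprod(wts$W2, D2) * (1 - fwd$A1^2)
    grad <- c(tcrossprod(D1, X), rowSums(D1),
              tcrossprod(D2, fwd$A1), rowSums(D2),
              tcrossprod(D3, fwd$A2), rowSums(D3))
    vel <- config$momentum * vel - config$learning_rate * grad
    theta <- theta + vel
  }
  list(theta = theta, epochs = epoch, mse = mse, alpha = NA, beta = NA,
       gamma = NA, history = history)
}

#' Multilayer-perceptron calibration (28-16-8-4)
#'
#' Feed-forward network with an identity input stage, two tanh hidden layers
#' and a linear output layer, trained on data min-max scaled to `[-1, 1]`.
#' The default trainer is Bayesian-regularized Levenberg-Marquardt: it
#' minimizes `beta * sum(e^2)/2 + alpha * sum(w^2)/2` and re-estimates the
#' trade-off `(alpha, beta)` after every accepted step by the MacKay
#' evidence approximation, which keeps the heavily parameterized network
#' from overfitting the 81 calibration mixtures.  A plain gradient-descent
#' mode with learning rate and momentum is available via
#' `mlp_config(algorithm = "gd")`.  Training stops when the scaled mean
#' squared error reaches `target_error` (default 0.015) or at `max_epochs`.
#'
#' @param x predictors: samples x features matrix, or a
#'   [calibration_dataset()] (then `y` is ignored).
#' @param y responses: samples x outputs matrix (umol/L).
#' @param hidden sizes of the two hidden layers.
#' @param config an [mlp_config()].
#' @return Object of class `mlp_cal` with layer weights, the input/output
#'   scaling maps, the training history and diagnostics.
#' @examples
#' \donttest{
#' ts <- generate_training_set()
#' cs <- compress_set(ts$voltammograms)
#' fit <- mlp_calibration(t(cs$coefficients), t(ts$concentrations))
#' fit
#' }
#' @export
mlp_calibration <- function(x, y = NULL, hidden = c(16L, 8L),
                            config = mlp_config()) {
  d <- .as_xy(x, y)
  X <- d$X; Y <- d$Y
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("training data must be finite")
  if (nrow(X) < 2L) stop("training set must contain at least two samples")
  if (length(hidden) != 2L) stop("'hidden' must give two hidden-layer sizes")
  sizes <- c(ncol(X), as.integer(hidden), ncol(Y))
  in_scale <- .fit_scaling(X)
  out_scale <- .fit_scaling(Y)
  Xs <- t(.apply_scaling(X, in_scale))    # inputs x samples
  Ts <- t(.apply_scaling(Y, out_scale))   # outputs x samples
  n_par <- sizes[2] * (sizes[1] + 1) + sizes[3] * (sizes[2] + 1) +
    sizes[4] * (sizes[3] + 1)
  trained <- NULL
  for (r in seq_len(max(config$restarts, 1L))) {
    init_seed <- stage_seed(config$seed, sprintf("init-%d", r))
    theta0 <- .with_seed(init_seed, runif(n_par, -0.5, 0.5))
    run <- if (config$algorithm == "br")
      .mlp_train_br(theta0, sizes, Xs, Ts, config)
    else .mlp_train_gd(theta0, sizes, Xs, Ts, config)
    run$restart <- r
    if (is.null(trained) ||
        (all(is.finite(run$theta)) && run$mse < trained$mse))
      trained <- run
    if (all(is.finite(trained$theta)) &&
        trained$mse <= config$target_error) break
  }
  if (!all(is.finite(trained$theta)))
    stop(sprintf("non-finite network weights after %d epochs (mse %.4g)",
                 trained$epochs, trained$mse))
  fit <- structure(
    list(layer_sizes = sizes, weights = .mlp_unpack(trained$theta, sizes),
         input_scaling = in_scale, output_scaling = out_scale,
         config = config, epochs = trained$epochs,
         training_mse = trained$mse, alpha = trained$alpha,
         beta = trained$beta, restart = trained$restart,
         history = trained$history, y_names = colnames(Y)),
    class = "mlp_cal")
  fit$fitted <- predict(fit, X)
  fit$residuals <- Y - fit$fitted
  fit
}

#' Predict concentrations from a neural-network calibration
#'
#' Applies the stored input scaling, runs the forward pass and inverts the
#' output scaling, returning concentrations in the original units.
#'
#' @param object an `mlp_cal` fit.
#' @param newdata samples x features matrix, a features x samples matrix with
#'   `features_as_rows = TRUE`, or a [calibration_dataset()].
#' @param features_as_rows set `TRUE` when `newdata` is features x samples.
#' @param ... unused.
#' @return samples x outputs matrix of predicted concentrations (umol/L).
#' @export
predict.mlp_cal <- function(object, newdata, features_as_rows = FALSE, ...) {
  if (inherits(newdata, "calibration_dataset")) newdata <- t(newdata$X)
  else if (features_as_rows) newdata <- t(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$layer_sizes[1])
    stop(sprintf("'newdata' must have %d feature columns",
                 object$layer_sizes[1]))
  Xs <- t(.apply_scaling(newdata, object$input_scaling))
  Yh <- t(.mlp_forward(object$weights, Xs)$Yh)
  out <- .invert_scaling(Yh, object$output_scaling)
  colnames(out) <- object$y_names
  out
}

#' @export
print.mlp_cal <- function(x, ...) {
  cat(sprintf("MLP calibration %s (%s), %d epochs, scaled training MSE %.4g\n",
              paste(x$layer_sizes, collapse = " x "),
              x$config$algorithm, x$epochs, x$training_mse))
  invisible(x)
}

#' @export
residuals.mlp_cal <- function(object, ...) object$residuals

#' @export
summary.mlp_cal <- function(object, ...) {
  rmse <- sqrt(colMeans(object$residuals^2))
  cat(sprintf("MLP calibration %s, trained %d epochs (%s)\n",
              paste(object$layer_sizes, collapse = " x "), object$epochs,
              object$config$algorithm))
  cat(sprintf("scaled training MSE: %.4g (target %.4g)\n",
              object$training_mse, object$config$target_error))
  cat("training RMSE per response (umol/L):\n")
  print(round(rmse, 4))
  invisible(rmse)
}
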