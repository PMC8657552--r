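#' Radial-basis-function kernel
#'
#' Evaluates the Gaussian (RBF) kernel
#' \eqn{K(x, x') = \exp(-\|x - x'\|^2 / (2\sigma^2))} between two points.
#'
#' @param x,x2 Numeric vectors of equal length.
#' @param sigma Kernel width, a positive scalar on the same scale as the
#'   (normalized) predictors.
#' @return A scalar in `(0, 1]`; exactly 1 when `x == x2`.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)
#' @export
rbf_kernel <- function(x, x2, sigma) {
  stopifnot(is.numeric(x), is.numeric(x2))
  if (length(x) != length(x2)) {
    stop("rbf_kernel: 'x' and 'x2' must have the same dimension (",
         length(x), " vs ", length(x2), ")")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("rbf_kernel: 'sigma' must be a positive scalar")
  }
  d <- x - x2
  exp(-sum(d * d) / (2 * sigma^2))
}

#' RBF Gram matrix over training rows
#'
#' Computes the matrix \eqn{\Omega} with
#' \eqn{\Omega_{ij} = K(x_i, x_j)} for all pairs of rows of `X`.
#' The result is symmetric, has unit diagonal, and is positive
#' semidefinite for every `sigma > 0`.
#'
#' @param X Numeric matrix, one row per observation.
#' @param sigma Kernel width (positive scalar).
#' @return An `m x m` symmetric matrix.
#' @export
rbf_gram <- function(X, sigma) {
  X <- as.matrix(X)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("rbf_gram: 'sigma' must be a positive scalar")
  }
  # squared Euclidean distances via the usual ||a||^2 + ||b||^2 - 2ab' identity
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  K <- exp(-d2 / (2 * sigma^2))
  # enforce exact symmetry and unit diagonal against rounding
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Fit a least-squares support-vector regression
#'
#' Solves the LS-SVR dual problem in closed form. With
#' \eqn{A = \Omega + \gamma^{-1} I} (positive definite for every
#' \eqn{\gamma > 0}), the intercept and dual coefficients are
#' \deqn{b = \frac{1^\top A^{-1} y}{1^\top A^{-1} 1}, \qquad
#'       \alpha = A^{-1}(y - b 1).}
#' There is no iterative training; the model is the solution of one
#' symmetric positive-definite linear system. Larger `gamma` means
#' weaker regularization (the `gamma -> Inf` limit interpolates the
#' training data on distinct points).
#'
#' @param X Numeric predictor matrix (`m x d`), `m >= 2`. Normalization,
#'   if wanted, is the caller's responsibility: the fit uses `X` as given.
#' @param y Numeric response vector of length `m`.
#' @param sigma RBF kernel width (positive).
#' @param gamma Regularization weight (positive).
#' @return An object of class `"lssvr"`: a list with `X_train`, `alpha`,
#'   `b`, `sigma`, `gamma`.
#' @seealso [predict.lssvr()], [lssvr_objective()], [direct_search()]
#' @examples
#' X <- matrix(runif(20), 10, 2)
#' y <- sin(X[, 1]) + X[, 2]
#' fit <- lssvr(X, y, sigma = 1, gamma = 10)
#' predict(fit, X)
#' @export
lssvr <- function(X, y, sigma, gamma) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  if (m < 2L) stop("lssvr: need at least 2 training rows")
  if (length(y) != m) stop("lssvr: length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("lssvr: non-finite values in training data")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("lssvr: 'gamma' must be a positive scalar")
  }
  K <- rbf_gram(X, sigma)
  A <- K
  diag(A) <- diag(A) + 1 / gamma
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    stop("lssvr: A = Omega + I/gamma is numerically singular ",
         "(duplicate rows with very large gamma?); reduce gamma or jitter X")
  }
  ones <- rep(1, m)
  Ainv_y <- backsolve(R, forwardsolve(t(R), y))
  Ainv_1 <- backsolve(R, forwardsolve(t(R), ones))
  b <- sum(Ainv_y) / sum(Ainv_1)
  alpha <- Ainv_y - b * Ainv_1
  structure(
    list(X_train = X, alpha = alpha, b = b, sigma = sigma, gamma = gamma),
    class = "lssvr"
  )
}

#' Predict from a fitted LS-SVR
#'
#' Evaluates \eqn{\hat y(x) = \sum_i \alpha_i K(x, x_i) + b} at each
#' query row.
#'
#' @param object An `"lssvr"` model.
#' @param newdata Numeric matrix (`q x d`) of query rows; column count
#'   must match the training data.
#' @param ... Unused.
#' @return Numeric vector of `q` predictions.
#' @export
predict.lssvr <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  Xt <- object$X_train
  if (ncol(Xq) != ncol(Xt)) {
    stop("predict.lssvr: query has ", ncol(Xq), " columns, model expects ",
         ncol(Xt))
  }
  sq_q <- rowSums(Xq^2)
  sq_t <- rowSums(Xt^2)
  d2 <- outer(sq_q, sq_t, "+") - 2 * tcrossprod(Xq, Xt)
  d2[d2 < 0] <- 0
  Kq <- exp(-d2 / (2 * object$sigma^2))
  drop(Kq %*% object$alpha) + object$b
}

#' @export
print.lssvr <- function(x, ...) {
  cat("LS-SVR model (RBF kernel)\n")
  cat(sprintf("  training rows: %d, predictors: %d\n",
              nrow(x$X_train), ncol(x$X_train)))
  cat(sprintf("  sigma = %g, gamma = %g, b = %g\n", x$sigma, x$gamma, x$b))
  invisible(x)
}

#' In-sample squared-error objective G(sigma, gamma)
#'
#' Fits an LS-SVR with the given hyperparameters and returns the mean
#' squared residual over the same training rows:
#' \deqn{G(\sigma, \gamma) = \frac{1}{m} \sum_j
#'   \big[y_j - \hat y(x_j; \sigma, \gamma)\big]^2.}
#' This is the surface the random direct search minimizes.
#'
#' @inheritParams lssvr
#' @return A nonnegative scalar.
#' @export
lssvr_objective <- function(X, y, sigma, gamma) {
  fit <- lssvr(X, y, sigma, gamma)
  mean((y - predict(fit, X))^2)
}
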