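#' @useDynLib spectraTransfer, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' SVR hyperparameters
#'
#' The RBF-kernel epsilon-insensitive support vector regression is
#' parameterized by the penalty `C` (unitless), the kernel parameter
#' `gamma` (inverse squared feature units) and the tube width `epsilon`
#' (label units).
#'
#' @param C penalty factor, > 0.
#' @param gamma RBF kernel parameter, > 0.
#' @param epsilon insensitive-tube half width, >= 0.
#' @return A list of class `svrParams`.
#' @export
svrParams <- function(C = 10, gamma = 0.01, epsilon = 0.01) {
  stopifnot(C > 0, gamma > 0, epsilon >= 0)
  structure(list(C = C, gamma = gamma, epsilon = epsilon,
                 kernel = "rbf"), class = "svrParams")
}

sqDist <- function(X, Z = NULL) {
  X <- as.matrix(X)
  if (is.null(Z)) Z <- X else Z <- as.matrix(Z)
  nx <- rowSums(X^2); nz <- rowSums(Z^2)
  d2 <- outer(nx, nz, "+") - 2 * tcrossprod(X, Z)
  pmax(d2, 0)
}

rbfKernel <- function(X, Z = NULL, gamma) exp(-gamma * sqDist(X, Z))

# Kernel-level weighted fit: per-sample penalties Cvec, bias absorbed into
# the kernel. Returns the dual coefficient vector.
svrFitKernel <- function(K, y, Cvec, epsilon, betaInit = NULL,
                         tol = NULL, maxSweeps = 20000L) {
  n <- length(y)
  if (is.null(betaInit)) betaInit <- numeric(n)
  if (is.null(tol)) tol <- 1e-8 * max(1, max(abs(y)))
  svr_cd_fit(K + 1, y, Cvec, epsilon, tol, maxSweeps, betaInit)
}

#' Fit a (weighted) RBF support vector regression
#'
#' Epsilon-insensitive SVR with the bias term absorbed into an augmented
#' kernel (K + 1), solved by dual coordinate descent with per-sample box
#' constraints. Optional nonnegative `sampleWeight`s scale each sample's
#' slack penalty as `C_i = C * w_i / mean(w)`, so a constant weight vector
#' reproduces the unweighted fit exactly and a zero-weight sample has no
#' influence. Feature columns are standardized with training-set
#' statistics by default (bottleneck-feature magnitudes are
#' scale-arbitrary).
#'
#' @param features samples x features matrix.
#' @param y labels.
#' @param params an [svrParams()].
#' @param sampleWeight optional nonnegative weights, not all zero.
#' @param scale standardize feature columns (default TRUE).
#' @return An object of class `svrModel`.
#' @export
svrFit <- function(features, y, params = svrParams(),
                   sampleWeight = NULL, scale = TRUE) {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (!all(is.finite(X))) stop("non-finite features")
  if (n > 1 && all(sqDist(X[1, , drop = FALSE], X) == 0))
    stop("all feature rows are identical; SVR is degenerate")
  if (is.null(sampleWeight)) sampleWeight <- rep(1, n)
  if (any(sampleWeight < 0) || all(sampleWeight == 0))
    stop("sampleWeight must be nonnegative and not all zero")
  ctr <- if (scale) colMeans(X) else numeric(ncol(X))
  scl <- if (scale) {
    s <- apply(X, 2L, sd); s[s == 0] <- 1; s
  } else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  # normalize by the mean positive weight: constant weights reproduce the
  # unweighted fit and zero-weight samples drop out exactly
  Cvec <- params$C * sampleWeight / mean(sampleWeight[sampleWeight > 0])
  K <- rbfKernel(Xs, gamma = params$gamma)
  beta <- svrFitKernel(K, y, Cvec, params$epsilon)
  structure(list(beta = beta, X = Xs, center = ctr, scale = scl,
                 params = params), class = "svrModel")
}

#' Predict from an svrModel
#' @param object an `svrModel` from [svrFit()].
#' @param features new samples x features matrix.
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @method predict svrModel
#' @export
predict.svrModel <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != ncol(object$X)) stop("feature dimension mismatch")
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  drop((rbfKernel(Xs, object$X, object$params$gamma) + 1) %*% object$beta)
}

#' Data-driven default SVR hyperparameters
#'
#' Sets the RBF `gamma` to the reciprocal of the median pairwise squared
#' distance between (column-standardized) feature rows — the common
#' median heuristic — with fixed `C` and `epsilon`.
#'
#' @param features samples x features matrix.
#' @param C penalty factor.
#' @param epsilon tube half width (label units).
#' @return An [svrParams()].
#' @export
svrParamsAuto <- function(features, C = 10, epsilon = 0.01) {
  X <- as.matrix(features)
  s <- apply(X, 2L, sd); s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2L, colMeans(X)), 2L, s, "/")
  d2 <- sqDist(Xs)
  med <- median(d2[upper.tri(d2)])
  if (!is.finite(med) || med <= 0) med <- ncol(X)
  svrParams(C = C, gamma = 1 / med, epsilon = epsilon)
}
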