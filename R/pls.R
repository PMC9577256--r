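#' PLS1 regression (NIPALS)
#'
#' Fits a univariate partial least squares regression with `ncomp` latent
#' components by the NIPALS algorithm on column-centered data. With
#' `ncomp` equal to the rank of the centered predictor matrix the fit
#' coincides with ordinary least squares.
#'
#' @param X numeric matrix, samples x predictors.
#' @param y numeric response vector.
#' @param ncomp number of latent components,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return An object of class `plsrModel` with the regression vector,
#'   score/loading matrices and centering means.
#' @seealso [plsrPredict()], [plsrSelectNcomp()]
#' @export
plsrFit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n-1, ncol(X))")
  mx <- colMeans(X); my <- mean(y)
  E <- sweep(X, 2L, mx); f <- y - my
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    p_a <- drop(crossprod(E, tt)) / tt2
    q_a <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, p_a)
    f <- f - q_a * tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- tt; q[a] <- q_a
  }
  if (ncomp < 1L) stop("predictors have no covariance with y")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), q)
  structure(list(coef = drop(B), xMeans = mx, yMean = my,
                 scores = Tm, loadings = P, weights = W, q = q,
                 ncomp = ncomp),
            class = "plsrModel")
}

#' Predict from a PLS1 model
#'
#' @param model a `plsrModel` from [plsrFit()].
#' @param X new samples x predictors matrix on the same variables.
#' @return Numeric vector of predictions.
#' @export
plsrPredict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$xMeans)) stop("wrong number of predictors")
  drop(sweep(X, 2L, model$xMeans) %*% model$coef) + model$yMean
}

#' Choose the PLS component count by cross-validated RMSE
#'
#' @param X,y training data.
#' @param ncompMax largest component count to try (default 20, clipped to
#'   the data's limit).
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return The component count with minimal CV RMSE.
#' @export
plsrSelectNcomp <- function(X, y, ncompMax = 20L, folds = 10L, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  folds <- min(folds, n)
  ncompMax <- min(ncompMax, n - ceiling(n / folds) - 1L, ncol(X))
  if (ncompMax < 1L) stop("too few samples for cross-validation")
  fold <- cvFolds(n, folds, seed)
  press <- numeric(ncompMax)
  for (f in seq_len(folds)) {
    idx <- fold == f
    for (a in seq_len(ncompMax)) {
      m <- plsrFit(X[!idx, , drop = FALSE], y[!idx], a)
      press[a] <- press[a] +
        sum((y[idx] - plsrPredict(m, X[idx, , drop = FALSE]))^2)
    }
  }
  which.min(press)
}

# Seeded, near-equal-size fold assignment shared by the CV routines.
cvFolds <- function(n, folds, seed) {
  rng <- localRNG(seed)
  on.exit(rng())
  sample(rep(seq_len(folds), length.out = n))
}

# Run code under a private RNG state; returns a restore function.
localRNG <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
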