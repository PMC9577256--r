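#' Uniform initial instance weights
#'
#' All `m` source and `n` target instances start at weight `1/(m+n)`.
#'
#' @param m source-instance count (>= 1).
#' @param n target-instance count (>= 1).
#' @return Numeric weight vector of length `m + n` summing to 1.
#' @export
initWeights <- function(m, n) {
  stopifnot(m >= 1L, n >= 1L)
  rep(1 / (m + n), m + n)
}

#' Prescribed target-weight fraction schedule
#'
#' In the two-stage boosting transfer, the summed weight of the target
#' instances after outer step `t` is driven along the schedule
#' `n/(m+n) + (t/(K-1)) * (1 - n/(m+n))`: it starts at the target share of
#' a uniform weighting (t = 0) and reaches 1 at the final step
#' (t = K - 1), strictly increasing in between.
#'
#' @param m source-instance count.
#' @param n target-instance count.
#' @param t step index, `0 <= t <= K - 1`.
#' @param K number of outer steps (>= 2).
#' @return The prescribed fraction in `[n/(m+n), 1]`.
#' @export
targetWeightFraction <- function(m, n, t, K) {
  if (K < 2L) stop("K must be >= 2")
  if (t < 0L || t > K - 1L) stop("t must be in 0..K-1")
  base <- n / (m + n)
  base + (t / (K - 1)) * (1 - base)
}

#' Adjusted per-instance boosting error
#'
#' Maps residuals to `[0, 1]` for the regression-boosting weight update:
#' with `D = max(|r|)`, the linear shape is `|r|/D`, the square shape
#' `(|r|/D)^2`, and the exponential shape `1 - exp(-|r|/D)`. All-zero
#' residuals give all-zero errors (the perfect-learner degenerate case).
#'
#' @param residuals numeric residual vector.
#' @param shape one of `"linear"`, `"square"`, `"exponential"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
adjustedError <- function(residuals, shape = c("linear", "square",
                                               "exponential")) {
  shape <- match.arg(shape)
  if (!all(is.finite(residuals))) stop("non-finite residuals")
  D <- max(abs(residuals))
  if (D == 0) return(rep(0, length(residuals)))
  r <- abs(residuals) / D
  switch(shape, linear = r, square = r^2, exponential = 1 - exp(-r))
}

#' Weighted median
#'
#' The smallest value whose cumulative weight (in ascending value order)
#' reaches half the total weight — the ensemble combination rule of
#' regression boosting.
#'
#' @param values numeric vector.
#' @param weights positive weights, same length.
#' @return The weighted median (one of `values`).
#' @export
weightedMedian <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][match(TRUE, cw >= 0.5 * sum(weights))]
}

# ---- kernel-level boosting machinery ----------------------------------
# All boosting fits inside one transfer run share the same feature set and
# SVR hyperparameters, so the (bias-augmented) kernel matrix is computed
# once and every fit works on an index subset of it.

# Qfull: (K + 1) over all rows; trainIdx: rows used for fitting;
# w: normalized weights over trainIdx; isFixed: logical over trainIdx
# (weights held constant during the inner boost).
adaboostKernel <- function(Qfull, y, trainIdx, w, N, C, epsilon,
                           lossShape = "linear", isFixed = NULL,
                           warn = TRUE) {
  Q <- Qfull[trainIdx, trainIdx, drop = FALSE]
  yt <- y[trainIdx]
  nt <- length(trainIdx)
  if (is.null(isFixed)) isFixed <- rep(FALSE, nt)
  members <- list(); mw <- numeric(0)
  betaPrev <- NULL
  # boosting members tolerate a looser dual solve than a standalone fit
  tolFit <- 1e-6 * max(1, max(abs(yt)))
  for (iter in seq_len(N)) {
    Cvec <- C * w / mean(w[w > 0])
    beta <- svr_cd_fit(Q, yt, Cvec, epsilon, tolFit, 500L,
                       if (is.null(betaPrev)) numeric(nt) else betaPrev)
    betaPrev <- beta
    fhat <- drop(Q %*% beta)
    e <- adjustedError(yt - fhat, lossShape)
    epsW <- sum(w * e)
    if (epsW >= 0.5) {
      if (iter == 1L) {
        if (warn)
          warning("first weak learner has weighted error >= 0.5; ",
                  "returning a single-member ensemble")
        members[[1]] <- beta; mw <- 1
      }
      break
    }
    if (epsW < 1e-12) {                    # perfect learner: stop boosting
      members[[length(members) + 1L]] <- beta
      mw <- c(mw, log(1e12))
      break
    }
    betaT <- epsW / (1 - epsW)
    members[[length(members) + 1L]] <- beta
    mw <- c(mw, log(1 / betaT))
    upd <- betaT^(1 - e)
    if (any(isFixed)) {
      freeMass <- sum(w[!isFixed])
      w[!isFixed] <- w[!isFixed] * upd[!isFixed]
      s <- sum(w[!isFixed])
      if (s > 0) w[!isFixed] <- w[!isFixed] * freeMass / s
    } else {
      w <- w * upd
      w <- w / sum(w)
    }
  }
  list(members = members, memberWeights = mw, trainIdx = trainIdx,
       finalW = w)
}

predictEnsembleKernel <- function(ens, Qcross) {
  # Qcross: (K + 1) rows = query points, cols = all training rows
  P <- vapply(ens$members, function(b)
    drop(Qcross[, ens$trainIdx, drop = FALSE] %*% b),
    numeric(nrow(Qcross)))
  P <- matrix(P, nrow = nrow(Qcross))
  apply(P, 1L, weightedMedian, weights = ens$memberWeights)
}

#' Fit an AdaBoost.R2 regression ensemble with SVR base learners
#'
#' Iterates: weighted SVR fit, adjusted errors, weighted error
#' `eps_t = sum(w_i e_i)`, stop if `eps_t >= 0.5`, else
#' `beta_t = eps_t / (1 - eps_t)`, update `w_i <- w_i beta_t^(1 - e_i)`
#' and renormalize. Predictions are the weighted median of member
#' predictions with member weights `log(1 / beta_t)`.
#'
#' @param features samples x features matrix.
#' @param y labels.
#' @param wInit normalized initial weights (default uniform).
#' @param N maximum boosting iterations.
#' @param baseParams an [svrParams()] shared by all members.
#' @param lossShape adjusted-error shape, see [adjustedError()].
#' @param scale standardize feature columns (default TRUE).
#' @return An object of class `adaboostR2` supporting `predict`.
#' @export
adaboostR2Fit <- function(features, y, wInit = NULL, N = 50L,
                          baseParams = svrParams(),
                          lossShape = "linear", scale = TRUE) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (is.null(wInit)) wInit <- rep(1 / n, n)
  stopifnot(length(wInit) == n, all(wInit >= 0))
  wInit <- wInit / sum(wInit)
  ctr <- if (scale) colMeans(X) else numeric(ncol(X))
  scl <- if (scale) { s <- apply(X, 2L, sd); s[s == 0] <- 1; s }
         else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Q <- rbfKernel(Xs, gamma = baseParams$gamma) + 1
  ens <- adaboostKernel(Q, y, seq_len(n), wInit, N, baseParams$C,
                        baseParams$epsilon, lossShape)
  structure(list(ensemble = ens, X = Xs, center = ctr, scale = scl,
                 params = baseParams), class = "adaboostR2")
}

#' @rdname adaboostR2Fit
#' @param object a fitted `adaboostR2`.
#' @param ... ignored.
#' @method predict adaboostR2
#' @export
predict.adaboostR2 <- function(object, features, ...) {
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  Qc <- rbfKernel(Xs, object$X, object$params$gamma) + 1
  predictEnsembleKernel(object$ensemble, Qc)
}

#' Stage-1 source down-weighting by binary search
#'
#' Updates the source-instance weights `w_i <- w_i * beta^(e_i)` (target
#' weights untouched before the joint renormalization), where
#' `beta in (0, 1]` is found by bisection so that the renormalized summed
#' target weight equals `targetFraction` (tolerance 1e-10). Smaller beta
#' means a larger target fraction. If the current target fraction already
#' meets or exceeds the request, `beta = 1` is returned (source instances
#' are never up-weighted).
#'
#' @param w normalized weight vector, source instances first.
#' @param sourceAdjErr adjusted errors of the source instances (length
#'   `nSource`).
#' @param targetFraction requested summed target weight, in (0, 1].
#' @param nSource number of source instances (default: length of
#'   `sourceAdjErr`).
#' @return A list with the updated normalized weights `w` and `beta`.
#' @export
stage1Update <- function(w, sourceAdjErr, targetFraction,
                         nSource = length(sourceAdjErr)) {
  stopifnot(targetFraction > 0, targetFraction <= 1,
            nSource < length(w))
  w <- w / sum(w)
  ws <- w[seq_len(nSource)]
  wt <- w[-seq_len(nSource)]
  e <- sourceAdjErr
  frac <- function(b) {
    st <- sum(wt)
    st / (sum(ws * b^e) + st)
  }
  cur <- frac(1)
  if (targetFraction <= cur + 1e-12) {
    if (targetFraction < cur - 1e-12)
      warning("requested target fraction below the current one; beta = 1")
    return(list(w = w, beta = 1))
  }
  if (targetFraction >= 1 - 1e-12) {
    # attainable only in the beta -> 0 limit: all weight moves to the
    # target block and the final step becomes target-only
    wNew <- c(ws * 0, wt)
    return(list(w = wNew / sum(wNew), beta = 0))
  }
  lo <- -300; hi <- 0                      # bisection on log10(beta)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (frac(10^mid) < targetFraction) hi <- mid else lo <- mid
    if (hi - lo < 1e-14) break
  }
  beta <- 10^((lo + hi) / 2)
  if (abs(frac(beta) - targetFraction) > 1e-8)
    warning("requested target fraction not attainable (zero-error source ",
            "instances); using the closest achievable weighting")
  wNew <- c(ws * beta^e, wt)
  list(w = wNew / sum(wNew), beta = beta)
}
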