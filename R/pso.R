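#' Particle swarm settings for SVR hyperparameter search
#'
#' Defaults follow the tuning protocol used throughout the package: a
#' swarm of 50 particles, cognitive factor c1 = 1.5, social factor
#' c2 = 1.7, 50 iterations, and 10-fold cross-validated RMSE as the
#' objective. Positions are optimized in log10 space over `bounds`
#' (rows C, gamma, epsilon) for scale invariance; the inertia weight
#' decays linearly from 0.9 to 0.4.
#'
#' @param swarmSize number of particles (>= 2).
#' @param c1,c2 cognitive and social acceleration factors.
#' @param maxIters PSO iterations.
#' @param cvFolds cross-validation folds for the objective.
#' @param bounds 3 x 2 matrix of (low, high) on the natural scale, rows
#'   named C, gamma, epsilon.
#' @param inertia length-2 vector: start and end inertia weight.
#' @param fixEpsilon fix epsilon at this value instead of searching it
#'   (NULL = search jointly).
#' @param seed RNG seed.
#' @return A list of class `psoConfig`.
#' @export
psoConfig <- function(swarmSize = 50L, c1 = 1.5, c2 = 1.7,
                      maxIters = 50L, cvFolds = 10L,
                      bounds = rbind(C = c(1e-2, 1e3),
                                     gamma = c(1e-4, 1e1),
                                     epsilon = c(1e-4, 1e0)),
                      inertia = c(0.9, 0.4),
                      fixEpsilon = NULL, seed = 1L) {
  stopifnot(swarmSize >= 2L, all(bounds[, 1] < bounds[, 2]))
  structure(list(swarmSize = as.integer(swarmSize), c1 = c1, c2 = c2,
                 maxIters = as.integer(maxIters),
                 cvFolds = as.integer(cvFolds), bounds = bounds,
                 inertia = inertia, fixEpsilon = fixEpsilon,
                 seed = as.integer(seed)),
            class = "psoConfig")
}

svrCvRmse <- function(features, y, params, fold, scale = TRUE) {
  pred <- numeric(length(y))
  for (f in unique(fold)) {
    idx <- fold == f
    m <- svrFit(features[!idx, , drop = FALSE], y[!idx], params,
                scale = scale)
    pred[idx] <- predict(m, features[idx, , drop = FALSE])
  }
  sqrt(mean((y - pred)^2))
}

# Kernel-level CV objective: the pairwise squared distances are computed
# once per search (features standardized once on the full set), so each
# (C, gamma, epsilon) evaluation costs one exponentiation plus F small
# dual solves on kernel submatrices.
svrCvRmseKernel <- function(D2, y, params, fold) {
  Q <- exp(-params$gamma * D2) + 1
  n <- length(y)
  pred <- numeric(n)
  tol <- 1e-6 * max(1, max(abs(y)))
  for (f in unique(fold)) {
    idx <- which(fold == f)
    tr <- setdiff(seq_len(n), idx)
    beta <- svr_cd_fit(Q[tr, tr, drop = FALSE], y[tr],
                       rep(params$C, length(tr)), params$epsilon,
                       tol, 1000L, numeric(length(tr)))
    pred[idx] <- Q[idx, tr, drop = FALSE] %*% beta
  }
  sqrt(mean((y - pred)^2))
}

#' PSO search for SVR hyperparameters
#'
#' Minimizes the F-fold cross-validated RMSE of an RBF SVR over
#' (C, gamma, epsilon) within the configured bounds. Velocities follow
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`; positions are
#' clipped to the bounds. The global best is monotone over iterations and
#' the whole search is reproducible under the configured seed.
#'
#' @param features samples x features matrix.
#' @param y labels.
#' @param cfg a [psoConfig()].
#' @return An [svrParams()] with attributes `cvRmse` (best objective) and
#'   `trace` (data.frame: iteration, C, gamma, epsilon, cvRmse).
#' @export
psoOptimize <- function(features, y, cfg = psoConfig()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < cfg$cvFolds) stop("fewer samples than CV folds")
  restore <- localRNG(cfg$seed)
  on.exit(restore())
  fold <- cvFolds(n, cfg$cvFolds, seed = cfg$seed + 1L)

  s <- apply(features, 2L, sd); s[s == 0] <- 1
  Xs <- sweep(sweep(features, 2L, colMeans(features)), 2L, s, "/")
  D2 <- sqDist(Xs)

  lb <- log10(cfg$bounds[, 1]); ub <- log10(cfg$bounds[, 2])
  ndim <- 3L
  searchEps <- is.null(cfg$fixEpsilon)
  toParams <- function(pos) {
    eps <- if (searchEps) 10^pos[3] else cfg$fixEpsilon
    svrParams(C = 10^pos[1], gamma = 10^pos[2], epsilon = eps)
  }
  S <- cfg$swarmSize
  pos <- t(vapply(seq_len(S), function(i) lb + runif(ndim) * (ub - lb),
                  numeric(ndim)))
  vel <- matrix(0, S, ndim)
  fitness <- vapply(seq_len(S), function(i)
    svrCvRmseKernel(D2, y, toParams(pos[i, ]), fold), numeric(1))
  pbest <- pos; pbestFit <- fitness
  g <- which.min(fitness)
  gbest <- pos[g, ]; gbestFit <- fitness[g]
  trace <- vector("list", cfg$maxIters)
  for (it in seq_len(cfg$maxIters)) {
    w <- cfg$inertia[1] +
      (cfg$inertia[2] - cfg$inertia[1]) * (it - 1) / max(cfg$maxIters - 1, 1)
    for (i in seq_len(S)) {
      r1 <- runif(ndim); r2 <- runif(ndim)
      vel[i, ] <- w * vel[i, ] + cfg$c1 * r1 * (pbest[i, ] - pos[i, ]) +
        cfg$c2 * r2 * (gbest - pos[i, ])
      pos[i, ] <- pmin(pmax(pos[i, ] + vel[i, ], lb), ub)
      f <- svrCvRmseKernel(D2, y, toParams(pos[i, ]), fold)
      if (f < pbestFit[i]) { pbest[i, ] <- pos[i, ]; pbestFit[i] <- f }
      if (f < gbestFit) { gbest <- pos[i, ]; gbestFit <- f }
    }
    pp <- toParams(gbest)
    trace[[it]] <- data.frame(iteration = it, C = pp$C, gamma = pp$gamma,
                              epsilon = pp$epsilon, cvRmse = gbestFit)
  }
  out <- toParams(gbest)
  attr(out, "cvRmse") <- gbestFit
  attr(out, "trace") <- do.call(rbind, trace)
  out
}
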