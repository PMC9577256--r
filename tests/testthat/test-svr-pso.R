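# independent cross-validated-RMSE oracle used by the PSO tests
cvRmseOracle <- function(X, y, params, folds = 4, seed = 11) {
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = length(y)))
  pred <- numeric(length(y))
  for (f in seq_len(folds)) {
    idx <- fold == f
    m <- svrFit(X[!idx, , drop = FALSE], y[!idx], params)
    pred[idx] <- predict(m, X[idx, , drop = FALSE])
  }
  sqrt(mean((y - pred)^2))
}

test_that("SVR interpolates an RBF-representable function at large C", {
  set.seed(1)
  X <- matrix(rnorm(30 * 2), 30, 2)
  alpha <- rnorm(30)
  K <- exp(-2 * as.matrix(dist(X))^2)
  y <- drop(K %*% alpha)                   # exactly representable
  m <- svrFit(X, y, svrParams(C = 1e4, gamma = 2, epsilon = 1e-3),
              scale = FALSE)
  expect_lt(max(abs(y - predict(m, X))), 1e-3 + 1e-4)
})

test_that("constant sample weights reproduce the unweighted fit exactly", {
  set.seed(2)
  X <- matrix(rnorm(25 * 3), 25, 3)
  y <- X[, 1] + 0.2 * rnorm(25)
  p <- svrParams(C = 5, gamma = 0.2, epsilon = 0.01)
  m0 <- svrFit(X, y, p)
  mk <- svrFit(X, y, p, sampleWeight = rep(3.7, 25))
  expect_identical(m0$beta, mk$beta)
  Xq <- matrix(rnorm(10 * 3), 10, 3)
  expect_identical(predict(m0, Xq), predict(mk, Xq))
})

test_that("a zero-weight sample has no influence", {
  set.seed(3)
  X <- matrix(rnorm(20 * 2), 20, 2)
  y <- sin(X[, 1]) + 0.1 * rnorm(20)
  p <- svrParams(C = 10, gamma = 0.5, epsilon = 0.01)
  w <- rep(1, 20); w[9] <- 0
  mw <- svrFit(X, y, p, sampleWeight = w, scale = FALSE)
  mr <- svrFit(X[-9, ], y[-9], p, sampleWeight = w[-9], scale = FALSE)
  Xq <- matrix(rnorm(8 * 2), 8, 2)
  expect_equal(predict(mw, Xq), predict(mr, Xq), tolerance = 1e-8)
})

test_that("the fit agrees with an independent SVR implementation", {
  skip_if_not_installed("e1071")
  set.seed(4)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- sin(X[, 1]) + 0.5 * X[, 2]
  y <- y - mean(y)                         # near-zero bias regime
  m <- svrFit(X, y, svrParams(C = 10, gamma = 0.5, epsilon = 0.01),
              scale = FALSE)
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = 10, gamma = 0.5, epsilon = 0.01, scale = FALSE)
  Xq <- matrix(rnorm(20 * 2), 20, 2)
  expect_lt(sqrt(mean((predict(m, Xq) -
                       unname(predict(ref, Xq)))^2)), 0.05 * sd(y))
})

test_that("degenerate inputs are rejected", {
  X <- matrix(1, 5, 3)
  expect_error(svrFit(X, rnorm(5), svrParams()), "identical")
  X2 <- matrix(rnorm(10), 5, 2)
  expect_error(svrFit(X2, rnorm(5), svrParams(),
                      sampleWeight = rep(0, 5)), "sampleWeight")
})

test_that("PSO is elitist, bounded, and seed-reproducible", {
  fx <- featureFixture(30, d = 2, seed = 5)
  cfg <- psoConfig(swarmSize = 6L, maxIters = 6L, cvFolds = 4L, seed = 3L)
  best <- psoOptimize(fx$X, fx$y, cfg)
  tr <- attr(best, "trace")
  expect_true(all(diff(tr$cvRmse) <= 1e-12))
  b <- cfg$bounds
  expect_true(best$C >= b[1, 1] && best$C <= b[1, 2])
  expect_true(best$gamma >= b[2, 1] && best$gamma <= b[2, 2])
  expect_true(best$epsilon >= b[3, 1] && best$epsilon <= b[3, 2])
  best2 <- psoOptimize(fx$X, fx$y, cfg)
  expect_identical(unclass(best)[], unclass(best2)[])
  expect_error(psoOptimize(fx$X[1:3, ], fx$y[1:3], cfg), "folds")
})

test_that("PSO beats random search when only C is free", {
  fx <- featureFixture(32, d = 2, seed = 6)
  b <- rbind(C = c(1e-2, 1e3),
             gamma = c(0.3, 0.3 * (1 + 1e-9)),
             epsilon = c(0.01, 0.01 * (1 + 1e-9)))
  cfg <- psoConfig(swarmSize = 10L, maxIters = 10L, cvFolds = 4L,
                   bounds = b, seed = 4L)
  best <- psoOptimize(fx$X, fx$y, cfg)
  expect_true(best$C >= b[1, 1] && best$C <= b[1, 2])
  # evaluate PSO's winner and the random candidates on the very fold
  # partition PSO optimized, with an independently written CV loop
  cvSame <- function(params) {
    set.seed(cfg$seed + 1L)
    fold <- sample(rep(seq_len(4L), length.out = length(fx$y)))
    pred <- numeric(length(fx$y))
    for (f in 1:4) {
      idx <- fold == f
      m <- svrFit(fx$X[!idx, , drop = FALSE], fx$y[!idx], params)
      pred[idx] <- predict(m, fx$X[idx, , drop = FALSE])
    }
    sqrt(mean((fx$y - pred)^2))
  }
  set.seed(9)
  randRmse <- vapply(1:20, function(i)
    cvSame(svrParams(C = 10^runif(1, -2, 3), gamma = 0.3,
                     epsilon = 0.01)), numeric(1))
  expect_lte(cvSame(best), min(randRmse) * 1.02)
})

test_that("PSO tuning improves on fixed mid-bounds defaults", {
  wins <- vapply(1:5, function(s) {
    fx <- featureFixture(30, d = 2, seed = 20 + s)
    cfg <- psoConfig(swarmSize = 6L, maxIters = 5L, cvFolds = 4L,
                     seed = s)
    best <- psoOptimize(fx$X, fx$y, cfg)
    mid <- svrParams(C = sqrt(1e-2 * 1e3), gamma = sqrt(1e-4 * 1e1),
                     epsilon = sqrt(1e-4 * 1))
    cvRmseOracle(fx$X, fx$y, best, seed = s) -
      cvRmseOracle(fx$X, fx$y, mid, seed = s)
  }, numeric(1))
  expect_lte(median(wins), 0)
})
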