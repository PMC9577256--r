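test_that("initial weights are uniform over the pooled instances", {
  expect_equal(initWeights(3, 1), rep(0.25, 4))
  expect_equal(initWeights(118, 118), rep(1 / 236, 236))
  for (m in c(1, 7, 50)) for (n in c(1, 9))
    expect_equal(sum(initWeights(m, n)), 1)
  expect_error(initWeights(0, 5))
})

test_that("the target-weight schedule runs from the uniform share to 1", {
  expect_equal(targetWeightFraction(80, 20, 0, 5), 20 / 100)
  expect_equal(targetWeightFraction(80, 20, 4, 5), 1)
  expect_equal(targetWeightFraction(80, 20, 2, 5), 0.2 + 0.5 * 0.8)
  fr <- vapply(0:9, targetWeightFraction, numeric(1), m = 30, n = 10,
               K = 10)
  expect_true(all(diff(fr) > 0))
  expect_error(targetWeightFraction(5, 5, 0, 1), "K")
  expect_error(targetWeightFraction(5, 5, 5, 5), "t must")
})

test_that("adjusted errors normalize residuals into [0, 1]", {
  expect_equal(adjustedError(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(adjustedError(c(-1, 2, -4)), c(0.25, 0.5, 1))
  expect_equal(max(adjustedError(rnorm(10))), 1)
  expect_equal(adjustedError(rep(0, 5)), rep(0, 5))
  expect_equal(adjustedError(c(1, 2, 4), "square"), c(0.0625, 0.25, 1))
  expect_equal(adjustedError(c(1, 2, 4), "exponential"),
               1 - exp(-c(0.25, 0.5, 1)))
})

test_that("the weighted median matches exhaustive candidate checking", {
  bruteWeightedMedian <- function(v, w) {
    # smallest candidate whose <=-cumulated weight reaches half the total
    for (cand in sort(v)) if (sum(w[v <= cand]) >= 0.5 * sum(w)) return(cand)
  }
  set.seed(1)
  for (i in 1:50) {
    v <- rnorm(3); w <- runif(3)
    expect_equal(weightedMedian(v, w), bruteWeightedMedian(v, w))
  }
  expect_equal(weightedMedian(c(5, 1, 9), c(1, 1, 1)), 5)
  expect_equal(weightedMedian(c(5, 1, 9), c(0.1, 0.1, 10)), 9)
})

test_that("stage-1 beta matches the grid-search oracle on the worked case", {
  # m = n = 2, uniform weights, source errors (1, 1), requested 2/3
  up <- stage1Update(rep(0.25, 4), c(1, 1), 2 / 3, nSource = 2)
  grid <- seq(1e-6, 1, by = 1e-6)
  frac <- (0.5) / (0.25 * grid^1 + 0.25 * grid^1 + 0.5)
  betaGrid <- grid[which.min(abs(frac - 2 / 3))]
  expect_equal(up$beta, 0.5, tolerance = 1e-9)
  expect_equal(up$beta, betaGrid, tolerance = 1e-5)
  expect_equal(sum(up$w[3:4]), 2 / 3, tolerance = 1e-10)
  expect_equal(sum(up$w), 1)
})

test_that("stage-1 update honours its contracts", {
  w <- c(0.3, 0.2, 0.25, 0.25)
  # fixed point: requested fraction equals the current one
  up <- stage1Update(w, c(0.5, 0.8), 0.5, nSource = 2)
  expect_equal(up$beta, 1)
  expect_equal(up$w, w)
  expect_warning(stage1Update(w, c(0.5, 0.8), 0.3, nSource = 2),
                 "below")
  set.seed(2)
  for (i in 1:10) {
    e <- runif(4)
    want <- runif(1, 0.55, 0.95)
    up <- stage1Update(rep(0.125, 8), e, want, nSource = 4)
    expect_gt(up$beta, 0); expect_lte(up$beta, 1)
    expect_equal(sum(up$w[5:8]), want, tolerance = 1e-10)
    expect_equal(sum(up$w), 1, tolerance = 1e-12)
    expect_true(all(up$w >= 0))
  }
  # monotonicity: a larger requested fraction needs a smaller beta
  e <- c(0.4, 0.9)
  b1 <- stage1Update(rep(0.25, 4), e, 0.6, nSource = 2)$beta
  b2 <- stage1Update(rep(0.25, 4), e, 0.9, nSource = 2)$beta
  expect_lt(b2, b1)
})

test_that("a single boosting iteration equals one weighted SVR", {
  fx <- featureFixture(30, seed = 3)
  w <- runif(30); w <- w / sum(w)
  p <- svrParams(C = 5, gamma = 0.3, epsilon = 0.01)
  ens <- adaboostR2Fit(fx$X, fx$y, wInit = w, N = 1L, baseParams = p)
  single <- svrFit(fx$X, fx$y, p, sampleWeight = w)
  Xq <- matrix(rnorm(20 * 3), 20, 3)
  # the ensemble's inner solver runs at a looser duality tolerance than a
  # standalone fit, so the agreement is numerical, not bit-exact
  expect_equal(predict(ens, Xq), predict(single, Xq), tolerance = 5e-3)
})

test_that("boosting conserves the weight distribution", {
  fx <- featureFixture(25, seed = 4)
  ens <- adaboostR2Fit(fx$X, fx$y, N = 8L,
                       baseParams = svrParams(C = 2, gamma = 0.3,
                                              epsilon = 0.05))
  w <- ens$ensemble$finalW
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
  expect_gte(length(ens$ensemble$members), 1L)
})

test_that("a hopeless first learner yields a single-member ensemble", {
  set.seed(5)
  X <- matrix(rnorm(20 * 2), 20, 2)
  y <- rep(c(-1, 1), 10)                  # tiny C: near-constant learner
  expect_warning(
    ens <- adaboostR2Fit(X, y, N = 10L,
                         baseParams = svrParams(C = 1e-4, gamma = 0.1,
                                                epsilon = 0)),
    ">= 0.5")
  expect_length(ens$ensemble$members, 1L)
})

test_that("transfer does no harm when source and target coincide", {
  ratios <- vapply(1:5, function(s) {
    src <- featureFixture(60, seed = 100 + s)
    tgt <- featureFixture(40, seed = 200 + s)
    new <- featureFixture(30, seed = 300 + s, noise = 0)
    p <- svrParams(C = 10, gamma = 0.3, epsilon = 0.01)
    tm <- fitTwoStage(src$X, src$y, tgt$X, tgt$y,
                      transferConfig(K = 3L, N = 5L, F = 3L, seed = s), p)
    hybrid <- sqrt(mean((new$y - predict(tm, new$X))^2))
    tonly <- svrFit(tgt$X, tgt$y, p)
    base <- sqrt(mean((new$y - predict(tonly, new$X))^2))
    hybrid / base
  }, numeric(1))
  expect_lte(median(ratios), 1.1)
})

test_that("transfer beats a source-only model under a planted label shift", {
  # a smooth kernel lets ten target points move the whole response
  # surface, which is the mechanism the boosting transfer exploits
  wins <- vapply(1:5, function(s) {
    src <- featureFixture(60, d = 2, seed = 400 + s)
    tgt <- featureFixture(10, d = 2, shift = 0.5, seed = 500 + s)
    new <- featureFixture(30, d = 2, shift = 0.5, seed = 600 + s,
                          noise = 0)
    p <- svrParams(C = 10, gamma = 0.1, epsilon = 0.01)
    tm <- fitTwoStage(src$X, src$y, tgt$X, tgt$y,
                      transferConfig(K = 4L, N = 8L, F = 5L, seed = s), p)
    hybrid <- sqrt(mean((new$y - predict(tm, new$X))^2))
    sonly <- svrFit(src$X, src$y, p)
    hybrid < sqrt(mean((new$y - predict(sonly, new$X))^2))
  }, logical(1))
  expect_gte(sum(wins), 4L)
})

test_that("the source share of the weight never increases across steps", {
  src <- featureFixture(40, seed = 7)
  tgt <- featureFixture(20, shift = 0.3, seed = 8)
  tm <- fitTwoStage(src$X, src$y, tgt$X, tgt$y,
                    transferConfig(K = 5L, N = 3L, F = 3L, seed = 1),
                    svrParams(C = 5, gamma = 0.3, epsilon = 0.01))
  tr <- transferTrace(tm)
  expect_true(all(diff(tr$targetFraction) >= -1e-12))
  expect_true(all(tr$beta[!is.na(tr$beta)] <= 1))
  expect_equal(tr$targetFraction[nrow(tr) - 1L], 1)
})

test_that("with beta forced to 1 the first step is plain pooled boosting", {
  src <- featureFixture(25, seed = 9)
  tgt <- featureFixture(15, seed = 10)
  p <- svrParams(C = 5, gamma = 0.3, epsilon = 0.02)
  tm <- fitTwoStage(src$X, src$y, tgt$X, tgt$y,
                    transferConfig(K = 2L, N = 4L, F = 3L, seed = 1,
                                   strictTwoStage = FALSE, forceBeta = 1),
                    p)
  pooled <- adaboostR2Fit(rbind(src$X, tgt$X), c(src$y, tgt$y), N = 4L,
                          baseParams = p)
  e1 <- tm@ensembles[[1]]
  expect_equal(e1$memberWeights, pooled$ensemble$memberWeights)
  Xq <- matrix(rnorm(10 * 3), 10, 3)
  Xqs <- sweep(sweep(Xq, 2, tm@center), 2, tm@scale, "/")
  Qc <- exp(-p$gamma * spectraTransfer:::sqDist(Xqs, tm@X)) + 1
  expect_equal(spectraTransfer:::predictEnsembleKernel(e1, Qc),
               predict(pooled, Xq), tolerance = 1e-10)
})

test_that("transfer predictions are deterministic and row-wise", {
  src <- featureFixture(30, seed = 11)
  tgt <- featureFixture(15, shift = 0.2, seed = 12)
  tm <- fitTwoStage(src$X, src$y, tgt$X, tgt$y,
                    transferConfig(K = 2L, N = 3L, F = 3L, seed = 1),
                    svrParams(C = 5, gamma = 0.3, epsilon = 0.01))
  Xq <- matrix(rnorm(12 * 3), 12, 3)
  p1 <- predict(tm, Xq)
  expect_identical(p1, predict(tm, Xq))
  perm <- sample(12)
  expect_identical(predict(tm, Xq[perm, ]), p1[perm])
  expect_error(predict(tm, Xq[, 1:2]), "dimension")
})
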