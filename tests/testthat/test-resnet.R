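tinyResnet <- function(inputLen = 32, seed = 1)
  buildBackbone(inputLen,
                resnetConfig(nStages = 1L, blocksPerStage = 1L,
                             channels = 4L, fcSizes = 8L, strides = 2L),
                seed = seed)

test_that("the architecture layout follows the stride arithmetic", {
  lay <- resnetLayout(resnetConfig(), 2151)
  expect_equal(lay$nMainConvs, 16L)        # 4 stages x 2 blocks x 2 convs
  expect_equal(lay$outLen, 135L)           # ceil(2151 / 16)
  expect_equal(lay$flattenDim, 135L * 512L)
  # projection shortcuts exactly where channels or stride change
  expect_equal(lay$blocks$projection,
               rep(c(TRUE, FALSE), 4))
  expect_error(resnetLayout(resnetConfig(), 8), "shorter")
})

test_that("a tiny backbone builds and emits one scalar per sample", {
  bb <- tinyResnet()
  x <- matrix(rnorm(3 * 32), 3, 32)
  p <- predict(bb, x)
  expect_length(p, 3L)
  expect_true(all(is.finite(p)))
  expect_error(predict(bb, matrix(0, 2, 31)), "expects")
})

test_that("training overfits a small set and is seed-reproducible", {
  set.seed(3)
  x <- matrix(rnorm(20 * 32), 20, 32)
  y <- rowMeans(x[, 1:8]) + 0.1 * rnorm(20)
  tc <- trainConfig(maxEpochs = 200L, earlyStopPatience = 200L,
                    lrPatience = 200L, seed = 7L)
  m1 <- trainBackbone(tinyResnet(seed = 2), x, y, tc)
  h <- trainingHistory(m1)
  expect_lt(tail(h$loss, 1), 0.1 * h$loss[1])
  m2 <- trainBackbone(tinyResnet(seed = 2), x, y, tc)
  expect_identical(tail(trainingHistory(m2)$loss, 1), tail(h$loss, 1))
})

test_that("early stopping halts a converged run within patience", {
  set.seed(4)
  x <- matrix(rnorm(10 * 32), 10, 32)
  y <- rnorm(10)
  m <- trainBackbone(tinyResnet(), x, y,
                     trainConfig(maxEpochs = 100L, earlyStopPatience = 100L,
                                 seed = 1L))
  # retraining the already-converged model with patience 1 stops fast
  m2 <- trainBackbone(m, x, y,
                      trainConfig(maxEpochs = 100L, lr = 1e-12,
                                  earlyStopPatience = 1L, seed = 1L))
  expect_lte(nrow(trainingHistory(m2)), 2L)
})

test_that("freezing controls exactly which convolutions can change", {
  cfg16 <- resnetConfig(nStages = 4L, blocksPerStage = 2L,
                        channels = c(2L, 2L, 4L, 4L), fcSizes = 8L,
                        strides = c(1L, 1L, 2L, 2L))
  src <- buildBackbone(32, cfg16, seed = 5)
  set.seed(6)
  x <- matrix(rnorm(12 * 32), 12, 32)
  y <- rnorm(12)
  tc <- trainConfig(maxEpochs = 3L, seed = 2L)
  total <- length(freezeMask(src))
  expect_equal(total, 16L)

  convNames <- function(mask) paste0(rep(names(mask), each = 2),
                                     c("_W", "_b"))
  # freeze all: every main conv bit-identical after training
  ftAll <- fineTune(src, x, y, nFrozenConv = total, tc = tc)
  for (nm in convNames(freezeMask(ftAll)))
    expect_identical(ftAll@params[[nm]], src@params[[nm]])

  # freeze none: all conv weights move on a nontrivial set
  ft0 <- fineTune(src, x, y, nFrozenConv = 0L, tc = tc)
  for (nm in names(freezeMask(ft0)))
    expect_false(identical(ft0@params[[paste0(nm, "_W")]],
                           src@params[[paste0(nm, "_W")]]))

  # freeze 10 of 16: exactly convolutions 1-10 (forward order) frozen
  ft10 <- fineTune(src, x, y, nFrozenConv = 10L, tc = tc)
  expect_identical(unname(freezeMask(ft10)),
                   rep(c(TRUE, FALSE), c(10L, 6L)))
  nms <- names(freezeMask(ft10))
  for (i in seq_len(16L)) {
    same <- identical(ft10@params[[paste0(nms[i], "_W")]],
                      src@params[[paste0(nms[i], "_W")]])
    expect_equal(same, i <= 10L, label = nms[i])
  }
  expect_error(fineTune(src, x, y, nFrozenConv = 17L), "0..16")
})

test_that("bottleneck features are deterministic inference outputs", {
  set.seed(8)
  x <- matrix(rnorm(6 * 32), 6, 32)
  m <- trainBackbone(tinyResnet(), x, rnorm(6),
                     trainConfig(maxEpochs = 5L, seed = 1L))
  f1 <- bottleneckFeatures(m, x)
  expect_equal(dim(f1), c(6L, resnetLayout(m@config, 32L)$flattenDim))
  expect_identical(f1, bottleneckFeatures(m, x))
  xdup <- x[c(1, 1, 3:6), ]
  fdup <- bottleneckFeatures(m, xdup)
  expect_identical(fdup[1, ], fdup[2, ])
})

test_that("zeroing a residual branch makes the block an identity", {
  cfg2 <- resnetConfig(nStages = 1L, blocksPerStage = 2L, channels = 4L,
                       fcSizes = 8L, strides = 2L)
  m2 <- buildBackbone(32, cfg2, seed = 9)
  # kill block 2's residual branch via its second BN scale/offset
  m2@params[["s1b2n2_g"]][] <- 0
  m2@params[["s1b2n2_be"]][] <- 0
  # block 2 has an identity shortcut, so features equal those of the
  # one-block network sharing block 1's parameters
  cfg1 <- resnetConfig(nStages = 1L, blocksPerStage = 1L, channels = 4L,
                       fcSizes = 8L, strides = 2L)
  m1 <- buildBackbone(32, cfg1, seed = 10)
  for (nm in grep("^s1b1", names(m1@params), value = TRUE))
    m1@params[[nm]] <- m2@params[[nm]]
  m1@bnState <- m2@bnState[names(m1@bnState)]
  x <- matrix(rnorm(4 * 32), 4, 32)
  expect_equal(bottleneckFeatures(m2, x), bottleneckFeatures(m1, x),
               tolerance = 1e-12)
})

test_that("an all-zero output head yields a constant prediction", {
  m <- tinyResnet()
  m@params[["out_W"]][] <- 0
  m@params[["out_b"]][] <- 0.25
  p <- predict(m, matrix(rnorm(5 * 32), 5, 32))
  expect_equal(p, rep(m@yCenter + m@yScale * 0.25, 5))
})
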