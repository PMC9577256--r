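#' Configuration of the 1D residual backbone
#'
#' Describes the regression CNN used as spectral feature extractor: a
#' stack of residual stages (each stage = `blocksPerStage` basic blocks;
#' each basic block = Conv-BN-ReLU-Conv-BN plus a shortcut, followed by
#' ReLU), a flatten layer, fully connected ReLU layers and a scalar
#' linear output. The first convolution of each stage downsamples by the
#' stage stride; shortcuts are identity when shapes match and a
#' kernel-width-1 projection convolution (plus BN) otherwise. The default
#' mirrors the full-size network: four stages of two basic blocks with two
#' kernel-3 convolutions each (16 main convolutions), channels
#' 64/128/256/512, and FC sizes 512/128/64/32.
#'
#' @param nStages number of residual stages.
#' @param blocksPerStage basic blocks per stage.
#' @param channels integer vector of channel counts, length `nStages`.
#' @param kernelSize odd convolution kernel width.
#' @param fcSizes sizes of the fully connected layers after flatten.
#' @param strides per-stage downsampling stride (applied in the first
#'   convolution of the stage's first block).
#' @return A list of class `resnetConfig`.
#' @seealso [resnetTestProfile()] for a small fast profile.
#' @export
resnetConfig <- function(nStages = 4L, blocksPerStage = 2L,
                         channels = c(64L, 128L, 256L, 512L),
                         kernelSize = 3L,
                         fcSizes = c(512L, 128L, 64L, 32L),
                         strides = rep(2L, nStages)) {
  stopifnot(length(channels) == nStages, length(strides) == nStages,
            kernelSize %% 2L == 1L, nStages >= 1L, blocksPerStage >= 1L)
  structure(list(nStages = as.integer(nStages),
                 blocksPerStage = as.integer(blocksPerStage),
                 channels = as.integer(channels),
                 kernelSize = as.integer(kernelSize),
                 fcSizes = as.integer(fcSizes),
                 strides = as.integer(strides)),
            class = "resnetConfig")
}

#' Small backbone profile for fast experiments
#'
#' Two stages of 8 and 16 channels with FC sizes 16/8: the same
#' architecture family at a size that trains in seconds on a CPU. Used
#' throughout the test suite and the worked examples.
#'
#' @return A `resnetConfig`.
#' @export
resnetTestProfile <- function() {
  resnetConfig(nStages = 2L, blocksPerStage = 2L, channels = c(8L, 16L),
               kernelSize = 3L, fcSizes = c(16L, 8L),
               strides = c(2L, 2L))
}

#' Training settings for the backbone
#'
#' Adam with MSE loss; the learning rate is halved (by `lrReduceFactor`)
#' when the monitored loss has not improved for `lrPatience` epochs, and
#' training stops early after `earlyStopPatience` stalled epochs. The
#' monitored loss is the training loss by default (the calibration sets
#' are small); set `valFraction > 0` to monitor a held-out split instead.
#'
#' @param batchSize minibatch size (default 5).
#' @param lr initial Adam learning rate.
#' @param lrReduceFactor multiplicative LR decay on plateau, in (0, 1).
#' @param lrPatience epochs without improvement before LR reduction.
#' @param earlyStopPatience epochs without improvement before stopping.
#' @param maxEpochs hard epoch cap.
#' @param valFraction fraction of samples held out for monitoring (0 =
#'   monitor training loss).
#' @param seed RNG seed for shuffling (and the validation split).
#' @return A list of class `trainConfig`.
#' @export
trainConfig <- function(batchSize = 5L, lr = 1e-3, lrReduceFactor = 0.5,
                        lrPatience = 10L, earlyStopPatience = 30L,
                        maxEpochs = 500L, valFraction = 0,
                        seed = 1L) {
  stopifnot(batchSize >= 1L, lrReduceFactor > 0, lrReduceFactor < 1)
  structure(list(batchSize = as.integer(batchSize), lr = lr,
                 lrReduceFactor = lrReduceFactor,
                 lrPatience = as.integer(lrPatience),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 maxEpochs = as.integer(maxEpochs),
                 valFraction = valFraction, seed = as.integer(seed)),
            class = "trainConfig")
}

#' Static layout of a backbone
#'
#' Resolves the architecture against an input length without allocating
#' any weights: per-block input/output channels, strides, spatial lengths
#' and shortcut type, the main-convolution count, and the flatten
#' dimension (`ceil`-mode stride arithmetic).
#'
#' @param config a [resnetConfig()].
#' @param inputLen spectrum length in points.
#' @return A list with `blocks` (data.frame), `nMainConvs`, `outLen`,
#'   `flattenDim`.
#' @export
resnetLayout <- function(config, inputLen) {
  if (inputLen < prod(config$strides))
    stop("input length shorter than the total downsampling factor")
  rows <- list()
  inCh <- 1L; L <- as.integer(inputLen)
  for (s in seq_len(config$nStages)) {
    for (b in seq_len(config$blocksPerStage)) {
      stride <- if (b == 1L) config$strides[s] else 1L
      outCh <- config$channels[s]
      Lout <- convOutLen(L, stride)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = s, block = b, inCh = inCh, outCh = outCh,
        stride = stride, inLen = L, outLen = Lout,
        projection = (inCh != outCh || stride != 1L))
      inCh <- outCh; L <- Lout
    }
  }
  blocks <- do.call(rbind, rows)
  list(blocks = blocks,
       nMainConvs = 2L * nrow(blocks),
       outLen = L,
       flattenDim = L * inCh)
}

heInit <- function(dims, fanIn) array(rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)

#' Build an (untrained) residual backbone
#'
#' Allocates seeded He-initialized weights for the architecture described
#' by `config` at the given input length.
#'
#' @param inputLen spectrum length in points.
#' @param config a [resnetConfig()].
#' @param seed RNG seed for the weight initialization.
#' @return A `ResnetBackbone` object.
#' @export
buildBackbone <- function(inputLen, config = resnetConfig(), seed = 1L) {
  lay <- resnetLayout(config, inputLen)
  restore <- localRNG(seed)
  on.exit(restore())
  params <- list(); bnState <- list()
  k <- config$kernelSize
  for (i in seq_len(nrow(lay$blocks))) {
    blk <- lay$blocks[i, ]
    pre <- sprintf("s%db%d", blk$stage, blk$block)
    params[[paste0(pre, "c1_W")]] <- heInit(c(k, blk$inCh, blk$outCh),
                                            k * blk$inCh)
    params[[paste0(pre, "c1_b")]] <- numeric(blk$outCh)
    params[[paste0(pre, "c2_W")]] <- heInit(c(k, blk$outCh, blk$outCh),
                                            k * blk$outCh)
    params[[paste0(pre, "c2_b")]] <- numeric(blk$outCh)
    for (j in 1:2) {
      params[[sprintf("%sn%d_g", pre, j)]] <- rep(1, blk$outCh)
      params[[sprintf("%sn%d_be", pre, j)]] <- numeric(blk$outCh)
      bnState[[sprintf("%sn%d", pre, j)]] <-
        list(mean = numeric(blk$outCh), var = rep(1, blk$outCh))
    }
    if (blk$projection) {
      params[[paste0(pre, "p_W")]] <- heInit(c(1L, blk$inCh, blk$outCh),
                                             blk$inCh)
      params[[paste0(pre, "p_b")]] <- numeric(blk$outCh)
      params[[paste0(pre, "pn_g")]] <- rep(1, blk$outCh)
      params[[paste0(pre, "pn_be")]] <- numeric(blk$outCh)
      bnState[[paste0(pre, "pn")]] <-
        list(mean = numeric(blk$outCh), var = rep(1, blk$outCh))
    }
  }
  sizes <- c(lay$flattenDim, config$fcSizes, 1L)
  for (i in seq_len(length(sizes) - 1L)) {
    nm <- if (i == length(sizes) - 1L) "out" else paste0("fc", i)
    params[[paste0(nm, "_W")]] <- heInit(c(sizes[i], sizes[i + 1L]),
                                         sizes[i])
    params[[paste0(nm, "_b")]] <- numeric(sizes[i + 1L])
  }
  mask <- rep(FALSE, lay$nMainConvs)
  names(mask) <- as.vector(t(outer(
    sprintf("s%db%d", lay$blocks$stage, lay$blocks$block),
    c("c1", "c2"), paste0)))
  methods::new("ResnetBackbone", config = unclass(config),
               inputLen = as.integer(inputLen), params = params,
               bnState = bnState, freezeMask = mask,
               history = data.frame(), yCenter = 0, yScale = 1,
               trained = FALSE)
}

#' ResnetBackbone: the 1D residual CNN
#'
#' Holds the architecture configuration, all layer parameters, batch-norm
#' running statistics, the per-main-convolution freeze mask used during
#' fine-tuning, the per-epoch training history, and the label
#' standardization learned at training time.
#'
#' @aliases ResnetBackbone
#' @seealso [buildBackbone()], [trainBackbone()], [fineTune()],
#'   [bottleneckFeatures()]
#' @export
setClass("ResnetBackbone",
         representation(config = "list", inputLen = "integer",
                        params = "list", bnState = "list",
                        freezeMask = "logical", history = "data.frame",
                        yCenter = "numeric", yScale = "numeric",
                        trained = "logical"))

setMethod("show", "ResnetBackbone", function(object) {
  lay <- resnetLayout(object@config, object@inputLen)
  cat("ResnetBackbone:", object@config$nStages, "stages x",
      object@config$blocksPerStage, "basic blocks,",
      lay$nMainConvs, "main convs\n")
  cat("  channels:", paste(object@config$channels, collapse = "/"),
      " kernel:", object@config$kernelSize, "\n")
  cat(sprintf("  input %d -> flatten %d -> FC %s -> 1\n", object@inputLen,
              lay$flattenDim,
              paste(object@config$fcSizes, collapse = "/")))
  cat("  trained:", object@trained, "; frozen convs:",
      sum(object@freezeMask), "\n")
})

# ---- forward / backward over the whole network -------------------------

blockPrefixes <- function(model) {
  lay <- resnetLayout(model@config, model@inputLen)
  list(lay = lay,
       pre = sprintf("s%db%d", lay$blocks$stage, lay$blocks$block))
}

netForward <- function(model, x, train = FALSE) {
  p <- model@params
  st <- model@bnState
  bp <- blockPrefixes(model)
  lay <- bp$lay
  caches <- vector("list", nrow(lay$blocks))
  for (i in seq_len(nrow(lay$blocks))) {
    blk <- lay$blocks[i, ]; pre <- bp$pre[i]
    c1 <- convForward(x, p[[paste0(pre, "c1_W")]], p[[paste0(pre, "c1_b")]],
                      blk$stride)
    n1 <- bnForward(c1$out, p[[paste0(pre, "n1_g")]],
                    p[[paste0(pre, "n1_be")]], st[[paste0(pre, "n1")]],
                    train)
    st[[paste0(pre, "n1")]] <- n1$running
    r1 <- reluForward(n1$out)
    c2 <- convForward(r1$out, p[[paste0(pre, "c2_W")]],
                      p[[paste0(pre, "c2_b")]], 1L)
    n2 <- bnForward(c2$out, p[[paste0(pre, "n2_g")]],
                    p[[paste0(pre, "n2_be")]], st[[paste0(pre, "n2")]],
                    train)
    st[[paste0(pre, "n2")]] <- n2$running
    if (blk$projection) {
      cp <- convForward(x, p[[paste0(pre, "p_W")]], p[[paste0(pre, "p_b")]],
                        blk$stride)
      np <- bnForward(cp$out, p[[paste0(pre, "pn_g")]],
                      p[[paste0(pre, "pn_be")]], st[[paste0(pre, "pn")]],
                      train)
      st[[paste0(pre, "pn")]] <- np$running
      sc <- np$out
      projCache <- list(cp = cp$cache, np = np$cache)
    } else {
      sc <- x
      projCache <- NULL
    }
    r2 <- reluForward(n2$out + sc)
    caches[[i]] <- list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                        c2 = c2$cache, n2 = n2$cache, r2 = r2$cache,
                        proj = projCache)
    x <- r2$out
  }
  n <- dim(x)[1]
  flat <- matrix(x, n, lay$flattenDim)
  h <- flat
  nfc <- length(model@config$fcSizes)
  fcCaches <- vector("list", nfc)
  reluCaches <- vector("list", nfc)
  for (i in seq_len(nfc)) {
    dn <- denseForward(h, p[[sprintf("fc%d_W", i)]], p[[sprintf("fc%d_b", i)]])
    rl <- reluForward(dn$out)
    fcCaches[[i]] <- dn$cache; reluCaches[[i]] <- rl$cache
    h <- rl$out
  }
  outL <- denseForward(h, p[["out_W"]], p[["out_b"]])
  list(pred = drop(outL$out), flat = flat, bnState = st,
       cache = list(blocks = caches, fc = fcCaches, relu = reluCaches,
                    outc = outL$cache, lay = lay, pre = bp$pre,
                    flatDims = dim(x)))
}

netBackward <- function(model, cache, dpred) {
  p <- model@params
  grads <- list()
  dout <- matrix(dpred, ncol = 1)
  bo <- denseBackward(dout, cache$outc)
  grads[["out_W"]] <- bo$dW; grads[["out_b"]] <- bo$db
  dh <- bo$dx
  for (i in rev(seq_along(cache$fc))) {
    dh <- reluBackward(dh, cache$relu[[i]])
    bd <- denseBackward(dh, cache$fc[[i]])
    grads[[sprintf("fc%d_W", i)]] <- bd$dW
    grads[[sprintf("fc%d_b", i)]] <- bd$db
    dh <- bd$dx
  }
  dx <- array(dh, cache$flatDims)
  for (i in rev(seq_len(nrow(cache$lay$blocks)))) {
    blk <- cache$lay$blocks[i, ]; pre <- cache$pre[i]
    cc <- cache$blocks[[i]]
    dsum <- reluBackward(dx, cc$r2)
    b2 <- bnBackward(dsum, cc$n2)
    grads[[paste0(pre, "n2_g")]] <- b2$dgamma
    grads[[paste0(pre, "n2_be")]] <- b2$dbeta
    bc2 <- convBackward(b2$dx, cc$c2)
    grads[[paste0(pre, "c2_W")]] <- bc2$dW
    grads[[paste0(pre, "c2_b")]] <- bc2$db
    dr1 <- reluBackward(bc2$dx, cc$r1)
    b1 <- bnBackward(dr1, cc$n1)
    grads[[paste0(pre, "n1_g")]] <- b1$dgamma
    grads[[paste0(pre, "n1_be")]] <- b1$dbeta
    bc1 <- convBackward(b1$dx, cc$c1)
    grads[[paste0(pre, "c1_W")]] <- bc1$dW
    grads[[paste0(pre, "c1_b")]] <- bc1$db
    if (blk$projection) {
      bp2 <- bnBackward(dsum, cc$proj$np)
      grads[[paste0(pre, "pn_g")]] <- bp2$dgamma
      grads[[paste0(pre, "pn_be")]] <- bp2$dbeta
      bcp <- convBackward(bp2$dx, cc$proj$cp)
      grads[[paste0(pre, "p_W")]] <- bcp$dW
      grads[[paste0(pre, "p_b")]] <- bcp$db
      dsc <- bcp$dx
    } else {
      dsc <- dsum
    }
    dx <- bc1$dx + dsc
  }
  grads
}

# Parameter names excluded from gradient updates under the freeze mask:
# frozen main convolutions, plus a block's projection convolution when both
# of its main convolutions are frozen.
frozenParamNames <- function(model) {
  mask <- model@freezeMask
  if (!any(mask)) return(character())
  nms <- names(mask)[mask]
  out <- c(paste0(nms, "_W"), paste0(nms, "_b"))
  blocks <- unique(sub("c[12]$", "", names(mask)))
  for (b in blocks) {
    if (all(mask[paste0(b, c("c1", "c2"))]) &&
        !is.null(model@params[[paste0(b, "p_W")]]))
      out <- c(out, paste0(b, "p_W"), paste0(b, "p_b"))
  }
  out
}

asInputArray <- function(x, inputLen) {
  if (methods::is(x, "SpectraSet")) x <- absorbance(x)
  x <- as.matrix(x)
  if (ncol(x) != inputLen)
    stop("input has ", ncol(x), " points; the backbone expects ", inputLen)
  array(x, c(nrow(x), ncol(x), 1L))
}

#' Train the backbone by Adam on MSE loss
#'
#' Labels are standardized internally (the inverse transform is stored on
#' the model and applied by `predict`). Runs are fully reproducible under
#' a fixed seed. Parameters named in the freeze mask receive no updates.
#'
#' @param model a `ResnetBackbone`.
#' @param x a [SpectraSet] (preprocessed spectra) or samples x wavelengths
#'   matrix.
#' @param y labels; taken from `x` when it is a `SpectraSet`.
#' @param tc a [trainConfig()].
#' @return The trained `ResnetBackbone` (with `@history` filled).
#' @export
trainBackbone <- function(model, x, y = NULL, tc = trainConfig()) {
  if (methods::is(x, "SpectraSet") && is.null(y)) y <- density(x)
  xa <- asInputArray(x, model@inputLen)
  n <- dim(xa)[1]
  stopifnot(length(y) == n)
  model@yCenter <- mean(y)
  model@yScale <- if (sd(y) > 0) sd(y) else 1
  ys <- (y - model@yCenter) / model@yScale

  restore <- localRNG(tc$seed)
  on.exit(restore())

  valIdx <- integer()
  if (tc$valFraction > 0) {
    nVal <- max(1L, round(tc$valFraction * n))
    valIdx <- sample(n, nVal)
  }
  trIdx <- setdiff(seq_len(n), valIdx)

  params <- model@params
  frozen <- frozenParamNames(model)
  mAdam <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  vAdam <- mAdam
  lr <- tc$lr
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; step <- 0L
  best <- Inf; sinceBest <- 0L; sinceLr <- 0L
  hist <- vector("list", tc$maxEpochs)

  for (epoch in seq_len(tc$maxEpochs)) {
    ord <- sample(trIdx)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batchSize))
    epochLoss <- 0
    for (bidx in batches) {
      xb <- xa[bidx, , , drop = FALSE]
      yb <- ys[bidx]
      fw <- netForward(model, xb, train = TRUE)
      model@bnState <- fw$bnState
      res <- fw$pred - yb
      loss <- mean(res^2)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; reduce the learning rate")
      epochLoss <- epochLoss + loss * length(bidx)
      grads <- netBackward(model, fw$cache, 2 * res / length(bidx))
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(grads)) {
        if (nm %in% frozen) next
        g <- grads[[nm]]
        mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
        vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g * g
        params[[nm]] <- params[[nm]] -
          lr * corr * mAdam[[nm]] / (sqrt(vAdam[[nm]]) + epsA)
      }
      model@params <- params
    }
    trainLoss <- epochLoss / length(trIdx)
    monitored <- trainLoss
    valLoss <- NA_real_
    if (length(valIdx)) {
      fv <- netForward(model, xa[valIdx, , , drop = FALSE], train = FALSE)
      valLoss <- mean((fv$pred - ys[valIdx])^2)
      monitored <- valLoss
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss = trainLoss,
                                valLoss = valLoss, lr = lr)
    if (monitored < best - 1e-12) {
      best <- monitored; sinceBest <- 0L; sinceLr <- 0L
    } else {
      sinceBest <- sinceBest + 1L; sinceLr <- sinceLr + 1L
    }
    if (sinceLr >= tc$lrPatience) {
      lr <- lr * tc$lrReduceFactor
      sinceLr <- 0L
    }
    if (sinceBest >= tc$earlyStopPatience) break
  }
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model@trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fine-tune a backbone on target-condition data
#'
#' Initializes every layer from the source-trained model, freezes the
#' first `nFrozenConv` main-path convolutions (forward order; a block's
#' projection shortcut convolution is frozen when both of its main
#' convolutions are), and trains the remaining layers on the target data.
#'
#' @param model a source-trained `ResnetBackbone` (its weights are the
#'   starting point).
#' @param x,y target-condition training data (as in [trainBackbone()]).
#' @param nFrozenConv how many leading main convolutions to freeze
#'   (default 10).
#' @param tc a [trainConfig()].
#' @return The fine-tuned `ResnetBackbone`.
#' @export
fineTune <- function(model, x, y = NULL, nFrozenConv = 10L,
                     tc = trainConfig()) {
  total <- length(model@freezeMask)
  if (nFrozenConv < 0L || nFrozenConv > total)
    stop("nFrozenConv must be in 0..", total)
  model@freezeMask[] <- seq_len(total) <= nFrozenConv
  trainBackbone(model, x, y, tc)
}

#' Bottleneck features at the flatten layer
#'
#' Deterministic inference-mode forward pass through the residual stages;
#' the activations at the flatten layer (before the first FC layer) are
#' the features handed to the downstream SVR.
#'
#' @param model a trained `ResnetBackbone`.
#' @param x [SpectraSet] or samples x wavelengths matrix on the model's
#'   input length.
#' @return A samples x flattenDim numeric matrix.
#' @export
bottleneckFeatures <- function(model, x) {
  xa <- asInputArray(x, model@inputLen)
  netForward(model, xa, train = FALSE)$flat
}

#' Predict labels with the backbone's own regression head
#' @param object a trained `ResnetBackbone`.
#' @param x [SpectraSet] or matrix of spectra.
#' @param ... ignored.
#' @return Numeric vector of predictions on the label scale.
#' @export
setMethod("predict", "ResnetBackbone", function(object, x, ...) {
  xa <- asInputArray(x, object@inputLen)
  object@yCenter + object@yScale * netForward(object, xa, FALSE)$pred
})

#' Per-epoch training history
#' @param model a trained `ResnetBackbone`.
#' @return data.frame with epoch, loss, valLoss, lr.
#' @export
trainingHistory <- function(model) model@history

#' The freeze mask over main convolutions
#' @param model a `ResnetBackbone`.
#' @return Named logical vector in forward order.
#' @export
freezeMask <- function(model) model@freezeMask
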