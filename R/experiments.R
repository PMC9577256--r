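# Experiment protocols: the target-calibration-size sweep, the
# method-by-method comparison on both domains, and the inner-iteration
# sweep of the boosting transfer. All runners take raw SpectraSets,
# preprocess (SGS + SNV), split by SPXY, and emit tidy data.frames.

METHODS_ALL <- c("PLSR", "SVR", "PLSR+SBC", "PLSR+PDS", "SVR+PDS",
                 "Resnet1D-TL", "Resnet1D-SVR",
                 "Resnet1D-SVR-TrAdaBoost.R2")

#' Settings shared by the experiment runners
#'
#' @param resnet backbone architecture, a [resnetConfig()] (default: the
#'   small test profile).
#' @param train a [trainConfig()] for backbone training/fine-tuning.
#' @param nFrozenConv main convolutions frozen during fine-tuning; NULL
#'   (default) freezes the leading 10/16 of the main convolutions, the
#'   same proportion as freezing 10 of the full architecture's 16.
#' @param transfer a [transferConfig()] for the boosting transfer.
#' @param svr an [svrParams()] used by every SVR-based method; NULL
#'   (default) picks gamma by the median-distance heuristic
#'   ([svrParamsAuto()]) on the source-domain calibration data.
#' @param pso optional [psoConfig()]; when given, SVR hyperparameters are
#'   tuned once per repeat on the source-domain calibration features.
#' @param pdsHalfWidth PDS window half-width in points.
#' @param sgWindow Savitzky-Golay window for preprocessing.
#' @return A list of class `experimentConfig`.
#' @export
experimentConfig <- function(resnet = resnetTestProfile(),
                             train = trainConfig(maxEpochs = 60L,
                                                 lrPatience = 5L,
                                                 earlyStopPatience = 12L),
                             nFrozenConv = NULL,
                             transfer = transferConfig(K = 5L, N = 20L,
                                                       F = 5L),
                             svr = NULL,
                             pso = NULL,
                             pdsHalfWidth = 5L,
                             sgWindow = 21L) {
  structure(list(resnet = resnet, train = train,
                 nFrozenConv = nFrozenConv, transfer = transfer,
                 svr = svr, pso = pso, pdsHalfWidth = pdsHalfWidth,
                 sgWindow = sgWindow),
            class = "experimentConfig")
}

defaultFrozen <- function(cfg, inputLen) {
  if (!is.null(cfg$nFrozenConv)) return(cfg$nFrozenConv)
  total <- resnetLayout(cfg$resnet, inputLen)$nMainConvs
  round(10 / 16 * total)
}

withSeed <- function(tc, seed) { tc$seed <- as.integer(seed); tc }

# Preprocess and SPXY-split one domain: a fixed-size prediction set and a
# calibration pool holding the remainder.
prepareDomain <- function(x, predSize, sgWindow) {
  xp <- preprocessSpectra(x, sgWindow = sgWindow)
  sp <- spxySplit(xp, nCal = ncol(xp) - predSize)
  list(full = xp, cal = selectSamples(xp, sp$calIdx),
       pred = selectSamples(xp, sp$predIdx))
}

# SPXY-select M calibration samples from a pool.
selectCal <- function(pool, M) {
  if (M >= ncol(pool)) stop("M must be below the calibration pool size")
  selectSamples(pool, spxySplit(pool, nCal = M)$calIdx)
}

pairedSourceSpectra <- function(sourceFull, targetSet) {
  ids <- intersect(sampleIds(targetSet), sampleIds(sourceFull))
  if (length(ids) < 2L)
    stop("PDS needs paired standards: no shared sample ids between domains")
  list(master = absorbance(selectSamples(sourceFull, ids)),
       slave = absorbance(selectSamples(targetSet, ids)),
       y = density(selectSamples(targetSet, ids)))
}

evalRow <- function(yTrue, yPred, ...) {
  m <- regressionMetrics(yTrue, yPred)
  data.frame(..., r2 = m$r2, rmse = m$rmse, mae = m$mae)
}

# Fit every requested method once and return a list of prediction
# closures keyed by method; ctx carries the prepared data and models.
fitMethods <- function(methods, ctx, cfg) {
  Xcal <- absorbance(ctx$targetCal); ycal <- density(ctx$targetCal)
  XcalS <- absorbance(ctx$sourceCal); ycalS <- density(ctx$sourceCal)
  # each method gets its own frame so fitted objects captured by the
  # returned closures cannot clobber one another
  fitOne <- function(mth) {
    switch(
      mth,
      "PLSR" = {
        a <- plsrSelectNcomp(Xcal, ycal, ncompMax = 15L, folds = 5L,
                             seed = ctx$seed)
        fitT <- plsrFit(Xcal, ycal, a)
        aS <- plsrSelectNcomp(XcalS, ycalS, ncompMax = 15L, folds = 5L,
                              seed = ctx$seed)
        fitS <- plsrFit(XcalS, ycalS, aS)
        function(x, domain)
          plsrPredict(if (domain == "source") fitS else fitT, absorbance(x))
      },
      "SVR" = {
        fitT <- svrFit(Xcal, ycal, ctx$svrSpec)
        fitS <- svrFit(XcalS, ycalS, ctx$svrSpec)
        function(x, domain)
          predict(if (domain == "source") fitS else fitT, absorbance(x))
      },
      "PLSR+SBC" = {
        a <- plsrSelectNcomp(XcalS, ycalS, ncompMax = 15L, folds = 5L,
                             seed = ctx$seed)
        master <- plsrFit(XcalS, ycalS, a)
        sbc <- sbcFit(ycal, plsrPredict(master, Xcal))
        function(x, domain) {
          p <- plsrPredict(master, absorbance(x))
          if (domain == "source") p else sbcApply(sbc, p)
        }
      },
      "PLSR+PDS" = {
        a <- plsrSelectNcomp(XcalS, ycalS, ncompMax = 15L, folds = 5L,
                             seed = ctx$seed)
        master <- plsrFit(XcalS, ycalS, a)
        std <- pairedSourceSpectra(ctx$sourceFull, ctx$targetCal)
        tf <- pdsFit(std$master, std$slave, cfg$pdsHalfWidth)
        function(x, domain) {
          Xq <- absorbance(x)
          if (domain != "source") Xq <- pdsApply(tf, Xq)
          plsrPredict(master, Xq)
        }
      },
      "SVR+PDS" = {
        master <- svrFit(XcalS, ycalS, ctx$svrSpec)
        std <- pairedSourceSpectra(ctx$sourceFull, ctx$targetCal)
        tf <- pdsFit(std$master, std$slave, cfg$pdsHalfWidth)
        function(x, domain) {
          Xq <- absorbance(x)
          if (domain != "source") Xq <- pdsApply(tf, Xq)
          predict(master, Xq)
        }
      },
      "Resnet1D-TL" = {
        ft <- ctx$fineTuned
        src <- ctx$sourceModel
        function(x, domain)
          predict(if (domain == "source") src else ft, x)
      },
      "Resnet1D-SVR" = {
        fit <- svrFit(ctx$featTargetCal, ycal, ctx$svrFeat)
        fitS <- svrFit(ctx$featSourceCal, ycalS, ctx$svrFeat)
        function(x, domain) {
          if (domain == "source")
            predict(fitS, bottleneckFeatures(ctx$sourceModel, x))
          else predict(fit, bottleneckFeatures(ctx$fineTuned, x))
        }
      },
      "Resnet1D-SVR-TrAdaBoost.R2" = {
        tm <- fitTwoStage(ctx$featSourceCal, ycalS,
                          ctx$featTargetCal, ycal,
                          ctx$transferCfg, ctx$svrFeat)
        function(x, domain)
          predict(tm, bottleneckFeatures(
            if (domain == "source") ctx$sourceModel else ctx$fineTuned, x))
      },
      stop("unknown method: ", mth))
  }
  out <- list()
  for (mth in methods) out[[mth]] <- fitOne(mth)
  out
}

needsBackbone <- function(methods)
  any(methods %in% c("Resnet1D-TL", "Resnet1D-SVR",
                     "Resnet1D-SVR-TrAdaBoost.R2"))

buildContext <- function(src, tgt, targetCal, cfg, seed) {
  spec <- if (is.null(cfg$svr)) svrParamsAuto(absorbance(src$cal))
          else cfg$svr
  ctx <- list(sourceFull = src$full, sourceCal = src$cal,
              targetCal = targetCal, seed = seed,
              svrSpec = spec, svrFeat = spec,
              transferCfg = cfg$transfer)
  ctx$transferCfg$seed <- seed
  ctx
}

addBackbone <- function(ctx, methods, cfg, seed, sourceModel = NULL) {
  if (!needsBackbone(methods)) return(ctx)
  inputLen <- length(wavelengths(ctx$sourceCal))
  if (is.null(sourceModel)) {
    sourceModel <- buildBackbone(inputLen, cfg$resnet, seed = seed)
    sourceModel <- trainBackbone(sourceModel, ctx$sourceCal,
                                 tc = withSeed(cfg$train, seed))
  }
  ctx$sourceModel <- sourceModel
  ctx$fineTuned <- fineTune(sourceModel, ctx$targetCal,
                            nFrozenConv = defaultFrozen(cfg, inputLen),
                            tc = withSeed(cfg$train, seed + 1L))
  # each domain's features come from its own extractor; the frozen lower
  # convolutions keep the two flatten spaces aligned
  ctx$featSourceCal <- bottleneckFeatures(ctx$sourceModel, ctx$sourceCal)
  ctx$featTargetCal <- bottleneckFeatures(ctx$fineTuned, ctx$targetCal)
  if (!is.null(cfg$pso)) {
    ps <- cfg$pso; ps$seed <- seed
    ctx$svrFeat <- psoOptimize(ctx$featSourceCal,
                               density(ctx$sourceCal), ps)
  } else if (is.null(cfg$svr)) {
    ctx$svrFeat <- svrParamsAuto(ctx$featSourceCal)
  }
  ctx
}

#' Sweep the target-domain calibration size
#'
#' For every requested calibration size M and method: SPXY-select M
#' target calibration samples from the target calibration pool, fit, and
#' evaluate R2/RMSE/MAE on the fixed held-out target prediction set.
#' Repeats differ in the stochastic model components (network
#' initialization and shuffling, CV fold draws); preprocessing and SPXY
#' selection are deterministic.
#'
#' @param source,target raw [SpectraSet]s on one wavelength grid.
#' @param M integer vector of calibration sizes.
#' @param methods subset of the supported method names (see
#'   `spectraTransfer:::METHODS_ALL`).
#' @param predSize held-out prediction-set size per domain (default 30).
#' @param repeats number of repeated runs (default 5).
#' @param seed base seed.
#' @param cfg an [experimentConfig()].
#' @return Tidy data.frame: method, M, repeat, r2, rmse, mae.
#' @export
runMSweep <- function(source, target, M = c(20, 40, 60, 80, 100, 120, 140),
                      methods = METHODS_ALL, predSize = 30L,
                      repeats = 5L, seed = 1L,
                      cfg = experimentConfig()) {
  src <- prepareDomain(source, predSize, cfg$sgWindow)
  tgt <- prepareDomain(target, predSize, cfg$sgWindow)
  rows <- list()
  for (r in seq_len(repeats)) {
    rs <- seed + 1000L * r
    srcModel <- NULL
    for (Mi in M) {
      if (Mi >= ncol(tgt$cal)) {
        warning("M = ", Mi, " >= calibration pool size; skipped")
        next
      }
      targetCal <- selectCal(tgt$cal, Mi)
      ctx <- buildContext(src, tgt, targetCal, cfg, rs)
      ctx <- addBackbone(ctx, methods, cfg, rs, srcModel)
      srcModel <- ctx$sourceModel
      fits <- fitMethods(methods, ctx, cfg)
      for (mth in methods)
        rows[[length(rows) + 1L]] <- evalRow(
          density(tgt$pred), fits[[mth]](tgt$pred, "target"),
          method = mth, M = Mi, rep = r)
    }
  }
  do.call(rbind, rows)
}

#' Compare all methods on both domains
#'
#' Uses the full calibration pools of both domains (the target pool plays
#' the role of the transfer standards / target calibration set) and
#' evaluates every method on the held-out source- and target-domain
#' prediction sets.
#'
#' @inheritParams runMSweep
#' @param residuals if TRUE, attach a per-sample prediction table as
#'   `attr(result, "residuals")` (method, domain, id, yTrue, yPred).
#' @return Tidy data.frame: method, domain, repeat, r2, rmse, mae.
#' @export
runMethodComparison <- function(source, target, methods = METHODS_ALL,
                                predSize = 30L, repeats = 5L, seed = 1L,
                                cfg = experimentConfig(),
                                residuals = FALSE) {
  src <- prepareDomain(source, predSize, cfg$sgWindow)
  tgt <- prepareDomain(target, predSize, cfg$sgWindow)
  rows <- list(); resid <- list()
  for (r in seq_len(repeats)) {
    rs <- seed + 1000L * r
    ctx <- buildContext(src, tgt, tgt$cal, cfg, rs)
    ctx <- addBackbone(ctx, methods, cfg, rs)
    fits <- fitMethods(methods, ctx, cfg)
    for (mth in methods) {
      for (dom in c("source", "target")) {
        ev <- if (dom == "source") src$pred else tgt$pred
        p <- fits[[mth]](ev, dom)
        rows[[length(rows) + 1L]] <- evalRow(density(ev), p,
                                             method = mth, domain = dom,
                                             rep = r)
        if (residuals)
          resid[[length(resid) + 1L]] <- data.frame(
            method = mth, domain = dom, rep = r, id = sampleIds(ev),
            yTrue = density(ev), yPred = p)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (residuals) attr(out, "residuals") <- do.call(rbind, resid)
  out
}

#' Sweep the inner boosting iteration count
#'
#' Runs the full hybrid (backbone fine-tuning + boosting transfer) for
#' every combination of inner iterations N and target calibration size M.
#'
#' @inheritParams runMSweep
#' @param Ns integer vector of inner boosting iteration counts.
#' @return Tidy data.frame: N, M, repeat, r2, rmse, mae.
#' @export
runNSweep <- function(source, target, Ns = c(5, 20, 50, 80), M = 60L,
                      predSize = 30L, repeats = 5L, seed = 1L,
                      cfg = experimentConfig()) {
  src <- prepareDomain(source, predSize, cfg$sgWindow)
  tgt <- prepareDomain(target, predSize, cfg$sgWindow)
  rows <- list()
  for (r in seq_len(repeats)) {
    rs <- seed + 1000L * r
    srcModel <- NULL
    for (Mi in M) {
      targetCal <- selectCal(tgt$cal, Mi)
      ctx <- buildContext(src, tgt, targetCal, cfg, rs)
      ctx <- addBackbone(ctx, "Resnet1D-SVR-TrAdaBoost.R2", cfg, rs,
                         srcModel)
      srcModel <- ctx$sourceModel
      for (N in Ns) {
        tcf <- ctx$transferCfg; tcf$N <- as.integer(N)
        tm <- fitTwoStage(ctx$featSourceCal, density(ctx$sourceCal),
                          ctx$featTargetCal, density(ctx$targetCal),
                          tcf, ctx$svrFeat)
        p <- predict(tm, bottleneckFeatures(ctx$fineTuned, tgt$pred))
        rows[[length(rows) + 1L]] <- evalRow(density(tgt$pred), p,
                                             N = N, M = Mi, rep = r)
      }
    }
  }
  do.call(rbind, rows)
}
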