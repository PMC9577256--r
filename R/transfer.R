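#' Configuration of the two-stage boosting transfer
#'
#' @param K outer steps (>= 2; each outer step fits one candidate
#'   ensemble and then down-weights the source domain along the
#'   [targetWeightFraction()] schedule).
#' @param N inner boosting iterations per ensemble (default 50).
#' @param F cross-validation folds for the per-step target-domain error
#'   (default 10; reduced with a warning when the target set is smaller).
#' @param lossShape adjusted-error shape, see [adjustedError()].
#' @param strictTwoStage if TRUE (default) the inner boost holds source
#'   weights fixed and re-weights only target instances; if FALSE the
#'   inner boost updates all instance weights (plain pooled AdaBoost.R2).
#' @param cvLoss `"rmse"` (default) or `"mse"` for the per-step CV error.
#' @param forceBeta if non-NULL, overrides the stage-1 binary-searched
#'   beta (useful to switch the source down-weighting off with
#'   `forceBeta = 1`).
#' @param seed RNG seed (CV fold assignment).
#' @return A list of class `transferConfig`.
#' @export
transferConfig <- function(K = 10L, N = 50L, F = 10L,
                           lossShape = "linear", strictTwoStage = TRUE,
                           cvLoss = c("rmse", "mse"), forceBeta = NULL,
                           seed = 1L) {
  stopifnot(K >= 2L, N >= 1L, F >= 2L)
  structure(list(K = as.integer(K), N = as.integer(N), F = as.integer(F),
                 lossShape = lossShape, strictTwoStage = strictTwoStage,
                 cvLoss = match.arg(cvLoss), forceBeta = forceBeta,
                 seed = as.integer(seed)),
            class = "transferConfig")
}

#' TransferModel: fitted two-stage boosting transfer
#'
#' Holds the per-step SVR ensembles, their cross-validated target-domain
#' errors, the selected step index (argmin error, earliest on ties), the
#' boosting trace, and the shared scaled feature matrix the ensembles are
#' defined on.
#'
#' @aliases TransferModel
#' @seealso [fitTwoStage()]
#' @export
setClass("TransferModel",
         representation(ensembles = "list", cvErrors = "numeric",
                        selected = "integer", trace = "data.frame",
                        X = "matrix", center = "numeric",
                        scale = "numeric", params = "list",
                        nSource = "integer", weights = "numeric"))

setMethod("show", "TransferModel", function(object) {
  cat("TransferModel:", length(object@ensembles), "outer steps,",
      object@nSource, "source +",
      nrow(object@X) - object@nSource, "target instances\n")
  cat(sprintf("  selected step %d (CV %s %.4g); members: %d\n",
              object@selected, "error", object@cvErrors[object@selected],
              length(object@ensembles[[object@selected]]$members)))
})

#' Fit the two-stage boosting transfer over bottleneck features
#'
#' Pools `m` source and `n` target instances and runs `K` outer steps.
#' At each step an AdaBoost.R2 ensemble of weighted SVRs is fitted with
#' the current instance weights (source weights held fixed inside the
#' boost under the default strict two-stage behaviour) and its error is
#' estimated by F-fold cross-validation on the target instances only.
#' Between steps, a single weighted SVR provides adjusted errors and the
#' source weights are down-weighted by the binary-searched beta of
#' [stage1Update()] so that the summed target weight follows the
#' [targetWeightFraction()] schedule. The returned model predicts with
#' the ensemble of the step minimizing the CV error.
#'
#' @param sourceFeats,ys source-domain features and labels.
#' @param targetFeats,yt target-domain features and labels (same feature
#'   dimension).
#' @param cfg a [transferConfig()].
#' @param baseParams an [svrParams()] shared by all base learners.
#' @param scale standardize feature columns (default TRUE).
#' @return A [TransferModel-class].
#' @export
fitTwoStage <- function(sourceFeats, ys, targetFeats, yt,
                        cfg = transferConfig(),
                        baseParams = svrParams(), scale = TRUE) {
  Xs <- as.matrix(sourceFeats); Xt <- as.matrix(targetFeats)
  if (ncol(Xs) != ncol(Xt)) stop("feature dimension mismatch")
  m <- nrow(Xs); n <- nrow(Xt)
  X <- rbind(Xs, Xt); y <- c(ys, yt)
  ctr <- if (scale) colMeans(X) else numeric(ncol(X))
  scl <- if (scale) { s <- apply(X, 2L, sd); s[s == 0] <- 1; s }
         else rep(1, ncol(X))
  Xsc <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Q <- rbfKernel(Xsc, gamma = baseParams$gamma) + 1

  Fused <- cfg$F
  if (n < Fused) {
    warning("target set smaller than F; reducing folds to ", max(2L, n))
    Fused <- max(2L, min(n, Fused))
  }
  fold <- cvFolds(n, Fused, seed = cfg$seed)
  idxT <- m + seq_len(n)
  isFixed <- if (cfg$strictTwoStage) c(rep(TRUE, m), rep(FALSE, n))
             else NULL

  w <- initWeights(m, n)
  ensembles <- vector("list", cfg$K)
  cvErrors <- numeric(cfg$K)
  trace <- vector("list", cfg$K)
  for (t in seq_len(cfg$K)) {
    ensembles[[t]] <- adaboostKernel(
      Q, y, seq_len(m + n), w, cfg$N, baseParams$C, baseParams$epsilon,
      cfg$lossShape, isFixed, warn = FALSE)
    # cross-validated error on the target instances only
    predT <- numeric(n)
    for (f in seq_len(Fused)) {
      hold <- idxT[fold == f]
      tr <- setdiff(seq_len(m + n), hold)
      wf <- w[tr] / sum(w[tr])
      ensF <- adaboostKernel(Q, y, tr, wf, cfg$N, baseParams$C,
                             baseParams$epsilon, cfg$lossShape,
                             if (is.null(isFixed)) NULL else isFixed[tr],
                             warn = FALSE)
      predT[fold == f] <- predictEnsembleKernel(
        ensF, Q[hold, , drop = FALSE])
    }
    errT <- if (cfg$cvLoss == "rmse") sqrt(mean((yt - predT)^2))
            else mean((yt - predT)^2)
    cvErrors[t] <- errT
    beta1 <- NA_real_
    if (t < cfg$K) {
      Cvec <- baseParams$C * w / mean(w[w > 0])
      bfit <- svr_cd_fit(Q, y, Cvec, baseParams$epsilon,
                         1e-6 * max(1, max(abs(y))), 500L,
                         numeric(m + n))
      e <- adjustedError(y - drop(Q %*% bfit), cfg$lossShape)
      want <- targetWeightFraction(m, n, t, cfg$K)
      if (!is.null(cfg$forceBeta)) {
        beta1 <- cfg$forceBeta
        wNew <- c(w[seq_len(m)] * beta1^e[seq_len(m)], w[idxT])
        w <- wNew / sum(wNew)
      } else {
        up <- stage1Update(w, e[seq_len(m)], want, nSource = m)
        w <- up$w; beta1 <- up$beta
      }
    }
    trace[[t]] <- data.frame(step = t, cvError = errT, beta = beta1,
                             targetFraction = sum(w[idxT]),
                             members = length(ensembles[[t]]$members))
  }
  methods::new("TransferModel", ensembles = ensembles,
               cvErrors = cvErrors,
               selected = which.min(cvErrors)[1],
               trace = do.call(rbind, trace), X = Xsc, center = ctr,
               scale = scl, params = unclass(baseParams),
               nSource = as.integer(m), weights = w)
}

#' Predict with a fitted transfer model
#' @param object a [TransferModel-class].
#' @param features new samples x features matrix.
#' @param ... ignored.
#' @return Numeric vector: weighted-median ensemble predictions of the
#'   selected step.
#' @export
setMethod("predict", "TransferModel", function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != ncol(object@X)) stop("feature dimension mismatch")
  Xs <- sweep(sweep(X, 2L, object@center), 2L, object@scale, "/")
  Qc <- rbfKernel(Xs, object@X, object@params$gamma) + 1
  predictEnsembleKernel(object@ensembles[[object@selected]], Qc)
})

#' Boosting trace of a transfer fit
#' @param model a [TransferModel-class].
#' @return data.frame: step, cvError, beta, targetFraction, members.
#' @export
transferTrace <- function(model) model@trace
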