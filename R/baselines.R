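#' Slope/bias correction (SBC)
#'
#' Ordinary least squares of the reference values on the master model's
#' predictions for a set of transfer standards; the correction
#' `slope * pred + bias` is exact whenever the true relation is affine.
#'
#' @param yRef reference values of the standards.
#' @param yPredMaster master-model predictions for the same standards
#'   (>= 2, not constant).
#' @return A list with `slope` and `bias`.
#' @export
sbcFit <- function(yRef, yPredMaster) {
  stopifnot(length(yRef) == length(yPredMaster), length(yRef) >= 2L)
  if (sd(yPredMaster) == 0)
    stop("master predictions are constant; SBC undefined")
  slope <- cov(yRef, yPredMaster) / var(yPredMaster)
  list(slope = slope, bias = mean(yRef) - slope * mean(yPredMaster))
}

#' @rdname sbcFit
#' @param sbc a list from `sbcFit`.
#' @param yPred predictions to correct.
#' @return Corrected predictions.
#' @export
sbcApply <- function(sbc, yPred) sbc$slope * yPred + sbc$bias

#' Piecewise direct standardization (PDS)
#'
#' For each wavelength j, the master absorbance at j is regressed (ridge,
#' small penalty for stability at narrow windows) on the slave absorbance
#' over the window `[j - halfWidth, j + halfWidth]` (clipped at the
#' edges), using paired transfer standards measured in both domains. The
#' assembled banded transform maps slave spectra into master space.
#'
#' @param master,slave paired standards, samples x wavelengths matrices on
#'   the same grid (same row = same physical sample).
#' @param halfWidth window half-width in points (default 5).
#' @param lambda relative ridge penalty (default 1e-6, scaled by the
#'   mean diagonal of the window's cross-product matrix).
#' @return An object of class `pdsTransform`.
#' @export
pdsFit <- function(master, slave, halfWidth = 5L, lambda = 1e-6) {
  master <- as.matrix(master); slave <- as.matrix(slave)
  if (!all(dim(master) == dim(slave)))
    stop("master and slave standards must be paired on one grid")
  p <- ncol(master)
  coefs <- vector("list", p)
  windows <- vector("list", p)
  intercepts <- numeric(p)
  for (j in seq_len(p)) {
    win <- max(1L, j - halfWidth):min(p, j + halfWidth)
    Z <- slave[, win, drop = FALSE]
    zc <- colMeans(Z); yc <- mean(master[, j])
    Zc <- sweep(Z, 2L, zc)
    G <- crossprod(Zc)
    A <- G + diag(lambda * max(mean(diag(G)), 1e-300), length(win))
    b <- solve(A, crossprod(Zc, master[, j] - yc))
    coefs[[j]] <- drop(b)
    windows[[j]] <- win
    intercepts[j] <- yc - sum(zc * b)
  }
  structure(list(coefs = coefs, windows = windows,
                 intercepts = intercepts, p = p, halfWidth = halfWidth),
            class = "pdsTransform")
}

#' @rdname pdsFit
#' @param tf a `pdsTransform`.
#' @param spectra slave-domain spectra to map into master space.
#' @return Transformed samples x wavelengths matrix.
#' @export
pdsApply <- function(tf, spectra) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != tf$p) stop("wrong number of wavelengths")
  out <- matrix(0, nrow(spectra), tf$p)
  for (j in seq_len(tf$p))
    out[, j] <- tf$intercepts[j] +
      spectra[, tf$windows[[j]], drop = FALSE] %*% tf$coefs[[j]]
  dimnames(out) <- dimnames(spectra)
  out
}
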