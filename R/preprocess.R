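#' Savitzky-Golay smoothing of spectra
#'
#' Smooths each spectrum by local least-squares polynomial fitting over a
#' sliding window (the standard noise-suppression step for Vis-NIR spectra;
#' a 21-point window is the package default throughout). Edges are handled
#' by polynomial fits over the trailing windows, so the output keeps the
#' input shape and any row that is itself a polynomial of degree <=
#' `polyorder` is reproduced exactly.
#'
#' @param spectra numeric matrix, samples x wavelengths (or a [SpectraSet]).
#' @param window odd integer window width in points (default 21).
#' @param polyorder polynomial order, < `window` (default 2).
#' @return Smoothed matrix of the same shape (or a [SpectraSet]).
#' @export
savitzkyGolay <- function(spectra, window = 21L, polyorder = 2L) {
  if (methods::is(spectra, "SpectraSet")) {
    out <- spectra
    SummarizedExperiment::assay(out, "absorbance") <-
      t(savitzkyGolay(absorbance(spectra), window, polyorder))
    return(out)
  }
  spectra <- as.matrix(spectra)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (ncol(spectra) < window)
    stop("spectra have fewer points than the window")
  out <- t(apply(spectra, 1L, signal::sgolayfilt,
                 p = polyorder, n = window))
  dimnames(out) <- dimnames(spectra)
  out
}

#' Standard normal variate (SNV) correction
#'
#' Centers every spectrum by its own mean and scales by its own sample
#' standard deviation (divisor n-1), removing additive baseline and
#' multiplicative scatter effects per spectrum. Idempotent.
#'
#' @param spectra numeric matrix, samples x wavelengths (or a [SpectraSet]).
#' @return Matrix of row-standardized spectra (or a [SpectraSet]).
#' @export
snv <- function(spectra) {
  if (methods::is(spectra, "SpectraSet")) {
    out <- spectra
    SummarizedExperiment::assay(out, "absorbance") <-
      t(snv(absorbance(spectra)))
    return(out)
  }
  spectra <- as.matrix(spectra)
  mu <- rowMeans(spectra)
  s <- apply(spectra, 1L, sd)
  if (any(s == 0)) {
    bad <- which(s == 0)[1]
    stop("constant spectrum in row ", bad, "; SNV undefined")
  }
  out <- (spectra - mu) / s
  dimnames(out) <- dimnames(spectra)
  out
}

#' Apply the standard preprocessing chain
#'
#' Runs the configured steps in order; the default chain is Savitzky-Golay
#' smoothing followed by SNV.
#'
#' @param x a [SpectraSet] or a samples x wavelengths matrix.
#' @param steps character vector drawn from `c("SGS", "SNV")`, applied in
#'   order.
#' @param sgWindow,sgPolyorder Savitzky-Golay settings.
#' @return Same type as `x`.
#' @export
preprocessSpectra <- function(x, steps = c("SGS", "SNV"),
                              sgWindow = 21L, sgPolyorder = 2L) {
  if (!all(steps %in% c("SGS", "SNV")))
    stop("steps must be drawn from 'SGS', 'SNV'")
  for (s in steps) {
    x <- if (s == "SGS") savitzkyGolay(x, sgWindow, sgPolyorder) else snv(x)
  }
  x
}

#' Synchronous 2D correlation map of wavelengths
#'
#' Entry (j, k) is the Pearson correlation, across samples, between
#' absorbance at wavelength j and at wavelength k — the synchronous
#' two-dimensional correlation diagnostic used to compare spectral
#' redundancy before and after preprocessing. Constant wavelength columns
#' (zero variance) get their row/column set to 0 with a warning; the
#' diagonal is kept at 1.
#'
#' @param spectra numeric matrix, samples x wavelengths (or a [SpectraSet]).
#' @return A symmetric n_wavelengths x n_wavelengths correlation matrix.
#' @export
sync2DCorrelation <- function(spectra) {
  if (methods::is(spectra, "SpectraSet")) spectra <- absorbance(spectra)
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 3L) stop("need at least 3 samples")
  s <- apply(spectra, 2L, sd)
  const <- s == 0
  r <- suppressWarnings(cor(spectra))
  if (any(const)) {
    warning(sum(const), " constant wavelength column(s); correlations set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r
}
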