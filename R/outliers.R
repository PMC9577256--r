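#' Leverage / studentized-residual outlier screen
#'
#' Screens samples before modeling by fitting a PLS1 regression of the
#' reference value on the (preprocessed) spectra and flagging samples that
#' are influential in either space: leverage `h_i` in the latent-score
#' space (with intercept) above `3 * (nLatent + 1) / n`, or externally
#' studentized residual `|t_i|` above the two-sided Student-t quantile at
#' `alpha` with `n - nLatent - 2` degrees of freedom. Either criterion
#' alone flags a distinct pathology (spectral vs label space), so the two
#' are combined by OR.
#'
#' @param spectra samples x wavelengths matrix (or [SpectraSet]; its
#'   density is then used as `y`).
#' @param y reference values (ignored when `spectra` is a `SpectraSet`).
#' @param nLatent PLS components for the screen (default 10).
#' @param alpha two-sided significance level for the t criterion
#'   (default 0.05).
#' @return An [OutlierReport-class] object.
#' @export
flagOutliers <- function(spectra, y = NULL, nLatent = 10L, alpha = 0.05) {
  if (methods::is(spectra, "SpectraSet")) {
    y <- density(spectra)
    ids <- sampleIds(spectra)
    spectra <- absorbance(spectra)
  } else {
    spectra <- as.matrix(spectra)
    ids <- rownames(spectra)
    if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(spectra)))
  }
  n <- nrow(spectra)
  if (n <= nLatent + 1L) stop("need n_samples > nLatent + 1")
  fit <- plsrFit(spectra, y, nLatent)
  a <- fit$ncomp
  Z <- cbind(1, fit$scores)               # intercept + latent scores
  H <- Z %*% solve(crossprod(Z), t(Z))
  h <- pmin(pmax(diag(H), 0), 1)
  res <- y - (drop(fit$scores %*% fit$q) + fit$yMean)
  p <- a + 1L                             # parameters incl. intercept
  dfE <- n - p
  sse <- sum(res^2)
  # externally studentized residuals
  s2i <- pmax((sse - res^2 / pmax(1 - h, 1e-12)) / (dfE - 1L), 1e-300)
  tres <- res / sqrt(s2i * pmax(1 - h, 1e-12))
  hThr <- 3 * p / n
  tCrit <- qt(1 - alpha / 2, df = n - nLatent - 2L)
  flagged <- ids[h > hThr | abs(tres) > tCrit]
  methods::new("OutlierReport", ids = as.character(ids),
               leverage = as.numeric(h), tResidual = as.numeric(tres),
               leverageThreshold = hThr, tCritical = tCrit,
               flaggedIds = as.character(flagged))
}

#' OutlierReport: result of the outlier screen
#'
#' Holds per-sample leverage and externally studentized residuals, the two
#' thresholds, and the flagged sample ids. Convert to a data.frame with
#' [as.data.frame()].
#'
#' @aliases OutlierReport
#' @export
setClass("OutlierReport",
         representation(ids = "character", leverage = "numeric",
                        tResidual = "numeric",
                        leverageThreshold = "numeric",
                        tCritical = "numeric", flaggedIds = "character"))

setMethod("show", "OutlierReport", function(object) {
  cat("OutlierReport:", length(object@ids), "samples,",
      length(object@flaggedIds), "flagged",
      sprintf("(h > %.3f or |t| > %.2f)\n",
              object@leverageThreshold, object@tCritical))
  if (length(object@flaggedIds))
    cat(" ", paste(object@flaggedIds, collapse = ", "), "\n")
})

#' @describeIn OutlierReport-class per-sample table (id, h, t, flagged)
#' @param x an `OutlierReport`.
#' @param ... ignored.
#' @export
as.data.frame.OutlierReport <- function(x, ...) {
  data.frame(id = x@ids, leverage = x@leverage, tResidual = x@tResidual,
             flagged = x@ids %in% x@flaggedIds)
}

#' Flagged ids of an outlier report
#' @param x an `OutlierReport`.
#' @return Character vector of flagged sample ids.
#' @export
flaggedIds <- function(x) x@flaggedIds

#' Merge outlier screens run on parallel sample groups
#'
#' When the same physical samples are measured under several conditions
#' (moisture groups), the screen is run per group and a sample flagged in
#' any group is removed from every group, keeping the groups aligned by
#' id. All reports must cover the same id universe.
#'
#' @param reports a list of [OutlierReport-class] objects.
#' @return Character vector: the union of flagged ids.
#' @export
unionOutliers <- function(reports) {
  stopifnot(length(reports) >= 1L)
  ids <- sort(reports[[1]]@ids)
  for (r in reports)
    if (!identical(sort(r@ids), ids))
      stop("reports cover different sample-id universes")
  sort(unique(unlist(lapply(reports, flaggedIds))))
}
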