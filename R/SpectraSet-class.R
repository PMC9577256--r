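#' @import methods
#' @importFrom stats predict sd cor cov var dist qt rnorm runif median
#'   quantile
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SpectraSet: a set of spectra with a scalar reference value
#'
#' `SpectraSet` is the central data container of the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `"absorbance"`, holding unitless absorbance values with wavelengths in
#' rows and samples in columns. The wavelength grid (nm) is kept in
#' `rowData(x)$wavelength_nm`; the scalar reference value (wood air-dry
#' density, g/cm3) and the acquisition condition tag (moisture content, %)
#' are kept in `colData(x)` as `density` and `moisture`.
#'
#' Validity requires a strictly increasing wavelength grid, matching
#' dimensions, and no missing values in absorbance, density or moisture.
#'
#' @param absorbance numeric matrix, samples x wavelengths (the user-facing
#'   orientation; it is stored transposed internally).
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, length `ncol(absorbance)`.
#' @param density numeric vector of reference values (g/cm3), length
#'   `nrow(absorbance)`.
#' @param moisture numeric scalar or per-sample vector, moisture content in
#'   percent.
#' @param sampleIds optional character vector of sample identifiers;
#'   defaults to `s001, s002, ...`.
#'
#' @return A `SpectraSet` object.
#' @examples
#' x <- SpectraSet(matrix(runif(10), 2, 5), wavelengths = 1:5 * 100,
#'                 density = c(0.5, 0.6), moisture = 10)
#' density(x)
#' @export
#' @aliases SpectraSet-class
#' @rdname SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

#' @export
#' @rdname SpectraSet
SpectraSet <- function(absorbance, wavelengths, density, moisture,
                       sampleIds = NULL) {
  absorbance <- as.matrix(absorbance)
  n <- nrow(absorbance)
  if (is.null(sampleIds))
    sampleIds <- sprintf("s%03d", seq_len(n))
  if (length(moisture) == 1L) moisture <- rep(moisture, n)
  a <- t(absorbance)                       # wavelengths x samples
  dimnames(a) <- list(NULL, as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = a),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = S4Vectors::DataFrame(density = as.numeric(density),
                                   moisture = as.numeric(moisture),
                                   row.names = as.character(sampleIds)))
  methods::new("SpectraSet", se)
}

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl))
    msg <- c(msg, "rowData column 'wavelength_nm' is required")
  else if (any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("density", "moisture") %in% colnames(cd)))
    msg <- c(msg, "colData columns 'density' and 'moisture' are required")
  if (length(msg) == 0L) {
    a <- SummarizedExperiment::assay(object, "absorbance")
    if (anyNA(a) || anyNA(cd$density) || anyNA(cd$moisture))
      msg <- c(msg, "missing values are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for SpectraSet
#'
#' `absorbance()` returns the samples x wavelengths absorbance matrix,
#' `wavelengths()` the wavelength grid (nm), `density()` the reference
#' values (g/cm3), `moisture()` the per-sample moisture tags (%), and
#' `sampleIds()` the sample identifiers.
#'
#' @param x a `SpectraSet`.
#' @return A matrix (`absorbance`) or numeric/character vector.
#' @examples
#' x <- SpectraSet(matrix(runif(10), 2, 5), 1:5 * 100, c(0.5, 0.6), 10)
#' dim(absorbance(x))
#' @export
#' @rdname SpectraSet-accessors
absorbance <- function(x) t(SummarizedExperiment::assay(x, "absorbance"))

#' @export
#' @rdname SpectraSet-accessors
wavelengths <- function(x) SummarizedExperiment::rowData(x)$wavelength_nm

#' @export
#' @rdname SpectraSet-accessors
density <- function(x) unname(SummarizedExperiment::colData(x)$density)

#' @export
#' @rdname SpectraSet-accessors
moisture <- function(x) unname(SummarizedExperiment::colData(x)$moisture)

#' @export
#' @rdname SpectraSet-accessors
sampleIds <- function(x) colnames(x)

#' Subset samples of a SpectraSet
#'
#' @param x a `SpectraSet`.
#' @param i sample indices or ids.
#' @return A `SpectraSet` with the selected samples.
#' @export
selectSamples <- function(x, i) x[, i]

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat("SpectraSet with", ncol(object), "samples,",
      nrow(object), "wavelengths\n")
  cat(sprintf("  grid: %.0f-%.0f nm (%d points)\n",
              min(wl), max(wl), length(wl)))
  d <- density(object)
  cat(sprintf("  density: %.3f-%.3f g/cm3; moisture: %s%%\n",
              min(d), max(d),
              paste(sort(unique(moisture(object))), collapse = "/")))
})
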