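#' Read a spectral dataset from CSV
#'
#' The expected layout is one header row `id,density,moisture,<w1>,<w2>,...`
#' where `<w1>...` are numeric wavelengths in nm (strictly increasing), and
#' one row per sample. This is the format written by [writeSpectra()]; the
#' two functions round-trip exactly.
#'
#' @param path path to a CSV file.
#' @return A [SpectraSet].
#' @seealso [writeSpectra()]
#' @examples
#' f <- system.file("extdata", "synthetic-larch-10pct.csv",
#'                  package = "spectraTransfer")
#' readSpectra(f)
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 4L || tolower(header[1]) != "id")
    stop("expected header 'id,density,moisture,<wavelengths...>'")
  wl <- suppressWarnings(as.numeric(header[-(1:3)]))
  if (anyNA(wl)) stop("non-numeric wavelength column headers")
  if (any(diff(wl) <= 0))
    stop("wavelength headers are not strictly increasing")
  lines <- readLines(path)[-1L]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfield <- 3L + length(wl)
  bad <- which(lengths(parts) != nfield)
  if (length(bad))
    stop("row ", bad[1] + 1L, " has ", lengths(parts)[bad[1]],
         " fields, expected ", nfield)
  m <- do.call(rbind, parts)
  absorb <- matrix(as.numeric(m[, -(1:3), drop = FALSE]),
                   nrow = nrow(m))
  if (anyNA(absorb)) stop("non-numeric absorbance value")
  SpectraSet(absorb, wl,
             density = as.numeric(m[, 2]),
             moisture = as.numeric(m[, 3]),
             sampleIds = m[, 1])
}

#' Write a spectral dataset to CSV
#'
#' @param x a [SpectraSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSpectra()]
#' @export
writeSpectra <- function(x, path) {
  stopifnot(methods::is(x, "SpectraSet"))
  num <- function(v) sprintf("%.17g", v)     # round-trips doubles exactly
  header <- paste(c("id", "density", "moisture", num(wavelengths(x))),
                  collapse = ",")
  a <- absorbance(x)
  rows <- vapply(seq_len(nrow(a)), function(i) {
    paste(c(sampleIds(x)[i], num(density(x)[i]), num(moisture(x)[i]),
            num(a[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
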