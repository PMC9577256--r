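#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on joint X-y distances. The joint distance
#' is `d(i,j) = dX(i,j)/max(dX) + dy(i,j)/max(dy)` with Euclidean distances
#' in spectral and label space. Selection starts from the pair at maximal
#' joint distance, then greedily adds the sample whose minimum joint
#' distance to the already-selected set is largest, until `nCal` samples
#' are selected. Deterministic; ties break to the lowest index, and the
#' selected set for `nCal = k` nests the one for `k - 1`.
#'
#' @param X samples x variables matrix (or a [SpectraSet]; density is then
#'   used as `y`).
#' @param y reference values (ignored for a `SpectraSet`).
#' @param nCal number of calibration samples, `2 <= nCal < n`.
#' @return A list with integer index vectors `calIdx` and `predIdx`
#'   (ascending), partitioning `1..n`.
#' @export
spxySplit <- function(X, y = NULL, nCal) {
  if (methods::is(X, "SpectraSet")) {
    y <- density(X)
    X <- absorbance(X)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (nCal < 2L || nCal >= n) stop("nCal must be in 2..(n-1)")
  dx <- as.matrix(dist(X))
  dy <- as.matrix(dist(y))
  mx <- max(dx); my <- max(dy)
  d <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)
  # initial pair at maximal joint distance (lowest indices on ties)
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1, ])
  minDist <- unname(pmin(d[, sel[1]], d[, sel[2]]))
  while (length(sel) < nCal) {
    minDist[sel] <- -Inf
    nxt <- as.integer(which.max(minDist)) # lowest index on ties
    sel <- c(sel, nxt)
    minDist <- pmin(minDist, unname(d[, nxt]))
  }
  list(calIdx = sort(sel), predIdx = setdiff(seq_len(n), sel))
}
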