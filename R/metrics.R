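#' Regression evaluation metrics
#'
#' Computes the coefficient of determination R2 = 1 - SS_res/SS_tot (with
#' SS_tot taken about the mean of `yTrue` over the evaluated set), the root
#' mean square error, and the mean absolute error. RMSE and MAE carry the
#' units of the label (g/cm3 for density); R2 is unitless. By Jensen's
#' inequality rmse >= mae always holds.
#'
#' @param yTrue numeric vector of reference values.
#' @param yPred numeric vector of predictions, same length.
#' @return A list with elements `r2`, `rmse`, `mae`.
#' @examples
#' regressionMetrics(c(0, 1, 2), c(0, 1, 3))
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have the same length")
  if (length(yTrue) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(yTrue)) || !all(is.finite(yPred)))
    stop("non-finite values in inputs")
  ssTot <- sum((yTrue - mean(yTrue))^2)
  if (ssTot == 0) stop("yTrue is constant; R2 is undefined")
  res <- yTrue - yPred
  list(r2 = 1 - sum(res^2) / ssTot,
       rmse = sqrt(mean(res^2)),
       mae = mean(abs(res)))
}
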