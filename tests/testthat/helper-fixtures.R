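# Small fixtures shared across the suite. Everything is generated in code
# under fixed seeds; nothing is read from disk.

tinySpectra <- function(n = 12, p = 60, seed = 1, moisture = 10) {
  cfg <- synthConfig(nSamples = n, nPoints = p, seed = seed,
                     noiseSd = 0.002)
  synthSpectra(cfg, moisture)
}

# Gaussian features with a linear signal; optional additive label shift
# emulates a domain gap in label space.
featureFixture <- function(n, d = 3, shift = 0, noise = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- X[, 1] + 0.5 * X[, min(2, d)] + shift + noise * rnorm(n)
  list(X = X, y = y)
}

# Exhaustive re-implementation of the SPXY max-min recursion used as an
# independent oracle: at every step, re-evaluate the minimum joint
# distance of every unselected candidate against the whole selected set.
spxyOracle <- function(X, y, nCal) {
  n <- nrow(X)
  dx <- as.matrix(dist(X)); dy <- as.matrix(dist(y))
  d <- dx / max(dx) + (if (max(dy) > 0) dy / max(dy) else dy)
  best <- c(1L, 2L); bv <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (d[i, j] > bv) { bv <- d[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < nCal) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(ci) min(d[ci, sel]), numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sort(sel)
}

# Direct per-window polynomial least squares: the Savitzky-Golay oracle.
sgOracle <- function(x, window, polyorder) {
  p <- length(x); h <- (window - 1) / 2
  out <- numeric(p)
  for (i in seq_len(p)) {
    lo <- max(1, min(i - h, p - window + 1))
    win <- lo:(lo + window - 1)
    fit <- lm(x[win] ~ poly(win, polyorder, raw = TRUE))
    out[i] <- unname(predict(fit, data.frame(win = i)))
  }
  out
}
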