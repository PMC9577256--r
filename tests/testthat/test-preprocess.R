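test_that("Savitzky-Golay reproduces low-order polynomials exactly", {
  x <- seq_len(60)
  const <- matrix(5, 2, 60)
  expect_equal(savitzkyGolay(const, 21, 2), const, tolerance = 1e-10)
  quad <- rbind(1 + 2 * x + 0.05 * x^2, 3 - x + 0.01 * x^2)
  expect_equal(savitzkyGolay(quad, 21, 2), quad, tolerance = 1e-8)
  expect_error(savitzkyGolay(quad, 20, 2), "odd")
  expect_error(savitzkyGolay(quad, 3, 3), "polyorder")
  expect_error(savitzkyGolay(matrix(1, 1, 10), 21, 2), "fewer")
})

test_that("Savitzky-Golay smooths noise and matches a per-window oracle", {
  set.seed(7)
  p <- 80
  noise <- matrix(rnorm(p), 1, p)
  sm <- savitzkyGolay(noise, 21, 2)
  interior <- 11:(p - 10)
  expect_lt(var(sm[1, interior]), var(noise[1, interior]))
  oracle <- sgOracle(noise[1, ], 21, 2)
  expect_equal(sm[1, interior], oracle[interior], tolerance = 1e-6)
})

test_that("SNV standardizes each spectrum and is idempotent", {
  expect_equal(snv(matrix(c(1, 2, 3), 1, 3)), matrix(c(-1, 0, 1), 1, 3))
  set.seed(1)
  X <- matrix(rnorm(5 * 30, mean = 2, sd = 3), 5, 30)
  S <- snv(X)
  expect_equal(rowMeans(S), rep(0, 5), tolerance = 1e-10)
  expect_equal(apply(S, 1, sd), rep(1, 5), tolerance = 1e-10)
  expect_equal(snv(S), S, tolerance = 1e-12)
  expect_error(snv(rbind(X[1, ], rep(2, 30))), "row 2")
})

test_that("synchronous 2D correlation is a correlation matrix", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  X <- cbind(X, 2 * X[, 1] + 1)           # exact affine copy, positive slope
  r <- sync2DCorrelation(X)
  expect_equal(diag(r), rep(1, 4))
  expect_equal(r, t(r))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  expect_equal(r[1, 4], 1)
  expect_error(sync2DCorrelation(X[1:2, ]), "3 samples")
  expect_warning(r2 <- sync2DCorrelation(cbind(X, 7)), "constant")
  expect_equal(r2[5, 1:4], rep(0, 4))
})

test_that("preprocessing strengthens inter-wavelength correlation", {
  # the property under test is noise suppression: raw spectra whose
  # wavelength-to-wavelength structure is masked by measurement noise
  # become strongly collinear after smoothing + row standardization
  # isolated from scatter, which is itself a common mode
  cfg <- synthConfig(nSamples = 25, nPoints = 60, seed = 9, noiseSd = 0.03,
                     scatterMultSd = 0, scatterAddSd = 0)
  x <- synthSpectra(cfg, 10)
  raw <- absorbance(x)
  pp <- absorbance(preprocessSpectra(x))
  offd <- function(r) mean(abs(r[upper.tri(r)]))
  expect_gt(offd(sync2DCorrelation(pp)), offd(sync2DCorrelation(raw)))
})

test_that("outlier screen is quiet on clean data and catches planted ones", {
  flaggedClean <- 0
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(30 * 20), 30, 20)
    y <- X %*% rnorm(20, sd = 0.2) + rnorm(30, sd = 0.01)
    rep <- flagOutliers(X, y, nLatent = 3, alpha = 0.01)
    flaggedClean <- flaggedClean + length(flaggedIds(rep))
    expect_true(all(rep@leverage >= 0 & rep@leverage <= 1))
  }
  expect_lte(flaggedClean / 5, 1)

  set.seed(11)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- drop(X %*% rnorm(20, sd = 0.2)) + rnorm(30, sd = 0.05)
  yb <- y; yb[7] <- y[7] + 10 * sd(y)      # gross label outlier
  expect_true("s007" %in% flaggedIds(flagOutliers(X, yb, nLatent = 3)))
  Xb <- X; Xb[13, ] <- 10 * X[13, ]        # gross spectral outlier
  repX <- flagOutliers(Xb, y, nLatent = 3)
  expect_true("s013" %in% flaggedIds(repX))
  expect_gt(repX@leverage[13], repX@leverageThreshold)

  expect_error(flagOutliers(X[1:4, ], y[1:4], nLatent = 3), "n_samples")
})

test_that("outlier screen is invariant to sample order", {
  set.seed(3)
  X <- matrix(rnorm(25 * 15), 25, 15)
  y <- drop(X %*% rnorm(15, sd = 0.3)) + rnorm(25, sd = 0.05)
  y[5] <- y[5] + 8 * sd(y)
  rownames(X) <- sprintf("id%02d", 1:25)
  r1 <- flagOutliers(X, y, nLatent = 4)
  perm <- sample(25)
  r2 <- flagOutliers(X[perm, ], y[perm], nLatent = 4)
  expect_setequal(flaggedIds(r1), flaggedIds(r2))
})

test_that("outlier reports merge by id union across aligned groups", {
  mk <- function(flag) methods::new("OutlierReport",
    ids = sprintf("s%02d", 1:20), leverage = rep(0.1, 20),
    tResidual = rep(0, 20), leverageThreshold = 0.5, tCritical = 2,
    flaggedIds = flag)
  reps <- list(mk("s01"), mk("s05"), mk(character()), mk("s01"))
  u <- unionOutliers(reps)
  expect_identical(u, c("s01", "s05"))
  expect_identical(unionOutliers(list(mk(character()))), character())
  # removal keeps all groups aligned: 20 ids, 3 distinct flags -> 17 left
  reps2 <- list(mk(c("s01", "s02")), mk("s09"), mk("s01"), mk(character()))
  u2 <- unionOutliers(reps2)
  expect_length(setdiff(sprintf("s%02d", 1:20), u2), 17L)
  bad <- methods::new("OutlierReport", ids = sprintf("x%02d", 1:20),
                      leverage = rep(0.1, 20), tResidual = rep(0, 20),
                      leverageThreshold = 0.5, tCritical = 2,
                      flaggedIds = character())
  expect_error(unionOutliers(list(mk(character()), bad)), "universe")
})
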