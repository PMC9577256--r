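#' Configuration of the synthetic spectra generator
#'
#' Generates Vis-NIR-like absorbance spectra as a sum of Gaussian
#' absorption bands on a smooth drift, with a density label coupled to
#' the band amplitudes, and a moisture-driven domain shift made of a
#' baseline offset, a small band-position shift and band broadening —
#' the same spectra measured at higher moisture keep their overall shape
#' but drift upward and smear. Moisture effects are expressed per percent
#' above the 10% reference condition. The default band centers sit on
#' the visible region and the water/cellulose overtone neighbourhoods
#' (no radiative-transfer realism is claimed).
#'
#' @param nSamples samples per dataset (default 181).
#' @param gridStart,gridStop,nPoints wavelength grid in nm (defaults
#'   350-2500 nm, 2151 points).
#' @param bandCenters,bandWidths,bandAmplitudes Gaussian band parameters
#'   (nm, nm, absorbance).
#' @param densityRange uniform label range in g/cm3 (default 0.4-0.8).
#' @param densityCoupling per-band coefficients linking density to band
#'   amplitude: `amplitude = base + coupling * (density - mid(range))`.
#' @param amplitudeNoiseSd sd of a per-sample, per-band amplitude jitter
#'   uncorrelated with density. It emulates the other constituents that
#'   shape real absorption bands and therefore sets the attainable
#'   prediction accuracy; it is a property of the wood sample, so it is
#'   shared across moisture levels.
#' @param moistureLevels admissible moisture tags in percent.
#' @param baselineOffsetPerMoisture absorbance offset per moisture
#'   percent above 10%.
#' @param waterBandIdx indices (into `bandCenters`) of the water
#'   absorption bands whose amplitude grows with moisture; defaults to
#'   the 1450 and 1940 nm overtone bands of the default band set.
#' @param waterAmpPerMoisture amplitude growth of the water bands per
#'   moisture percent above 10% — the moisture-driven peak-shape change
#'   that survives row standardization and creates the real domain gap.
#' @param peakShiftPerMoisture band-center shift, nm per percent.
#' @param peakBroadenPerMoisture relative band-width growth per percent.
#' @param moistureJitterSd relative sd of each sample's effective
#'   moisture around the nominal level (conditioning a batch of wood to
#'   an exact moisture content is imprecise); the moisture-driven
#'   distortions below use the per-sample effective moisture.
#' @param scatterMultSd sd of the per-sample multiplicative scatter
#'   factor (mean 1); emulates particle-size/scatter effects that SNV is
#'   designed to remove.
#' @param scatterAddSd sd of the per-sample additive scatter offset,
#'   absorbance units.
#' @param noiseSd iid measurement noise sd, absorbance units.
#' @param seed RNG seed; the same seed yields the same wood samples
#'   (density labels) at every moisture level, emulating one sample set
#'   measured repeatedly under different conditions.
#' @return A list of class `synthConfig`.
#' @export
synthConfig <- function(nSamples = 181L,
                        gridStart = 350, gridStop = 2500, nPoints = 2151L,
                        bandCenters = c(680, 1200, 1450, 1790, 1940, 2100,
                                        2270),
                        bandWidths = c(120, 60, 45, 55, 50, 60, 45),
                        bandAmplitudes = c(0.35, 0.25, 0.45, 0.2, 0.5,
                                           0.3, 0.25),
                        densityRange = c(0.4, 0.8),
                        densityCoupling = c(0.3, 0.5, 0.2, 0.45, 0.15,
                                            0.4, 0.5),
                        amplitudeNoiseSd = 0.04,
                        moistureLevels = c(10, 30, 50, 70),
                        baselineOffsetPerMoisture = 0.002,
                        waterBandIdx = c(3L, 5L),
                        waterAmpPerMoisture = 0.005,
                        peakShiftPerMoisture = 0.05,
                        peakBroadenPerMoisture = 0.002,
                        moistureJitterSd = 0.15,
                        scatterMultSd = 0.05,
                        scatterAddSd = 0.02,
                        noiseSd = 0.003,
                        seed = 1L) {
  nb <- length(bandCenters)
  stopifnot(nPoints >= 50L, noiseSd >= 0,
            length(bandWidths) == nb, length(bandAmplitudes) == nb,
            length(densityCoupling) == nb,
            all(waterBandIdx %in% seq_len(nb)),
            !anyDuplicated(moistureLevels))
  structure(list(nSamples = as.integer(nSamples), gridStart = gridStart,
                 gridStop = gridStop, nPoints = as.integer(nPoints),
                 bandCenters = bandCenters, bandWidths = bandWidths,
                 bandAmplitudes = bandAmplitudes,
                 densityRange = densityRange,
                 densityCoupling = densityCoupling,
                 amplitudeNoiseSd = amplitudeNoiseSd,
                 moistureLevels = moistureLevels,
                 baselineOffsetPerMoisture = baselineOffsetPerMoisture,
                 waterBandIdx = as.integer(waterBandIdx),
                 waterAmpPerMoisture = waterAmpPerMoisture,
                 peakShiftPerMoisture = peakShiftPerMoisture,
                 peakBroadenPerMoisture = peakBroadenPerMoisture,
                 moistureJitterSd = moistureJitterSd,
                 scatterMultSd = scatterMultSd,
                 scatterAddSd = scatterAddSd,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "synthConfig")
}

#' Generate a synthetic dataset at one moisture level
#'
#' The density labels depend only on the config seed, so datasets
#' generated at different moisture levels from the same config are paired
#' sample-by-sample (same wood, different measurement condition);
#' measurement noise is drawn independently per moisture level but
#' deterministically given (seed, moisture).
#'
#' @param cfg a [synthConfig()].
#' @param moistureLevel one of `cfg$moistureLevels`.
#' @return A [SpectraSet].
#' @export
synthSpectra <- function(cfg, moistureLevel) {
  li <- match(moistureLevel, cfg$moistureLevels)
  if (is.na(li)) stop("unknown moisture level: ", moistureLevel)
  wl <- seq(cfg$gridStart, cfg$gridStop, length.out = cfg$nPoints)
  n <- cfg$nSamples

  nb <- length(cfg$bandCenters)
  restore <- localRNG(cfg$seed)
  dens <- runif(n, cfg$densityRange[1], cfg$densityRange[2])
  jitter <- matrix(rnorm(n * nb, 0, cfg$amplitudeNoiseSd), n, nb)
  restore()

  # per-sample effective moisture (conditioning is imprecise); drawn from
  # the measurement-event stream so it differs between moisture levels
  restore <- localRNG(cfg$seed + 7919L * li)
  dmNom <- moistureLevel - 10             # shift relative to the 10% ref
  dm <- if (dmNom == 0) rep(0, n)
        else dmNom * (1 + rnorm(n, 0, cfg$moistureJitterSd))
  mult <- rnorm(n, 1, cfg$scatterMultSd)
  add <- rnorm(n, 0, cfg$scatterAddSd)
  noise <- if (cfg$noiseSd > 0)
    matrix(rnorm(n * cfg$nPoints, 0, cfg$noiseSd), n) else 0
  restore()

  offset <- cfg$baselineOffsetPerMoisture * dm
  shift <- cfg$peakShiftPerMoisture * dm
  broaden <- 1 + cfg$peakBroadenPerMoisture * dm
  drift <- 0.1 * (wl - cfg$gridStart) / (cfg$gridStop - cfg$gridStart)

  mid <- mean(cfg$densityRange)
  A <- matrix(0, n, cfg$nPoints)
  for (b in seq_along(cfg$bandCenters)) {
    # per-sample center shift and broadening: build row-wise profiles
    cb <- cfg$bandCenters[b] + shift
    wb <- cfg$bandWidths[b] * broaden
    g <- exp(-sweep(outer(-cb, wl, "+"), 1L, 2 * wb^2, "/") *
               outer(-cb, wl, "+"))
    amp <- cfg$bandAmplitudes[b] + cfg$densityCoupling[b] * (dens - mid) +
      jitter[, b]
    if (b %in% cfg$waterBandIdx)
      amp <- amp + cfg$waterAmpPerMoisture * dm
    A <- A + amp * g
  }
  A <- A + matrix(drift, n, cfg$nPoints, byrow = TRUE) + offset
  A <- A * mult + add + noise
  SpectraSet(A, wl, density = dens, moisture = moistureLevel)
}

#' Generate a mixed-moisture target dataset
#'
#' Concatenates `perLevel` samples drawn at each of the given moisture
#' levels (defaults to every configured level above the 10% source
#' condition), with the level recorded per sample — the mixed-condition
#' calibration design.
#'
#' @param cfg a [synthConfig()].
#' @param perLevel samples per moisture level (>= 1).
#' @param levels moisture levels to mix.
#' @return A [SpectraSet] with per-sample `moisture` tags.
#' @export
synthMixedTarget <- function(cfg, perLevel,
                             levels = setdiff(cfg$moistureLevels, 10)) {
  stopifnot(perLevel >= 1L)
  parts <- lapply(seq_along(levels), function(i) {
    c2 <- cfg
    c2$nSamples <- as.integer(perLevel)
    c2$seed <- cfg$seed + 104729L * i     # distinct wood per level
    synthSpectra(c2, levels[i])
  })
  absorb <- do.call(rbind, lapply(parts, absorbance))
  SpectraSet(absorb, wavelengths(parts[[1]]),
             density = unlist(lapply(parts, density)),
             moisture = rep(levels, each = perLevel),
             sampleIds = sprintf("mix%03d", seq_len(nrow(absorb))))
}
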