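# Synthetic spectral-reflectometry instrument: generates raw spectra, mirror
# references, volumetric scan stacks and barcoding scenarios with known
# ground truth, so that every stage of the pipeline is testable offline.
#
# Acquisition pipeline: simulate the true reflectance on a fine grid,
# convolve with the Gaussian line-spread function, sample on the (jittered)
# instrument grid, multiply by the source envelope, add Gaussian noise.
# The mirror reference is the envelope alone.

# supercontinuum-like envelope: smooth quartic peaking near 550 nm, positive
.defaultEnvelope <- function(wavelength) {
  u <- (wavelength - 550) / 200
  0.3 + (1 - u^2)^2
}

#' Construct an InstrumentModel
#'
#' Defaults emulate the confocal spectral-reflectometry setup: 450-700 nm
#' band, 0.6-nm sampling and Gaussian line-spread FWHM, a supercontinuum-like
#' source envelope, 1% additive noise and sub-sample grid jitter.
#'
#' @param band Band `c(min, max)` nm.
#' @param sampling Sampling step nm.
#' @param lsfFwhm Line-spread FWHM nm.
#' @param envelope Positive envelope function of wavelength (nm).
#' @param noiseSd Noise sd as a fraction of the fringe amplitude.
#' @param gridJitter Uniform grid offset half-width nm.
#' @param seed Default seed (`NA` = use current RNG state).
#' @return An [InstrumentModel-class].
#' @export
InstrumentModel <- function(band = c(450, 700), sampling = 0.6,
                            lsfFwhm = 0.6, envelope = .defaultEnvelope,
                            noiseSd = 0.01, gridJitter = 0.3, seed = NA) {
  new("InstrumentModel", band = as.numeric(band), sampling = sampling,
      lsfFwhm = lsfFwhm, envelope = envelope, noiseSd = noiseSd,
      gridJitter = gridJitter, seed = as.numeric(seed))
}

.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# True reflectance on a fine padded grid, blurred by the Gaussian LSF.
.blurredTruth <- function(instrument, trueD, core, medium, fineStep = 0.1) {
  sig <- instrument@lsfFwhm / (2 * sqrt(2 * log(2)))
  pad <- max(4 * sig, 1)
  fine <- seq(instrument@band[1] - pad, instrument@band[2] + pad,
              by = fineStep)
  R <- stackRT(sphereStack(trueD, core, medium), fine)$R
  if (sig > 0) {
    half <- ceiling(4 * sig / fineStep)
    kern <- stats::dnorm(seq(-half, half) * fineStep, sd = sig)
    kern <- kern / sum(kern)
    R <- stats::filter(R, kern, sides = 2)
  }
  keep <- !is.na(R)
  list(wavelengths = fine[keep], R = as.numeric(R[keep]))
}

.instrumentGrid <- function(instrument, offset = 0)
  seq(instrument@band[1], instrument@band[2], by = instrument@sampling) +
    offset

#' Acquire one synthetic raw spectrum plus its mirror reference
#'
#' @param instrument An [InstrumentModel-class].
#' @param trueD True sphere diameter nm.
#' @param core,medium [Material-class] objects (defaults: polystyrene in
#'   water).
#' @param seed Seed for this acquisition (default: the instrument's seed).
#' @return List with `raw` and `reference` ([Spectrum-class] objects) and
#'   `truth` (the blurred noiseless reflectance on the same grid).
#' @examples
#' inst <- InstrumentModel(noiseSd = 0)
#' acq <- acquireSpectrum(inst, 3000, seed = 1)
#' decodeSpectrum(normalizeSpectrum(acq$raw, acq$reference),
#'                buildDatabase(2990, 3010, 1, getMaterial("polystyrene"),
#'                              getMaterial("water")))
#' @export
acquireSpectrum <- function(instrument, trueD,
                            core = getMaterial("polystyrene"),
                            medium = getMaterial("water"),
                            seed = instrument@seed) {
  blur <- .blurredTruth(instrument, trueD, core, medium)
  .withSeed(seed, {
    off <- if (instrument@gridJitter > 0)
      stats::runif(1, -instrument@gridJitter, instrument@gridJitter)
    else 0
    grid <- .instrumentGrid(instrument, off)
    grid <- grid[grid >= min(blur$wavelengths) &
                 grid <= max(blur$wavelengths)]
    Rg <- as.vector(.resampleRows(blur$R, blur$wavelengths, grid))
    env <- instrument@envelope(grid)
    signal <- env * Rg
    famp <- (max(signal) - min(signal)) / 2
    raw <- signal + stats::rnorm(length(signal),
                                 sd = instrument@noiseSd * famp)
    meta <- list(resolution = instrument@sampling, source = "synthetic",
                 true_diameter = trueD, seed = seed)
    list(raw = Spectrum(grid, raw, meta),
         reference = Spectrum(grid, env, list(kind = "mirror_reference")),
         truth = Spectrum(grid, Rg, list(kind = "blurred_truth")))
  })
}

#' Acquire a synthetic volumetric scan stack
#'
#' Emulates the volumetric scan around a sphere (default 9 x 9 x 10 voxels,
#' 100 nm lateral / 200 nm axial spacing). The voxel nearest the sphere
#' centre carries the full-contrast spectrum; off-centre voxels have
#' intensity and fringe contrast attenuated by a 3-D Gaussian confocal
#' profile, without spectral distortion.
#'
#' @inheritParams acquireSpectrum
#' @param positionOffset Sphere-centre offset `c(x, y, z)` nm relative to the
#'   scan centre.
#' @param dims Scan dimensions (default `c(9, 9, 10)`).
#' @param spacing Voxel spacing `c(lateral, axial)` nm (default
#'   `c(100, 200)`).
#' @param confocalSigma Gaussian widths `c(lateral, axial)` nm of the
#'   confocal profile (default `c(200, 400)`).
#' @return List with `stack` ([ScanStack-class]) and `reference`
#'   ([Spectrum-class]).
#' @export
acquireStack <- function(instrument, trueD, positionOffset = c(0, 0, 0),
                         core = getMaterial("polystyrene"),
                         medium = getMaterial("water"),
                         dims = c(9L, 9L, 10L), spacing = c(100, 200),
                         confocalSigma = c(200, 400),
                         seed = instrument@seed) {
  dims <- as.integer(dims)
  blur <- .blurredTruth(instrument, trueD, core, medium)
  .withSeed(seed, {
    off <- if (instrument@gridJitter > 0)
      stats::runif(1, -instrument@gridJitter, instrument@gridJitter)
    else 0
    grid <- .instrumentGrid(instrument, off)
    grid <- grid[grid >= min(blur$wavelengths) &
                 grid <= max(blur$wavelengths)]
    Rg <- as.vector(.resampleRows(blur$R, blur$wavelengths, grid))
    env <- instrument@envelope(grid)
    m <- mean(Rg)
    famp <- (max(env * Rg) - min(env * Rg)) / 2
    centre <- (dims + 1) / 2  # voxel coordinates of the scan centre
    nvox <- prod(dims)
    spec <- matrix(NA_real_, nrow = nvox, ncol = length(grid))
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
      for (i in seq_len(dims[1])) {
        dx <- (i - centre[1]) * spacing[1] - positionOffset[1]
        dy <- (j - centre[2]) * spacing[1] - positionOffset[2]
        dz <- (k - centre[3]) * spacing[2] - positionOffset[3]
        g <- exp(-(dx^2 + dy^2) / (2 * confocalSigma[1]^2) -
                   dz^2 / (2 * confocalSigma[2]^2))
        v <- g * env * (m + g * (Rg - m)) +
          stats::rnorm(length(grid), sd = instrument@noiseSd * famp)
        spec[i + (j - 1L) * dims[1] + (k - 1L) * dims[1] * dims[2], ] <- v
      }
    stack <- new("ScanStack", dims = dims, spacing = as.numeric(spacing),
                 spectra = spec, wavelengths = grid,
                 meta = list(true_diameter = trueD, seed = seed,
                             position_offset = positionOffset,
                             dwell_time_ms = 30))
    list(stack = stack,
         reference = Spectrum(grid, env, list(kind = "mirror_reference")))
  })
}

#' Generate a multiplexed barcoding scenario with ground truth
#'
#' Assigns each simulated cell a distinct probe diameter (at least
#' `minSpacing` apart) and acquires one synthetic spectrum per cell per
#' timepoint. Diameter assignments and measurements are fully seeded.
#'
#' @param nCells Number of cells (>= 1).
#' @param diameterRange Diameter range `c(min, max)` nm.
#' @param timepoints Vector of timepoints.
#' @param instrument An [InstrumentModel-class].
#' @param seed Base seed.
#' @param minSpacing Minimum diameter spacing nm (default 40).
#' @param core,medium [Material-class] objects.
#' @return A [BarcodeScenario-class].
#' @export
makeBarcodeScenario <- function(nCells, diameterRange, timepoints,
                                instrument, seed = 1, minSpacing = 40,
                                core = getMaterial("polystyrene"),
                                medium = getMaterial("water")) {
  if (nCells < 1L) stop("nCells must be >= 1")
  slots <- floor(diff(range(diameterRange)) / minSpacing)
  if (nCells > slots)
    stop(sprintf(
      "diameter range too small: capacity %d (= multiplexingCapacity(%g, %g)) < %d cells",
      multiplexingCapacity(diff(range(diameterRange)), minSpacing),
      diff(range(diameterRange)), minSpacing, nCells))
  ds <- .withSeed(seed, {
    grid <- seq(diameterRange[1], diameterRange[2], by = minSpacing)
    sort(sample(grid, nCells))
  })
  cells <- data.frame(id = sprintf("cell%02d", seq_len(nCells)),
                      diameter = ds, stringsAsFactors = FALSE)
  measurements <- lapply(seq_len(nCells), function(ci) {
    lapply(seq_along(timepoints), function(ti) {
      si <- (seed + ci * 104729 + ti * 1299709) %% 2147483647
      acq <- acquireSpectrum(instrument, ds[ci], core = core,
                             medium = medium, seed = si)
      list(raw = acq$raw, reference = acq$reference)
    })
  })
  new("BarcodeScenario", cells = cells,
      timepoints = as.numeric(timepoints), measurements = measurements,
      seed = as.numeric(seed))
}

#' Decode and re-identify every measurement of a barcoding scenario
#'
#' Decodes each measurement and assigns it to the cell with the nearest true
#' diameter; reports the per-measurement assignments and the confusion rate
#' (fraction of measurements assigned to the wrong cell or rejected).
#'
#' @param scenario A [BarcodeScenario-class].
#' @param db A [SpectrumDatabase-class] covering the scenario's diameters.
#' @param ... Passed to [decodeSpectrum()].
#' @return List with `assignments` (data.frame: `cell`, `timepoint`,
#'   `decoded`, `assigned`, `correct`) and `confusionRate`.
#' @export
trackBarcodes <- function(scenario, db, ...) {
  rows <- list()
  for (ci in seq_len(nrow(scenario@cells))) {
    for (ti in seq_along(scenario@timepoints)) {
      m <- scenario@measurements[[ci]][[ti]]
      res <- decodeSpectrum(normalizeSpectrum(m$raw, m$reference), db, ...)
      dec <- if (res@status == "accepted") res@diameter else NA_real_
      assigned <- if (is.na(dec)) NA_character_
      else scenario@cells$id[which.min(abs(scenario@cells$diameter - dec))]
      rows[[length(rows) + 1L]] <- data.frame(
        cell = scenario@cells$id[ci],
        timepoint = scenario@timepoints[ti],
        decoded = dec, assigned = assigned,
        correct = identical(assigned, scenario@cells$id[ci]),
        stringsAsFactors = FALSE)
    }
  }
  assignments <- do.call(rbind, rows)
  list(assignments = assignments,
       confusionRate = mean(!assignments$correct))
}
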