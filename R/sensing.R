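# Microenvironmental sensing: a molecular adlayer (or a refractive-index
# change inside the probe) shifts the interference fringes toward longer
# wavelengths. The adlayer model tracks the displacement of the fringe peak
# nearest 589 nm; a partially dense layer is represented as an effective
# medium of the molecule and the solvent.

#' Construct an AdlayerModel
#'
#' Defaults describe the streptavidin-on-polystyrene configuration: a 3-um
#' core in water gaining a ~5-nm protein layer of index 1.50 per side.
#'
#' @param coreDiameter Core diameter nm (default 3000).
#' @param core,medium [Material-class] objects (defaults: polystyrene, water).
#' @param layerThickness Adlayer thickness per side nm (default 5).
#' @param layerIndex Fully dense layer index (default 1.50); must be at least
#'   the medium index.
#' @param mixing `"linear"` or `"maxwell-garnett"`.
#' @return An [AdlayerModel-class].
#' @export
AdlayerModel <- function(coreDiameter = 3000,
                         core = getMaterial("polystyrene"),
                         medium = getMaterial("water"),
                         layerThickness = 5, layerIndex = 1.50,
                         mixing = "linear") {
  m <- new("AdlayerModel", coreDiameter = coreDiameter, core = core,
           medium = medium, layerThickness = layerThickness,
           layerIndex = layerIndex, mixing = mixing)
  nMed <- refractiveIndex(medium, 589)
  if (layerIndex < nMed)
    stop("layerIndex must be >= the medium index (", round(nMed, 4), ")")
  m
}

# Effective index of a layer with molecular volume fraction p, solvent nMed.
.effectiveIndex <- function(p, nLayer, nMed, mixing) {
  if (mixing == "linear") return(p * nLayer + (1 - p) * nMed)
  # Maxwell-Garnett: inclusions (molecule) in host (solvent)
  eL <- nLayer^2; eM <- nMed^2
  eff <- eM * (eL + 2 * eM + 2 * p * (eL - eM)) /
              (eL + 2 * eM -     p * (eL - eM))
  sqrt(eff)
}

# Location of the fringe peak nearest `target`, with parabolic refinement.
.peakNear <- function(wl, v, target) {
  i <- which(diff(sign(diff(v))) == -2) + 1L
  if (!length(i))
    stop("no fringe peak found in the tracking window")
  i <- i[which.min(abs(wl[i] - target))]
  num <- v[i - 1L] - v[i + 1L]
  den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  wl[i] + 0.5 * num / den * (wl[2] - wl[1])
}

# Simulate the coated stack of an adlayer model at density p.
.adlayerSpectrum <- function(model, p, wl) {
  nMed <- refractiveIndex(model@medium, 589)
  ad <- if (p > 0)
    list(c(model@layerThickness,
           .effectiveIndex(p, model@layerIndex, nMed, model@mixing)))
  else NULL
  st <- sphereStack(model@coreDiameter, model@core, model@medium, ad)
  stackRT(st, wl)$R
}

#' Spectral redshift caused by a partially dense adlayer
#'
#' Simulates the bare and coated stacks over a window around the tracked
#' fringe and returns the displacement of the fringe peak nearest
#' `trackWavelength` (positive = redshift). The coated layer index is the
#' effective-medium mixture of the layer molecule and the surrounding medium
#' at volume fraction `density`.
#'
#' @param model An [AdlayerModel-class].
#' @param density Surface density fraction `p` in `[0, 1]`.
#' @param sampling Simulation sampling nm (default 0.01).
#' @param trackWavelength Fringe tracked (default 589 nm).
#' @param window Simulation window nm (default `c(540, 640)`).
#' @param metric `"peak"` (default) tracks the fringe-peak displacement;
#'   `"xcorr"` reports the lag maximizing the cross-correlation of coated vs
#'   bare spectra over the window.
#' @return Redshift in nm.
#' @examples
#' adlayerShift(AdlayerModel(), 1)
#' @export
adlayerShift <- function(model, density, sampling = 0.01,
                         trackWavelength = 589, window = c(540, 640),
                         metric = c("peak", "xcorr")) {
  metric <- match.arg(metric)
  if (density < 0 || density > 1) stop("density must lie in [0, 1]")
  wl <- seq(window[1], window[2], by = sampling)
  bare <- .adlayerSpectrum(model, 0, wl)
  if (density == 0) return(0)
  coat <- .adlayerSpectrum(model, density, wl)
  if (metric == "peak")
    return(.peakNear(wl, coat, trackWavelength) -
           .peakNear(wl, bare, trackWavelength))
  # cross-correlation metric: lag of max correlation, parabolic-refined
  maxLag <- as.integer(ceiling(5 / sampling))
  lags <- -maxLag:maxLag
  cc <- vapply(lags, function(l) {
    if (l >= 0)
      stats::cor(coat[(1 + l):length(coat)], bare[1:(length(bare) - l)])
    else
      stats::cor(coat[1:(length(coat) + l)], bare[(1 - l):length(bare)])
  }, numeric(1))
  i <- which.max(cc)
  off <- if (i > 1L && i < length(cc)) {
    den <- cc[i - 1L] - 2 * cc[i] + cc[i + 1L]
    if (den < 0) 0.5 * (cc[i - 1L] - cc[i + 1L]) / den else 0
  } else 0
  (lags[i] + off) * sampling  # coated shifted right => positive best lag
}

#' Invert a measured redshift into a surface density
#'
#' Bisection on the monotone density-to-shift map until the simulated shift
#' matches the measurement within `tol` nm. Shifts above the full-density
#' ceiling raise a saturation error reporting the ceiling.
#'
#' @param model An [AdlayerModel-class].
#' @param measuredShift Measured redshift nm (>= 0).
#' @param tol Shift-matching tolerance nm (default 1e-3).
#' @param ... Passed to [adlayerShift()] (sampling, window, ...).
#' @return Density fraction in `[0, 1]`.
#' @examples
#' invertDensity(AdlayerModel(), 0.57)
#' @export
invertDensity <- function(model, measuredShift, tol = 1e-3, ...) {
  if (measuredShift < 0) stop("measured shift must be non-negative")
  if (measuredShift == 0) return(0)
  ceiling <- adlayerShift(model, 1, ...)
  if (measuredShift > ceiling + tol)
    stop(sprintf(
      "measured shift %.3f nm exceeds the full-density ceiling %.3f nm (saturation)",
      measuredShift, ceiling))
  if (measuredShift >= ceiling) return(1)
  lo <- 0; hi <- 1
  repeat {
    mid <- (lo + hi) / 2
    s <- adlayerShift(model, mid, ...)
    if (abs(s - measuredShift) < tol && hi - lo < 1e-3) return(mid)
    if (s < measuredShift) lo <- mid else hi <- mid
    if (hi - lo < 1e-7) return((lo + hi) / 2)
  }
}

#' Construct an LCModel
#'
#' @param dropletDiameter Droplet diameter nm (default 4000).
#' @param nOrdinary,nExtraordinary Principal indices (defaults 1.55, 1.74).
#' @param medium Surrounding [Material-class] (default the PDMS-like
#'   constant-index material, n = 1.41).
#' @return An [LCModel-class].
#' @export
LCModel <- function(dropletDiameter = 4000, nOrdinary = 1.55,
                    nExtraordinary = 1.74, medium = getMaterial("pdms")) {
  new("LCModel", dropletDiameter = dropletDiameter, nOrdinary = nOrdinary,
      nExtraordinary = nExtraordinary, medium = medium)
}

#' Reflectance spectrum of a liquid-crystal droplet at a given effective index
#'
#' With no applied field the beam senses the ordinary index `n_o`; an
#' electric field reorients the molecules and raises the effective index
#' toward `n_e`, redshifting the fringes. The field-to-index mapping is the
#' caller's responsibility.
#'
#' @param model An [LCModel-class].
#' @param nEffective Effective index, must lie in `[n_o, n_e]`.
#' @param wavelengths Simulation grid (default 450-700 at 0.1 nm).
#' @return A [Spectrum-class].
#' @export
lcSpectrum <- function(model, nEffective,
                       wavelengths = seq(450, 700, by = 0.1)) {
  if (nEffective < model@nOrdinary - 1e-9 ||
      nEffective > model@nExtraordinary + 1e-9)
    stop(sprintf("nEffective = %.4g outside [n_o = %.4g, n_e = %.4g]",
                 nEffective, model@nOrdinary, model@nExtraordinary))
  st <- sphereStack(model@dropletDiameter,
                    fixedIndexMaterial(nEffective, "lc_effective"),
                    model@medium)
  reflectanceSpectrum(st, wavelengths)
}
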