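# Central S4 containers. All wavelengths are vacuum nm; wavenumber k = 1/lambda
# in nm^-1. Indices are real (lossless media only).

#' Material: a dispersive (or constant) refractive-index model
#'
#' A material is a named dispersion model mapping vacuum wavelength (nm) to a
#' real refractive index, valid over a stated wavelength range. Supported
#' models: `"sellmeier"` (coefficients `B`, `C`, lambda in um),
#' `"cauchy"` (coefficients `A`, lambda in um) and `"constant"`
#' (coefficient `value`). Absorbing (complex-index) materials are rejected by
#' design: the transfer-matrix solver is lossless.
#'
#' @slot name Identifier.
#' @slot model One of `"sellmeier"`, `"cauchy"`, `"constant"`.
#' @slot coefficients Named list of model coefficients.
#' @slot range Valid wavelength range `c(min, max)` in nm.
#' @export
setClass("Material",
  representation(name = "character", model = "character",
                 coefficients = "list", range = "numeric"))

setValidity("Material", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!object@model %in% c("sellmeier", "cauchy", "constant"))
    msg <- c(msg, sprintf("unknown dispersion model '%s'", object@model))
  if (length(object@range) != 2L || !all(is.finite(object@range)) ||
      object@range[1] >= object@range[2])
    msg <- c(msg, "'range' must be c(min, max) nm with min < max")
  if (length(msg)) msg else TRUE
})

#' Layer: one slab of a multilayer stack
#'
#' @slot material A [Material-class]. Fixed-index pseudo-materials are plain
#'   constant materials.
#' @slot thickness Thickness in nm; `Inf` marks the two semi-infinite outer
#'   media.
#' @export
setClass("Layer",
  representation(material = "Material", thickness = "numeric"))

setValidity("Layer", function(object) {
  if (length(object@thickness) != 1L || is.na(object@thickness) ||
      object@thickness <= 0)
    "layer thickness must be a single positive number (Inf for outer media)"
  else TRUE
})

#' LayerStack: an ordered dielectric multilayer
#'
#' Ordered outermost-to-outermost list of [Layer-class] objects. The first and
#' last layers are the semi-infinite outer media; all internal layers have
#' finite positive thickness. A sphere probed through its centre maps onto a
#' mirror-symmetric stack whose core thickness equals the sphere diameter (see
#' [sphereStack()]).
#'
#' @slot layers List of [Layer-class] objects (length >= 3).
#' @export
setClass("LayerStack", representation(layers = "list"))

setValidity("LayerStack", function(object) {
  ls <- object@layers
  if (length(ls) < 3L)
    return("a stack needs at least 3 layers: medium | core | medium")
  if (!all(vapply(ls, is, logical(1), "Layer")))
    return("all elements of 'layers' must be Layer objects")
  th <- vapply(ls, function(l) l@thickness, numeric(1))
  if (!is.infinite(th[1]) || !is.infinite(th[length(th)]))
    return("first and last layers must be semi-infinite (thickness = Inf)")
  if (length(th) > 2L && !all(is.finite(th[-c(1, length(th))])))
    return("internal layers must have finite positive thickness")
  TRUE
})

#' Spectrum: wavelength grid plus intensity values
#'
#' The universal currency of the pipeline. Values are reflectance
#' (dimensionless, in `[0, 1]` when simulated) or raw detector units before
#' mirror-reference normalization.
#'
#' @slot wavelengths Strictly increasing vacuum wavelengths (nm).
#' @slot values Intensities, same length as `wavelengths`.
#' @slot meta List of acquisition descriptors (resolution nm, source tag, ...).
#' @export
setClass("Spectrum",
  representation(wavelengths = "numeric", values = "numeric", meta = "list"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavelengths) != length(object@values))
    msg <- c(msg, "'wavelengths' and 'values' must have equal length")
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "'wavelengths' must be strictly increasing")
  if (anyNA(object@wavelengths))
    msg <- c(msg, "'wavelengths' must not contain NA")
  if (length(msg)) msg else TRUE
})

#' SpectrumDatabase: diameter-indexed simulated reflectance spectra
#'
#' The decoder's lookup structure: one simulated reflectance spectrum per
#' diameter on a common wavelength grid, with constant diameter step.
#'
#' @slot diameters Strictly increasing diameter grid (nm), constant step.
#' @slot spectra Matrix, one row per diameter.
#' @slot wavelengths Common wavelength grid (nm).
#' @slot meta Build parameters: core/medium material names, diameter step,
#'   format version.
#' @export
setClass("SpectrumDatabase",
  representation(diameters = "numeric", spectra = "matrix",
                 wavelengths = "numeric", meta = "list"))

setValidity("SpectrumDatabase", function(object) {
  msg <- character()
  if (nrow(object@spectra) != length(object@diameters))
    msg <- c(msg, "row count of 'spectra' must equal length of 'diameters'")
  if (ncol(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "column count of 'spectra' must equal wavelength count")
  d <- object@diameters
  if (length(d) > 1L) {
    st <- diff(d)
    if (any(st <= 0)) msg <- c(msg, "'diameters' must be strictly increasing")
    else if (diff(range(st)) > 1e-6 * mean(st))
      msg <- c(msg, "'diameters' must have a constant step")
  }
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "'wavelengths' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ScanStack: a volumetric confocal scan of spectra
#'
#' One spectrum per voxel of a small XYZ scan around a probe (default
#' 9 x 9 x 10 voxels at 100 nm lateral / 200 nm axial spacing). Voxel
#' `(i, j, k)` maps to row `i + (j-1)*nx + (k-1)*nx*ny` of `spectra`.
#'
#' @slot dims Integer `c(nx, ny, nz)`.
#' @slot spacing Numeric `c(lateral, axial)` in nm.
#' @slot spectra Matrix, one row per voxel, on a shared wavelength grid.
#' @slot wavelengths Shared wavelength grid (nm).
#' @slot meta Acquisition descriptors.
#' @export
setClass("ScanStack",
  representation(dims = "integer", spacing = "numeric", spectra = "matrix",
                 wavelengths = "numeric", meta = "list"))

setValidity("ScanStack", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "'dims' must be three positive integers")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be c(lateral, axial) nm, both positive")
  if (nrow(object@spectra) != prod(object@dims))
    msg <- c(msg, "'spectra' must have one row per voxel (prod(dims))")
  if (ncol(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "spectra columns must match the wavelength grid")
  if (length(msg)) msg else TRUE
})

#' DecodeResult: a decoded diameter with goodness of fit
#'
#' @slot diameter Best-fit diameter (nm); `NA` when rejected at the boundary.
#' @slot correlation Pearson r of measurement vs best-fit simulated spectrum.
#' @slot rSquared Squared Pearson r (the fit quality reported as R^2).
#' @slot refined `TRUE` if sub-grid parabolic refinement was applied.
#' @slot status `"accepted"`, `"rejected_boundary"` or `"rejected_low_fit"`.
#' @slot centerVoxel Voxel `(i, j, k)` used, when decoded from a stack.
#' @export
setClass("DecodeResult",
  representation(diameter = "numeric", correlation = "numeric",
                 rSquared = "numeric", refined = "logical",
                 status = "character", centerVoxel = "integer"),
  prototype(diameter = NA_real_, correlation = NA_real_, rSquared = NA_real_,
            refined = FALSE, status = "accepted", centerVoxel = integer()))

setValidity("DecodeResult", function(object) {
  if (!object@status %in%
      c("accepted", "rejected_boundary", "rejected_low_fit"))
    return(sprintf("invalid status '%s'", object@status))
  if (!is.na(object@correlation) &&
      (object@correlation < -1 - 1e-12 || object@correlation > 1 + 1e-12))
    return("correlation must lie in [-1, 1]")
  TRUE
})

#' PhasorPoint: fringe frequency and phase of a spectrum
#'
#' The phasor coordinates of a reflectance spectrum in the wavenumber domain:
#' radial coordinate = fringe frequency (nm; physically close to the
#' round-trip group optical thickness `2 * n_g * d`), angular coordinate =
#' phase evaluated at the 500-nm reference wavenumber, wrapped to `[0, 2*pi)`.
#'
#' @slot frequency Fringe frequency in nm (> 0).
#' @slot phase Phase in radians at k = 1/500 nm^-1, in `[0, 2*pi)`.
#' @slot amplitude Fringe modulation depth.
#' @slot offset Mean level of the fitted cosine model.
#' @export
setClass("PhasorPoint",
  representation(frequency = "numeric", phase = "numeric",
                 amplitude = "numeric", offset = "numeric"))

setValidity("PhasorPoint", function(object) {
  msg <- character()
  if (object@frequency <= 0) msg <- c(msg, "'frequency' must be positive")
  if (object@phase < 0 || object@phase >= 2 * pi)
    msg <- c(msg, "'phase' must be wrapped to [0, 2*pi)")
  if (length(msg)) msg else TRUE
})

#' InstrumentModel: the synthetic spectral-reflectometry instrument
#'
#' Parametrises the synthetic acquisition pipeline: band, spectral sampling,
#' Gaussian line-spread function, supercontinuum-like source envelope,
#' additive detector noise, and sub-sample grid jitter.
#'
#' @slot band Wavelength band `c(min, max)` nm (default 450-700).
#' @slot sampling Spectral sampling step nm (default 0.6).
#' @slot lsfFwhm FWHM of the Gaussian line-spread function, nm (default 0.6).
#' @slot envelope Strictly positive source-envelope function of wavelength.
#' @slot noiseSd Additive Gaussian noise sd as a fraction of the fringe
#'   amplitude (default 0.01).
#' @slot gridJitter Half-width (nm) of the uniform random offset applied to
#'   the sampling grid per acquisition (default 0.3).
#' @slot seed Integer seed; `NA` to use the current RNG state.
#' @export
setClass("InstrumentModel",
  representation(band = "numeric", sampling = "numeric", lsfFwhm = "numeric",
                 envelope = "function", noiseSd = "numeric",
                 gridJitter = "numeric", seed = "numeric"))

setValidity("InstrumentModel", function(object) {
  msg <- character()
  if (object@sampling <= 0) msg <- c(msg, "'sampling' must be > 0")
  if (object@lsfFwhm < 0) msg <- c(msg, "'lsfFwhm' must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@gridJitter < 0) msg <- c(msg, "'gridJitter' must be >= 0")
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    msg <- c(msg, "'band' must be c(min, max) nm")
  if (length(msg)) msg else TRUE
})

#' AdlayerModel: protein adlayer on a microsphere
#'
#' Models a molecular adlayer (e.g. bound streptavidin, ~5 nm, n = 1.50) as a
#' homogeneous thin film on each side of the core, with an effective index set
#' by the surface density through a mixing law.
#'
#' @slot coreDiameter Core diameter nm.
#' @slot core,medium [Material-class] objects.
#' @slot layerThickness Adlayer thickness per side, nm (default 5).
#' @slot layerIndex Index of the fully dense layer (default 1.50).
#' @slot mixing `"linear"` (volume-fraction index mixing, default) or
#'   `"maxwell-garnett"`.
#' @export
setClass("AdlayerModel",
  representation(coreDiameter = "numeric", core = "Material",
                 medium = "Material", layerThickness = "numeric",
                 layerIndex = "numeric", mixing = "character"))

setValidity("AdlayerModel", function(object) {
  msg <- character()
  if (object@coreDiameter <= 0) msg <- c(msg, "'coreDiameter' must be > 0")
  if (object@layerThickness <= 0) msg <- c(msg, "'layerThickness' must be > 0")
  if (!object@mixing %in% c("linear", "maxwell-garnett"))
    msg <- c(msg, "'mixing' must be 'linear' or 'maxwell-garnett'")
  if (length(msg)) msg else TRUE
})

#' LCModel: nematic liquid-crystal droplet probe
#'
#' A birefringent droplet in a polymer matrix. The probing beam senses an
#' effective index between the ordinary index `n_o` (no field) and the
#' extraordinary index `n_e` (full reorientation); the field-to-index mapping
#' is deliberately parametric (the caller supplies `n_effective`).
#'
#' @slot dropletDiameter Droplet diameter nm.
#' @slot nOrdinary Ordinary index (default 1.55).
#' @slot nExtraordinary Extraordinary index (default 1.74).
#' @slot medium Surrounding [Material-class] (default PDMS-like constant 1.41).
#' @export
setClass("LCModel",
  representation(dropletDiameter = "numeric", nOrdinary = "numeric",
                 nExtraordinary = "numeric", medium = "Material"))

setValidity("LCModel", function(object) {
  if (object@nOrdinary > object@nExtraordinary)
    return("'nOrdinary' must not exceed 'nExtraordinary'")
  if (object@dropletDiameter <= 0) return("'dropletDiameter' must be > 0")
  TRUE
})

#' FluorophoreModel: brightness model of a fluorophore solution
#'
#' Emitted-signal model `Phi * sigma * C * N_A * L_eff` with unit bookkeeping
#' (mol/L converted to nm^-3). `effectivePath` is a single calibration
#' constant; see [calibrateEffectivePath()].
#'
#' @slot quantumYield Quantum yield Phi (0 < Phi <= 1).
#' @slot crossSection Absorption cross-section sigma in nm^2.
#' @slot concentration Concentration in mol/L.
#' @slot effectivePath Effective excitation/collection path length nm.
#' @export
setClass("FluorophoreModel",
  representation(quantumYield = "numeric", crossSection = "numeric",
                 concentration = "numeric", effectivePath = "numeric"))

setValidity("FluorophoreModel", function(object) {
  msg <- character()
  if (object@quantumYield <= 0 || object@quantumYield > 1)
    msg <- c(msg, "'quantumYield' must be in (0, 1]")
  if (object@crossSection <= 0) msg <- c(msg, "'crossSection' must be > 0")
  if (object@concentration <= 0) msg <- c(msg, "'concentration' must be > 0")
  if (object@effectivePath <= 0) msg <- c(msg, "'effectivePath' must be > 0")
  if (length(msg)) msg else TRUE
})

#' PrecisionReport: Monte-Carlo repeatability of decoded diameters
#'
#' @slot nReplicates Number of simulated acquisitions.
#' @slot meanDiameter,sdDiameter,maxSpread Summary statistics (nm) over the
#'   accepted decodes; `maxSpread` is the maximum pairwise difference.
#' @slot nRejected Number of replicates rejected by the decoder.
#' @slot configDigest Human-readable digest of the instrument configuration.
#' @slot seed Base seed used.
#' @export
setClass("PrecisionReport",
  representation(nReplicates = "integer", meanDiameter = "numeric",
                 sdDiameter = "numeric", maxSpread = "numeric",
                 nRejected = "integer", configDigest = "character",
                 seed = "numeric"))

setValidity("PrecisionReport", function(object) {
  msg <- character()
  if (object@nReplicates < 2L) msg <- c(msg, "need at least 2 replicates")
  if (!is.na(object@maxSpread) && object@maxSpread < 0)
    msg <- c(msg, "'maxSpread' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' BarcodeScenario: multiplexed cell-barcoding ground truth plus measurements
#'
#' @slot cells data.frame with columns `id` and `diameter` (nm).
#' @slot timepoints Numeric vector of time points.
#' @slot measurements Nested list: `measurements[[cell]][[timepoint]]` is a
#'   list with elements `raw` and `reference` ([Spectrum-class] objects).
#' @slot seed Base seed.
#' @export
setClass("BarcodeScenario",
  representation(cells = "data.frame", timepoints = "numeric",
                 measurements = "list", seed = "numeric"))

setValidity("BarcodeScenario", function(object) {
  if (!all(c("id", "diameter") %in% names(object@cells)))
    return("'cells' must have columns 'id' and 'diameter'")
  if (length(object@measurements) != nrow(object@cells))
    return("one measurement series per cell required")
  TRUE
})

# ---- accessors and show methods ----

#' @rdname Spectrum-class
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' @rdname Spectrum-class
#' @export
setMethod("intensities", "Spectrum", function(x) x@values)

#' @rdname SpectrumDatabase-class
#' @export
setMethod("wavelengths", "SpectrumDatabase", function(x) x@wavelengths)

#' @rdname ScanStack-class
#' @export
setMethod("wavelengths", "ScanStack", function(x) x@wavelengths)

#' @rdname SpectrumDatabase-class
#' @export
setMethod("diameters", "SpectrumDatabase", function(x) x@diameters)

#' @rdname SpectrumDatabase-class
#' @export
setMethod("spectraMatrix", "SpectrumDatabase", function(x) x@spectra)

#' @rdname DecodeResult-class
#' @export
setMethod("diameter", "DecodeResult", function(object) object@diameter)

#' @rdname DecodeResult-class
#' @export
setMethod("decodeStatus", "DecodeResult", function(object) object@status)

#' @rdname DecodeResult-class
#' @export
setMethod("correlationScore", "DecodeResult",
          function(object) object@correlation)

setMethod("show", "Material", function(object) {
  cat(sprintf("Material '%s' (%s model), valid %g-%g nm\n",
              object@name, object@model, object@range[1], object@range[2]))
})

setMethod("show", "Spectrum", function(object) {
  n <- length(object@wavelengths)
  cat(sprintf("Spectrum: %d samples, %g-%g nm\n", n,
              if (n) min(object@wavelengths) else NA,
              if (n) max(object@wavelengths) else NA))
})

setMethod("show", "LayerStack", function(object) {
  th <- vapply(object@layers, function(l) l@thickness, numeric(1))
  nm <- vapply(object@layers, function(l) l@material@name, character(1))
  cat("LayerStack:", paste(sprintf("%s(%s)", nm,
      ifelse(is.finite(th), paste0(th, " nm"), "semi-inf")),
      collapse = " | "), "\n")
})

setMethod("show", "SpectrumDatabase", function(object) {
  cat(sprintf(
    "SpectrumDatabase: %d diameters (%g-%g nm, step %g nm), %d wavelengths (%g-%g nm)\n",
    length(object@diameters), min(object@diameters), max(object@diameters),
    if (length(object@diameters) > 1) diff(object@diameters[1:2]) else NA,
    length(object@wavelengths), min(object@wavelengths),
    max(object@wavelengths)))
  cat(sprintf("  core: %s | medium: %s\n",
              object@meta$core %||% "?", object@meta$medium %||% "?"))
})

setMethod("show", "ScanStack", function(object) {
  cat(sprintf("ScanStack: %d x %d x %d voxels @ (%g, %g) nm, %d wavelengths\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2],
              length(object@wavelengths)))
})

setMethod("show", "DecodeResult", function(object) {
  cat(sprintf("DecodeResult: status=%s, d=%s nm, r=%.6g (R^2=%.4g)%s\n",
              object@status,
              if (is.na(object@diameter)) "NA"
              else sprintf("%.3f", object@diameter),
              object@correlation, object@rSquared,
              if (object@refined) ", refined" else ""))
})

setMethod("show", "PhasorPoint", function(object) {
  cat(sprintf(
    "PhasorPoint: frequency=%.2f nm, phase=%.4f rad, amplitude=%.4g, offset=%.4g\n",
    object@frequency, object@phase, object@amplitude, object@offset))
})

setMethod("show", "PrecisionReport", function(object) {
  cat(sprintf(
    "PrecisionReport: n=%d, mean=%.3f nm, sd=%.3f nm, max spread=%.3f nm, rejected=%d\n",
    object@nReplicates, object@meanDiameter, object@sdDiameter,
    object@maxSpread, object@nRejected))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
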