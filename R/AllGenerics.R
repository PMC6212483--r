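#' @import methods
NULL

#' Refractive index of a material at a vacuum wavelength
#'
#' Evaluates the material's dispersion model. Wavelengths outside the
#' material's valid range raise an error naming the material and its bounds.
#'
#' @param material A [Material-class] object.
#' @param wavelength Vacuum wavelength(s) in nm.
#' @return Numeric vector of (real, dimensionless) refractive indices.
#' @examples
#' refractiveIndex(getMaterial("polystyrene"), 589)
#' @export
setGeneric("refractiveIndex", function(material, wavelength)
  standardGeneric("refractiveIndex"))

#' Group refractive index n_g = n - lambda * dn/dlambda
#'
#' The group index sets the observed fringe frequency of an etalon under
#' dispersion: the round-trip optical thickness seen by the fringe spacing is
#' `2 * n_g * d`, not `2 * n * d`. Derivatives are analytic per dispersion
#' model.
#'
#' @inheritParams refractiveIndex
#' @return Numeric vector of group indices.
#' @export
setGeneric("groupIndex", function(material, wavelength)
  standardGeneric("groupIndex"))

#' @rdname Spectrum-class
#' @param x A `Spectrum`, `ScanStack` or `SpectrumDatabase` object.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname Spectrum-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname SpectrumDatabase-class
#' @export
setGeneric("diameters", function(x) standardGeneric("diameters"))

#' @rdname SpectrumDatabase-class
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname DecodeResult-class
#' @export
setGeneric("diameter", function(object) standardGeneric("diameter"))

#' @rdname DecodeResult-class
#' @export
setGeneric("decodeStatus", function(object) standardGeneric("decodeStatus"))

#' @rdname DecodeResult-class
#' @export
setGeneric("correlationScore", function(object)
  standardGeneric("correlationScore"))
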