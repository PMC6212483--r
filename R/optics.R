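# Coherent normal-incidence transfer-matrix optics for lossless multilayers.
#
# A ray focused at the centre of a dielectric sphere meets both surfaces at
# normal incidence, so the sphere is optically equivalent to a plane-parallel
# film whose thickness equals the diameter. The characteristic matrix of
# layer j with index n and thickness d at vacuum wavelength lambda is
#   M_j = [[cos(delta), i sin(delta)/n], [i n sin(delta), cos(delta)]],
# delta = 2*pi*n*d/lambda, and the stack reflectance follows from the product
# of the internal-layer matrices between the two semi-infinite media.

#' Construct a Layer
#'
#' @param material A [Material-class] or a plain numeric index (wrapped as a
#'   fixed-index pseudo-material).
#' @param thickness Thickness nm; `Inf` for the semi-infinite outer media.
#' @return A [Layer-class].
#' @export
Layer <- function(material, thickness) {
  if (is.numeric(material)) material <- fixedIndexMaterial(material)
  new("Layer", material = material, thickness = as.numeric(thickness))
}

#' Construct a LayerStack
#'
#' @param ... [Layer-class] objects, or a single list of them, ordered
#'   outermost to outermost.
#' @return A [LayerStack-class].
#' @export
LayerStack <- function(...) {
  ls <- list(...)
  if (length(ls) == 1L && is.list(ls[[1]]) && !is(ls[[1]], "Layer"))
    ls <- ls[[1]]
  new("LayerStack", layers = ls)
}

#' Construct a Spectrum
#'
#' @param wavelengths Strictly increasing vacuum wavelengths (nm).
#' @param values Intensities.
#' @param meta List of acquisition descriptors.
#' @return A [Spectrum-class].
#' @export
Spectrum <- function(wavelengths, values, meta = list()) {
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), meta = meta)
}

#' Normal-incidence Fresnel interface reflectance
#'
#' `((n1 - n2) / (n1 + n2))^2`; symmetric in its arguments.
#'
#' @param n1,n2 Refractive indices (> 0).
#' @return Reflectance fraction in `[0, 1)`.
#' @examples
#' interfaceReflectance(1.33, 1.59)
#' @export
interfaceReflectance <- function(n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("refractive indices must be positive")
  ((n1 - n2) / (n1 + n2))^2
}

#' Build the layer stack of a sphere probed through its centre
#'
#' Returns `medium | [adlayer] | core(d) | [adlayer] | medium`. Adlayers are
#' applied symmetrically, one copy per side (innermost listed first), so the
#' stack is always mirror-symmetric.
#'
#' @param d Core diameter (nm, > 0).
#' @param core,medium [Material-class] objects.
#' @param adlayers Optional list of `c(thickness_nm, index)` pairs (or
#'   [Layer-class] objects) applied to each side.
#' @return A [LayerStack-class].
#' @examples
#' sphereStack(3000, getMaterial("polystyrene"), getMaterial("water"))
#' @export
sphereStack <- function(d, core, medium, adlayers = NULL) {
  if (d <= 0) stop("diameter must be positive")
  side <- list()
  if (!is.null(adlayers)) {
    side <- lapply(adlayers, function(a) {
      if (is(a, "Layer")) a else Layer(a[[2]], a[[1]])
    })
  }
  outer <- Layer(medium, Inf)
  LayerStack(c(list(outer), side, list(Layer(core, d)), rev(side),
               list(outer)))
}

# Indices of every layer at every wavelength (list of numeric vectors).
.stackIndices <- function(stack, wavelengths) {
  lapply(stack@layers, function(l)
    refractiveIndex(l@material, wavelengths))
}

# Core transfer-matrix solver, vectorised over wavelength.
# Returns list(R, T). Lossless by construction (real indices).
.tmmRT <- function(ns, ds, wavelengths) {
  L <- length(ds)
  one <- rep(1 + 0i, length(wavelengths))
  m11 <- one; m22 <- one
  m12 <- rep(0i, length(wavelengths)); m21 <- m12
  if (L > 2L) for (j in seq(2L, L - 1L)) {
    n <- ns[[j]]
    delta <- 2 * pi * n * ds[j] / wavelengths
    c1 <- cos(delta); s1 <- sin(delta)
    a12 <- 1i * s1 / n; a21 <- 1i * n * s1
    t11 <- m11 * c1 + m12 * a21
    t12 <- m11 * a12 + m12 * c1
    t21 <- m21 * c1 + m22 * a21
    t22 <- m21 * a12 + m22 * c1
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  n0 <- ns[[1L]]; nS <- ns[[L]]
  B <- m11 + m12 * nS
  C <- m21 + m22 * nS
  r <- (n0 * B - C) / (n0 * B + C)
  t <- 2 * n0 / (n0 * B + C)
  list(R = Mod(r)^2, T = Re(nS) / Re(n0) * Mod(t)^2)
}

#' Reflectance and transmittance of a multilayer stack
#'
#' Coherent normal-incidence transfer-matrix solution. For the lossless
#' (real-index) materials supported here, `R + T = 1` at every wavelength.
#'
#' @param stack A [LayerStack-class].
#' @param wavelengths Wavelength grid (nm) within all materials' valid ranges.
#' @return List with numeric vectors `R` and `T`.
#' @export
stackRT <- function(stack, wavelengths) {
  validObject(stack)
  ds <- vapply(stack@layers, function(l) l@thickness, numeric(1))
  ns <- .stackIndices(stack, wavelengths)
  .tmmRT(ns, ds, wavelengths)
}

#' Simulated reflectance spectrum of a stack
#'
#' @inheritParams stackRT
#' @return A [Spectrum-class] with reflectance values in `[0, 1]`.
#' @examples
#' st <- sphereStack(3000, getMaterial("polystyrene"), getMaterial("water"))
#' sp <- reflectanceSpectrum(st, seq(450, 700, by = 0.5))
#' max(intensities(sp))
#' @export
reflectanceSpectrum <- function(stack, wavelengths) {
  rt <- stackRT(stack, wavelengths)
  Spectrum(wavelengths, rt$R, meta = list(kind = "simulated_reflectance"))
}

#' Count interference fringes (local maxima) of a spectrum
#'
#' Used as a coarse check that spectral fringe density grows with optical
#' thickness.
#'
#' @param spectrum A [Spectrum-class].
#' @return Integer number of strict local maxima.
#' @export
countFringes <- function(spectrum) {
  v <- spectrum@values
  if (length(v) < 3L) return(0L)
  sum(diff(sign(diff(v))) == -2)
}

#' Band-peak reflectance of a bare microsphere
#'
#' Maximum constructive-interference reflectance of a `medium | core(d) |
#' medium` stack over the band; the brightness figure used in the photometric
#' comparisons.
#'
#' @param d Diameter nm.
#' @param core,medium [Material-class] objects.
#' @param wavelengths Band grid (default 450-700 nm at 0.1 nm).
#' @return Peak reflectance fraction.
#' @examples
#' peakReflectance(3000, getMaterial("polystyrene"), getMaterial("water"))
#' @export
peakReflectance <- function(d, core, medium,
                            wavelengths = seq(450, 700, by = 0.1)) {
  max(stackRT(sphereStack(d, core, medium), wavelengths)$R)
}
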