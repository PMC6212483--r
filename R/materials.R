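# Dispersion models and the materials registry.
#
# The registry (inst/extdata/materials.yaml) holds the coefficient sets:
#  - polystyrene: one-term Sellmeier reproducing n(589) ~ 1.59
#  - water: four-term Sellmeier (visible-range fit) reproducing n(589) ~ 1.33
#  - fused_silica: the standard three-term Sellmeier, n(589) ~ 1.46
#  - streptavidin_layer (1.50) and pdms (1.41): non-dispersive constants
# Sellmeier/Cauchy coefficients are in um; the public API is in nm.

.materials_env <- new.env(parent = emptyenv())

#' Construct a Material
#'
#' @param name Identifier.
#' @param model `"sellmeier"`, `"cauchy"` or `"constant"`.
#' @param coefficients Named list: `B` and `C` (um^2) for Sellmeier, `A` for
#'   Cauchy (um powers), `value` for constant.
#' @param range Valid wavelength range `c(min, max)` nm.
#' @return A [Material-class] object.
#' @examples
#' Material("glass", "constant", list(value = 1.52), c(400, 800))
#' @export
Material <- function(name, model, coefficients, range) {
  new("Material", name = name, model = model,
      coefficients = coefficients, range = as.numeric(range))
}

#' A fixed-index pseudo-material
#'
#' @param value Refractive index.
#' @param name Identifier (default derived from the value).
#' @param range Valid range nm.
#' @export
fixedIndexMaterial <- function(value, name = sprintf("n=%g", value),
                               range = c(200, 2000)) {
  Material(name, "constant", list(value = value), range)
}

#' Load the materials registry
#'
#' Reads a human-readable YAML registry of dispersion models. Called without
#' arguments it loads (and caches) the registry shipped with the package.
#'
#' @param path Path to a registry file; `NULL` for the packaged default.
#' @return Named list of [Material-class] objects.
#' @export
loadMaterials <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.materials_env$registry))
    return(.materials_env$registry)
  if (default)
    path <- system.file("extdata", "materials.yaml", package = "SpeRe",
                        mustWork = TRUE)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$materials))
    stop("materials registry '", path, "' has no 'materials' section")
  mats <- lapply(names(spec$materials), function(nm) {
    m <- spec$materials[[nm]]
    coef <- switch(m$model,
      sellmeier = list(B = as.numeric(m$B), C = as.numeric(m$C)),
      cauchy    = list(A = as.numeric(m$A)),
      constant  = list(value = as.numeric(m$value)),
      stop("material '", nm, "': unknown model '", m$model, "'"))
    Material(nm, m$model, coef, as.numeric(m$range))
  })
  names(mats) <- names(spec$materials)
  if (default) .materials_env$registry <- mats
  mats
}

#' Fetch a material from the registry by name
#'
#' @param name Registry key, e.g. `"polystyrene"`, `"water"`,
#'   `"fused_silica"`, `"streptavidin_layer"`, `"pdms"`.
#' @param registry Optional registry list from [loadMaterials()].
#' @return A [Material-class] object.
#' @examples
#' getMaterial("water")
#' @export
getMaterial <- function(name, registry = loadMaterials()) {
  if (!name %in% names(registry))
    stop("unknown material '", name, "'; registry has: ",
         paste(names(registry), collapse = ", "))
  registry[[name]]
}

.checkRange <- function(material, wavelength) {
  bad <- wavelength < material@range[1] | wavelength > material@range[2]
  if (any(bad))
    stop(sprintf(
      "wavelength %g nm outside valid range [%g, %g] nm for material '%s'",
      wavelength[which(bad)[1]], material@range[1], material@range[2],
      material@name))
}

#' @rdname refractiveIndex
#' @export
setMethod("refractiveIndex", "Material", function(material, wavelength) {
  .checkRange(material, wavelength)
  lam <- wavelength / 1000  # um
  co <- material@coefficients
  switch(material@model,
    sellmeier = {
      l2 <- lam^2
      n2 <- 1 + Reduce(`+`, Map(function(b, c) b * l2 / (l2 - c),
                                co$B, co$C))
      sqrt(n2)
    },
    cauchy = {
      p <- 2 * (seq_along(co$A) - 1)  # powers 0, 2, 4, ...
      Reduce(`+`, Map(function(a, pw) a / lam^pw, co$A, p))
    },
    constant = rep(co$value, length.out = length(wavelength)))
})

#' @rdname groupIndex
#' @export
setMethod("groupIndex", "Material", function(material, wavelength) {
  .checkRange(material, wavelength)
  lam <- wavelength / 1000  # um; n_g is unit-free so um throughout is fine
  co <- material@coefficients
  n <- refractiveIndex(material, wavelength)
  dndl <- switch(material@model,
    sellmeier = {
      l2 <- lam^2
      dn2 <- Reduce(`+`, Map(function(b, c) -2 * b * c * lam / (l2 - c)^2,
                             co$B, co$C))
      dn2 / (2 * n)
    },
    cauchy = {
      p <- 2 * (seq_along(co$A) - 1)
      Reduce(`+`, Map(function(a, pw) -pw * a / lam^(pw + 1), co$A, p))
    },
    constant = rep(0, length(lam)))
  n - lam * dndl
})
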