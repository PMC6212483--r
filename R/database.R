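# Diameter-indexed database of simulated reflectance spectra.

.DB_FORMAT_VERSION <- "1"

#' Build a diameter-indexed spectrum database
#'
#' Simulates one reflectance spectrum per diameter on a common wavelength
#' grid using the transfer-matrix solver. The build is deterministic: row
#' `i` is bit-for-bit the output of [reflectanceSpectrum()] at
#' `diameters[i]`.
#'
#' The default grid (450-700 nm at 0.1 nm) matches the measurement band;
#' decode-time resampling adapts the rows to any instrument grid.
#'
#' @param dMin,dMax,dStep Diameter range and step, nm (`0 < dMin < dMax`).
#' @param core,medium [Material-class] objects.
#' @param wavelengths Common wavelength grid, nm.
#' @return A [SpectrumDatabase-class].
#' @examples
#' db <- buildDatabase(2995, 3005, 0.5, getMaterial("polystyrene"),
#'                     getMaterial("water"), seq(450, 700, by = 1))
#' db
#' @export
buildDatabase <- function(dMin, dMax, dStep, core, medium,
                          wavelengths = seq(450, 700, by = 0.1)) {
  if (!(dMin > 0 && dMin < dMax)) stop("need 0 < dMin < dMax")
  if (dStep <= 0) stop("dStep must be positive")
  d <- seq(dMin, dMax, by = dStep)
  # shared per-wavelength indices: the stack geometry only changes thickness
  nMed <- refractiveIndex(medium, wavelengths)
  nCore <- refractiveIndex(core, wavelengths)
  ns <- list(nMed, nCore, nMed)
  spec <- matrix(NA_real_, nrow = length(d), ncol = length(wavelengths))
  for (i in seq_along(d))
    spec[i, ] <- .tmmRT(ns, c(Inf, d[i], Inf), wavelengths)$R
  new("SpectrumDatabase", diameters = d, spectra = spec,
      wavelengths = as.numeric(wavelengths),
      meta = list(core = core@name, medium = medium@name,
                  d_step = dStep, format_version = .DB_FORMAT_VERSION))
}

#' Persist a spectrum database
#'
#' Writes a single-file binary container (R serialization with an embedded
#' format version) plus a human-readable JSON metadata sidecar at
#' `<path>.json`. The round trip through [loadDatabase()] is lossless
#' (bit-exact arrays, complete metadata).
#'
#' @param db A [SpectrumDatabase-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveDatabase <- function(db, path) {
  stopifnot(is(db, "SpectrumDatabase"))
  payload <- list(format_version = .DB_FORMAT_VERSION,
                  diameters = db@diameters, spectra = db@spectra,
                  wavelengths = db@wavelengths, meta = db@meta)
  saveRDS(payload, path)
  sidecar <- c(db@meta,
               list(n_diameters = length(db@diameters),
                    d_min = min(db@diameters), d_max = max(db@diameters),
                    band = range(db@wavelengths),
                    n_wavelengths = length(db@wavelengths)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a spectrum database
#'
#' @param path Path written by [saveDatabase()].
#' @return A [SpectrumDatabase-class].
#' @export
loadDatabase <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("database file '", path, "' is corrupt or truncated: ",
         conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$format_version))
    stop("database file '", path, "' lacks format metadata (integrity error)")
  if (!identical(payload$format_version, .DB_FORMAT_VERSION))
    stop("database format version '", payload$format_version,
         "' is incompatible with supported version '", .DB_FORMAT_VERSION,
         "'")
  need <- c("diameters", "spectra", "wavelengths", "meta")
  if (!all(need %in% names(payload)))
    stop("database file '", path, "' is missing fields: ",
         paste(setdiff(need, names(payload)), collapse = ", "))
  new("SpectrumDatabase", diameters = payload$diameters,
      spectra = payload$spectra, wavelengths = payload$wavelengths,
      meta = payload$meta)
}

#' Export a database as CSV (one row per diameter)
#'
#' Interoperability export: first column `diameter_nm`, remaining columns the
#' wavelength grid.
#'
#' @param db A [SpectrumDatabase-class].
#' @param path Output CSV path.
#' @export
writeDatabaseCSV <- function(db, path) {
  df <- data.frame(diameter_nm = db@diameters, db@spectra,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("%g", db@wavelengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
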