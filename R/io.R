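# Plain-text interchange formats: spectrum CSV (`wavelength_nm,value`),
# scan-stack TSV (voxel i,j,k + one column per wavelength), and the YAML run
# configuration.

#' Read a spectrum from CSV
#'
#' Expects the header `wavelength_nm,value`, one row per sample, UTF-8 with
#' '.' decimal separators. Malformed rows are reported with their line
#' number.
#'
#' @param path CSV path.
#' @return A [Spectrum-class].
#' @export
readSpectrum <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df)[1:2], c("wavelength_nm", "value")))
    stop("'", path, "': expected header 'wavelength_nm,value', found '",
         paste(names(df), collapse = ","), "'")
  wl <- suppressWarnings(as.numeric(df$wavelength_nm))
  v <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(wl) | is.na(v))
  if (length(bad))
    stop(sprintf("'%s': malformed numeric value at line %d", path,
                 bad[1] + 1L))
  Spectrum(wl, v, meta = list(source = path))
}

#' Write a spectrum to CSV
#'
#' @param spectrum A [Spectrum-class].
#' @param path Output path.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spectrum@wavelengths,
               value = spectrum@values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scan stack as TSV
#'
#' Columns `i`, `j`, `k` followed by one column per wavelength (header = the
#' wavelength in nm). A leading comment line records dims and spacing.
#'
#' @param stack A [ScanStack-class].
#' @param path Output path.
#' @export
writeScanStack <- function(stack, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims=%d,%d,%d spacing=%g,%g",
                     stack@dims[1], stack@dims[2], stack@dims[3],
                     stack@spacing[1], stack@spacing[2]), con)
  dims <- stack@dims
  idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
  df <- cbind(idx, as.data.frame(stack@spectra))
  names(df)[-(1:3)] <- sprintf("%.6g", stack@wavelengths)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a scan stack from TSV
#'
#' @param path Path written by [writeScanStack()].
#' @return A [ScanStack-class].
#' @export
readScanStack <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
    regexec("dims=(\\d+),(\\d+),(\\d+) spacing=([0-9.]+),([0-9.]+)", first))[[1]]
  if (length(m) != 6L)
    stop("'", path, "': missing '# dims=... spacing=...' header line")
  dims <- as.integer(m[2:4]); spacing <- as.numeric(m[5:6])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  if (!identical(names(df)[1:3], c("i", "j", "k")))
    stop("'", path, "': first three columns must be i, j, k")
  wl <- as.numeric(names(df)[-(1:3)])
  if (anyNA(wl)) stop("'", path, "': non-numeric wavelength column header")
  ord <- order(df$k, df$j, df$i)  # row index = i-fastest voxel order
  new("ScanStack", dims = dims, spacing = spacing,
      spectra = as.matrix(df[ord, -(1:3)]), wavelengths = wl,
      meta = list(source = path))
}

.CONFIG_KEYS <- c("materials_registry", "database", "fit_band", "refine",
                  "correlation_floor", "sampling", "noise_sd", "band",
                  "lsf_fwhm", "grid_jitter", "seed", "verbosity")

#' Default run configuration
#'
#' @return Named list of configuration defaults.
#' @export
defaultRunConfig <- function() {
  list(materials_registry = NULL, database = NULL, fit_band = c(450, 700),
       refine = FALSE, correlation_floor = 0.8, sampling = 0.6,
       noise_sd = 0.01, band = c(450, 700), lsf_fwhm = 0.6,
       grid_jitter = 0.3, seed = NULL, verbosity = 1)
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; known keys override the defaults.
#'
#' @param path YAML path.
#' @return Named configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- defaultRunConfig()
  out[names(cfg)] <- cfg
  out
}
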