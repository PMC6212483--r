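# Decoding a measured spectrum into a diameter: centre-voxel selection,
# mirror-reference normalization, and best-fit search by Pearson correlation
# against the simulation database.

# Vectorised local-cubic (Catmull-Rom) interpolation of the rows of Y, sampled
# at x (uniform, increasing), onto the query points xout. Smooth simulated
# database rows are resampled with this (resampling the smooth side avoids
# distorting noisy measurements); the same routine serves single spectra.
.resampleRows <- function(Y, x, xout) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  n <- length(x)
  h <- diff(x)
  if (diff(range(h)) > 1e-6 * mean(h))
    stop("resampling requires a uniform source grid")
  h <- mean(h)
  if (any(xout < x[1] - 1e-9 | xout > x[n] + 1e-9))
    stop("query points outside the source grid")
  pos <- (xout - x[1]) / h
  i <- pmin(pmax(floor(pos), 0), n - 2L)  # 0-based left knot
  t <- pos - i
  i0 <- pmax(i, 1L); i3 <- pmin(i + 2L, n - 1L)  # clamped outer knots
  t2 <- t * t; t3 <- t2 * t
  w0 <- -0.5 * t + t2 - 0.5 * t3
  w1 <- 1 - 2.5 * t2 + 1.5 * t3
  w2 <- 0.5 * t + 2 * t2 - 1.5 * t3
  w3 <- -0.5 * t2 + 0.5 * t3
  out <- matrix(NA_real_, nrow = nrow(Y), ncol = length(xout))
  for (j in seq_along(xout)) {
    out[, j] <- w0[j] * Y[, i0[j]] + w1[j] * Y[, i[j] + 1L] +
      w2[j] * Y[, i[j] + 2L] + w3[j] * Y[, i3[j] + 1L]
  }
  out
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Local cubic interpolation; the new grid must lie within the old one.
#'
#' @param spectrum A [Spectrum-class] on a uniform grid.
#' @param wavelengths New grid (nm).
#' @return A [Spectrum-class].
#' @export
resampleSpectrum <- function(spectrum, wavelengths) {
  v <- .resampleRows(spectrum@values, spectrum@wavelengths, wavelengths)
  Spectrum(wavelengths, as.vector(v), meta = spectrum@meta)
}

#' Select the centre-voxel spectrum of a volumetric scan
#'
#' The geometric centre of the sphere is taken as the voxel with the maximum
#' total intensity (sum of raw counts over wavelengths). If that voxel lies on
#' any face of the scan volume the geometric centre was not captured and the
#' dataset is excluded (`status = "rejected_boundary"`). Exact intensity ties
#' resolve to the lowest `(i, j, k)` in lexicographic order (logged).
#'
#' @param stack A [ScanStack-class].
#' @return List with `spectrum` ([Spectrum-class] or `NULL`), `voxel`
#'   (`c(i, j, k)`), and `status` (`"accepted"` or `"rejected_boundary"`).
#' @export
selectCenterSpectrum <- function(stack) {
  validObject(stack)
  totals <- rowSums(stack@spectra)
  best <- which(totals == max(totals))
  dims <- stack@dims
  ijk <- cbind(i = (best - 1L) %% dims[1] + 1L,
               j = ((best - 1L) %/% dims[1]) %% dims[2] + 1L,
               k = (best - 1L) %/% (dims[1] * dims[2]) + 1L)
  ord <- order(ijk[, "i"], ijk[, "j"], ijk[, "k"])
  if (length(best) > 1L)
    message("selectCenterSpectrum: ", length(best),
            " voxels tied at maximum intensity; taking lowest (i,j,k)")
  pick <- ord[1L]
  vox <- as.integer(ijk[pick, ])
  row <- best[pick]
  onFace <- any(vox == 1L) || any(vox == dims)
  if (onFace)
    return(list(spectrum = NULL, voxel = vox, status = "rejected_boundary"))
  list(spectrum = Spectrum(stack@wavelengths, stack@spectra[row, ],
                           meta = c(stack@meta, list(voxel = vox))),
       voxel = vox, status = "accepted")
}

#' Normalize a raw spectrum by a mirror reference
#'
#' Pointwise ratio `raw / reference` on the raw spectrum's grid, removing the
#' source envelope and the spectral response of the detection path; the
#' output carries reflectance semantics. If the grids differ, the reference is
#' resampled onto the raw grid over the overlap.
#'
#' @param raw Raw [Spectrum-class].
#' @param reference Mirror-reference [Spectrum-class]; must be strictly
#'   positive over the overlap.
#' @param minOverlap Minimum acceptable overlap span, nm (default 100).
#' @return A normalized [Spectrum-class].
#' @export
normalizeSpectrum <- function(raw, reference, minOverlap = 100) {
  lo <- max(min(raw@wavelengths), min(reference@wavelengths))
  hi <- min(max(raw@wavelengths), max(reference@wavelengths))
  keep <- raw@wavelengths >= lo & raw@wavelengths <= hi
  if (!any(keep) || hi - lo < minOverlap)
    stop(sprintf(
      "wavelength overlap (%.1f nm) shorter than required %.1f nm",
      max(hi - lo, 0), minOverlap))
  wl <- raw@wavelengths[keep]
  ref <- if (isTRUE(all.equal(raw@wavelengths, reference@wavelengths)))
    reference@values[keep]
  else as.vector(.resampleRows(reference@values, reference@wavelengths, wl))
  if (any(ref <= 0))
    stop("reference spectrum must be strictly positive over the overlap")
  Spectrum(wl, raw@values[keep] / ref,
           meta = c(raw@meta, list(normalized = TRUE)))
}

# Pearson correlation of each row of Y against vector y.
.rowCor <- function(Y, y) {
  yc <- y - mean(y)
  Yc <- Y - rowMeans(Y)
  num <- as.vector(Yc %*% yc)
  num / sqrt(rowSums(Yc * Yc) * sum(yc * yc))
}

# Shared decode core over a query matrix (rows = spectra on grid wl).
.decodeBatch <- function(Y, wl, db, refine, fitBand, corFloor,
                         chunk = 1024L) {
  lo <- max(fitBand[1], min(db@wavelengths), min(wl))
  hi <- min(fitBand[2], max(db@wavelengths), max(wl))
  keep <- wl >= lo & wl <= hi
  if (sum(keep) < 16L)
    stop("spectrum does not overlap the database grid over the fit band")
  wlq <- wl[keep]
  D <- if (length(wlq) == length(db@wavelengths) &&
           isTRUE(all.equal(wlq, db@wavelengths)))
    db@spectra
  else .resampleRows(db@spectra, db@wavelengths, wlq)
  Dc <- D - rowMeans(D)
  Dn <- Dc / sqrt(rowSums(Dc * Dc))
  d <- db@diameters
  step <- if (length(d) > 1L) d[2] - d[1] else 0
  nq <- nrow(Y)
  outD <- numeric(nq); outR <- numeric(nq); outRef <- logical(nq)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    Q <- Y[s:e, keep, drop = FALSE]
    Qc <- Q - rowMeans(Q)
    Qn <- Qc / sqrt(rowSums(Qc * Qc))
    Rm <- Dn %*% t(Qn)  # n_db x n_chunk correlation matrix
    for (q in seq_len(e - s + 1L)) {
      r <- Rm[, q]
      best <- which(r == max(r))
      if (length(best) > 1L)
        message("decode: correlation tie; taking the smaller diameter")
      i <- best[1L]
      dHat <- d[i]; rBest <- r[i]; didRefine <- FALSE
      if (refine && i > 1L && i < length(d)) {
        den <- r[i - 1L] - 2 * r[i] + r[i + 1L]
        if (den < 0) {
          shift <- 0.5 * (r[i - 1L] - r[i + 1L]) / den
          shift <- max(-1, min(1, shift))
          dHat <- d[i] + shift * step
          didRefine <- TRUE
        }
      }
      outD[s + q - 1L] <- dHat
      outR[s + q - 1L] <- min(rBest, 1)
      outRef[s + q - 1L] <- didRefine
    }
  }
  status <- ifelse(outR < corFloor, "rejected_low_fit", "accepted")
  data.frame(diameter = outD, correlation = outR, r_squared = outR^2,
             refined = outRef, status = status, stringsAsFactors = FALSE)
}

#' Decode a spectrum against the simulation database
#'
#' Resamples the database rows onto the measurement grid over the fit band,
#' scores every candidate diameter by Pearson correlation, and returns the
#' argmax. Correlation is invariant under affine rescaling of the input, so
#' decoding works on envelope-scaled or normalized spectra alike. Ties break
#' toward the smaller diameter. With `refine = TRUE` a parabolic
#' interpolation of the correlation over the three diameters bracketing the
#' argmax yields a sub-grid estimate (clamped to the bracketing interval).
#'
#' @param spectrum A [Spectrum-class] overlapping the database grid.
#' @param db A [SpectrumDatabase-class].
#' @param refine Apply sub-grid parabolic refinement (default `FALSE`).
#' @param fitBand Wavelength band used for the fit (default `c(450, 700)`).
#' @param corFloor Minimum acceptable correlation (default 0.8); lower best
#'   fits return `status = "rejected_low_fit"`.
#' @return A [DecodeResult-class].
#' @examples
#' db <- buildDatabase(2990, 3010, 1, getMaterial("polystyrene"),
#'                     getMaterial("water"), seq(450, 700, by = 0.5))
#' sp <- Spectrum(wavelengths(db), spectraMatrix(db)[11, ])
#' decodeSpectrum(sp, db)
#' @export
decodeSpectrum <- function(spectrum, db, refine = FALSE,
                           fitBand = c(450, 700), corFloor = 0.8) {
  res <- .decodeBatch(matrix(spectrum@values, nrow = 1L),
                      spectrum@wavelengths, db, refine, fitBand, corFloor)
  if (res$status[1] == "rejected_low_fit")
    message(sprintf(
      "decode: best correlation %.3f below floor %.3f; rejected",
      res$correlation[1], corFloor))
  new("DecodeResult", diameter = res$diameter[1],
      correlation = res$correlation[1], rSquared = res$r_squared[1],
      refined = res$refined[1], status = res$status[1])
}

#' Decode many spectra sharing one wavelength grid
#'
#' Batch variant of [decodeSpectrum()] that resamples and standardizes the
#' database once and scores all queries by one correlation matrix product per
#' chunk; used for database self-consistency sweeps and Monte-Carlo studies.
#'
#' @param spectra Numeric matrix, one spectrum per row.
#' @param wavelengths Shared grid (nm).
#' @inheritParams decodeSpectrum
#' @return data.frame with columns `diameter`, `correlation`, `r_squared`,
#'   `refined`, `status`.
#' @export
decodeSpectra <- function(spectra, wavelengths, db, refine = FALSE,
                          fitBand = c(450, 700), corFloor = 0.8) {
  .decodeBatch(spectra, wavelengths, db, refine, fitBand, corFloor)
}

#' Decode a volumetric scan stack
#'
#' Composition of [selectCenterSpectrum()], [normalizeSpectrum()] and
#' [decodeSpectrum()]; rejection statuses propagate.
#'
#' @param stack A [ScanStack-class].
#' @param reference Mirror-reference [Spectrum-class] (required).
#' @inheritParams decodeSpectrum
#' @return A [DecodeResult-class] with `centerVoxel` set.
#' @export
decodeStack <- function(stack, reference, db, refine = FALSE,
                        fitBand = c(450, 700), corFloor = 0.8) {
  if (missing(reference) || is.null(reference))
    stop("a mirror reference spectrum is required to decode a scan stack")
  sel <- selectCenterSpectrum(stack)
  if (sel$status == "rejected_boundary")
    return(new("DecodeResult", status = "rejected_boundary",
               centerVoxel = sel$voxel))
  res <- decodeSpectrum(normalizeSpectrum(sel$spectrum, reference), db,
                        refine = refine, fitBand = fitBand,
                        corFloor = corFloor)
  res@centerVoxel <- sel$voxel
  res
}
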