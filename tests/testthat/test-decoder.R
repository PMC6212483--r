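test_that("centre selection picks the maximum-intensity voxel", {
  dims <- c(9L, 9L, 10L)
  totals <- rep(1, prod(dims))
  totals[voxelRow(4L, 4L, 5L, dims)] <- 10
  sel <- selectCenterSpectrum(stackFromTotals(totals, dims))
  expect_identical(sel$status, "accepted")
  expect_identical(sel$voxel, c(4L, 4L, 5L))
  expect_s4_class(sel$spectrum, "Spectrum")
})

test_that("a peak on any stack face means the centre was missed", {
  dims <- c(9L, 9L, 10L)
  for (vox in list(c(1L, 4L, 5L), c(5L, 9L, 5L), c(5L, 5L, 10L))) {
    totals <- rep(1, prod(dims))
    totals[voxelRow(vox[1], vox[2], vox[3], dims)] <- 10
    sel <- selectCenterSpectrum(stackFromTotals(totals, dims))
    expect_identical(sel$status, "rejected_boundary")
    expect_identical(sel$voxel, vox)
  }
})

test_that("intensity ties resolve to the lowest (i,j,k) lexicographically, logged", {
  dims <- c(5L, 5L, 5L)
  totals <- rep(1, prod(dims))
  totals[voxelRow(4L, 2L, 2L, dims)] <- 10
  totals[voxelRow(2L, 4L, 4L, dims)] <- 10
  expect_message(sel <- selectCenterSpectrum(stackFromTotals(totals, dims)),
                 "tied")
  expect_identical(sel$voxel, c(2L, 4L, 4L))
})

test_that("mirror normalization is exact for identical and synthetic inputs", {
  wl <- seq(450, 700, by = 0.6)
  ref <- Spectrum(wl, 2 + sin(wl / 40))
  expect_equal(intensities(normalizeSpectrum(ref, ref)), rep(1, length(wl)))
  truth <- reflectanceSpectrum(sphereStack(3000, psMat(), waterMat()), wl)
  raw <- Spectrum(wl, intensities(ref) * intensities(truth))
  expect_equal(intensities(normalizeSpectrum(raw, ref)),
               intensities(truth), tolerance = 1e-12)
})

test_that("normalization guards: coverage and positivity", {
  a <- Spectrum(seq(450, 500, 1), rep(1, 51))
  b <- Spectrum(seq(600, 700, 1), rep(1, 101))
  expect_error(normalizeSpectrum(a, b), "overlap")
  wl <- seq(450, 700, 1)
  bad <- Spectrum(wl, c(rep(1, 100), 0, rep(1, 150)))
  expect_error(normalizeSpectrum(Spectrum(wl, rep(1, 251)), bad),
               "strictly positive")
})

test_that("every database row decodes to itself with r = 1", {
  db <- tinyDB()
  res <- decodeSpectra(spectraMatrix(db), wavelengths(db), db)
  expect_identical(res$diameter, diameters(db))
  expect_true(all(res$correlation > 1 - 1e-12))
  expect_true(all(res$status == "accepted"))
})

test_that("a noiseless off-grid spectrum decodes within one database step", {
  db <- tinyDB(2999, 3001, 0.1, seq(450, 700, by = 0.1))
  sp <- reflectanceSpectrum(sphereStack(3000.05, psMat(), waterMat()),
                            wavelengths(db))
  expect_lt(abs(diameter(decodeSpectrum(sp, db)) - 3000.05), 0.1)
  # sub-grid parabolic refinement gets closer than the grid
  refined <- decodeSpectrum(sp, db, refine = TRUE)
  expect_true(refined@refined)
  expect_lt(abs(diameter(refined) - 3000.05), 0.05)
})

test_that("decoding is invariant under affine rescaling of the spectrum", {
  db <- tinyDB()
  sp <- Spectrum(wavelengths(db), spectraMatrix(db)[7, ])
  scaled <- Spectrum(wavelengths(db), 37.5 * intensities(sp) + 4.2)
  r1 <- decodeSpectrum(sp, db); r2 <- decodeSpectrum(scaled, db)
  expect_identical(diameter(r1), diameter(r2))
  expect_equal(correlationScore(r1), correlationScore(r2),
               tolerance = 1e-12)
})

test_that("a best fit below the correlation floor is rejected and logged", {
  db <- tinyDB()
  set.seed(99)
  noise <- Spectrum(wavelengths(db), runif(length(wavelengths(db))))
  expect_message(res <- decodeSpectrum(noise, db), "below floor")
  expect_identical(decodeStatus(res), "rejected_low_fit")
  expect_false(is.na(correlationScore(res)))
})

test_that("correlation ties break toward the smaller diameter", {
  db <- tinyDB(dStep = 5)
  dup <- db
  dup@spectra[3, ] <- dup@spectra[2, ]  # two diameters, identical spectra
  sp <- Spectrum(wavelengths(dup), dup@spectra[2, ])
  expect_message(res <- decodeSpectrum(sp, dup), "smaller diameter")
  expect_identical(diameter(res), diameters(dup)[2])
})

test_that("diameters 3 nm apart at 0.6-nm sampling always decode distinctly", {
  db <- buildDatabase(2995, 4010, 0.1, psMat(), waterMat(),
                      seq(450, 700, by = 0.1))
  wl <- seq(450, 700, by = 0.6)
  dSweep <- seq(3000, 4000, by = 100)
  Y <- t(vapply(c(dSweep, dSweep + 3), function(d)
    stackRT(sphereStack(d, psMat(), waterMat()), wl)$R,
    numeric(length(wl))))
  res <- decodeSpectra(Y, wl, db)
  lo <- res$diameter[seq_along(dSweep)]
  hi <- res$diameter[seq_along(dSweep) + length(dSweep)]
  expect_true(all(hi > lo))
  expect_true(all(abs(lo - dSweep) < 0.2) && all(abs(hi - dSweep - 3) < 0.2))
})

test_that("stack decoding composes selection, normalization and fitting", {
  inst <- InstrumentModel(noiseSd = 0.005)
  acq <- acquireStack(inst, 3000, seed = 5)
  db <- tinyDB(2995, 3005, 0.1, seq(450, 700, by = 0.1))
  res <- decodeStack(acq$stack, acq$reference, db)
  expect_identical(decodeStatus(res), "accepted")
  expect_lt(abs(diameter(res) - 3000), 1)
  expect_length(res@centerVoxel, 3L)
})

test_that("stack decoding propagates the boundary rejection and needs a reference", {
  inst <- InstrumentModel(noiseSd = 0.005)
  acq <- acquireStack(inst, 3000, positionOffset = c(0, 0, 1500), seed = 6)
  db <- tinyDB()
  res <- decodeStack(acq$stack, acq$reference, db)
  expect_identical(decodeStatus(res), "rejected_boundary")
  expect_true(is.na(diameter(res)))
  expect_error(decodeStack(acq$stack, NULL, db), "reference")
})
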