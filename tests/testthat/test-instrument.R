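test_that("with no noise the pipeline identity holds: normalize(raw, ref) = blurred truth", {
  inst <- InstrumentModel(noiseSd = 0, gridJitter = 0)
  acq <- acquireSpectrum(inst, 3000, seed = 1)
  norm <- normalizeSpectrum(acq$raw, acq$reference)
  expect_equal(intensities(norm), intensities(acq$truth), tolerance = 1e-12)
  # reference division removes any strictly positive envelope exactly
  env2 <- function(wl) 0.5 + ((wl - 500) / 300)^2
  inst2 <- InstrumentModel(noiseSd = 0, gridJitter = 0, envelope = env2)
  acq2 <- acquireSpectrum(inst2, 3000, seed = 1)
  expect_equal(intensities(normalizeSpectrum(acq2$raw, acq2$reference)),
               intensities(acq2$truth), tolerance = 1e-12)
})

test_that("acquisitions are bit-identical under a fixed seed", {
  inst <- InstrumentModel()
  a <- acquireSpectrum(inst, 3200, seed = 77)
  b <- acquireSpectrum(inst, 3200, seed = 77)
  expect_identical(intensities(a$raw), intensities(b$raw))
  expect_identical(wavelengths(a$raw), wavelengths(b$raw))
  c <- acquireSpectrum(inst, 3200, seed = 78)
  expect_false(identical(intensities(a$raw), intensities(c$raw)))
})

test_that("synthetic acquisitions decode back to the true diameter", {
  inst <- InstrumentModel()  # default 1% noise
  db <- tinyDB(2995, 3005, 0.1, seq(450, 700, by = 0.1))
  for (seed in 1:5) {
    acq <- acquireSpectrum(inst, 3000, seed = seed)
    res <- decodeSpectrum(normalizeSpectrum(acq$raw, acq$reference), db)
    expect_identical(decodeStatus(res), "accepted")
    expect_lt(abs(diameter(res) - 3000), 1)
  }
})

test_that("closed generator-decoder loop is unbiased at low noise", {
  inst <- InstrumentModel(noiseSd = 0.01)
  db <- tinyDB(2995, 3005, 0.1, seq(450, 700, by = 0.1))
  dec <- vapply(1:30, function(i) {
    acq <- acquireSpectrum(inst, 3000, seed = 1000 + i)
    diameter(decodeSpectrum(normalizeSpectrum(acq$raw, acq$reference), db))
  }, numeric(1))
  expect_lt(abs(mean(dec) - 3000), 0.1)  # bias below the database step
})

test_that("stack acquisition places the intensity peak at the offset position", {
  inst <- InstrumentModel(noiseSd = 0.005)
  acq <- acquireStack(inst, 3000, seed = 2)
  expect_identical(acq$stack@dims, c(9L, 9L, 10L))
  expect_identical(acq$stack@spacing, c(100, 200))
  sel <- selectCenterSpectrum(acq$stack)
  expect_identical(sel$status, "accepted")
  expect_identical(sel$voxel[1:2], c(5L, 5L))
  # a 300-nm lateral offset moves the peak by 3 voxels
  acq2 <- acquireStack(inst, 3000, positionOffset = c(300, 0, 0), seed = 2)
  sel2 <- selectCenterSpectrum(acq2$stack)
  expect_identical(sel2$voxel[1], 8L)
  # an offset beyond the half-extent pushes the peak onto a face
  acq3 <- acquireStack(inst, 3000, positionOffset = c(0, 0, 1500), seed = 2)
  expect_identical(selectCenterSpectrum(acq3$stack)$status,
                   "rejected_boundary")
})

test_that("acquisition outside the material validity band errors", {
  inst <- InstrumentModel(band = c(300, 700))
  expect_error(acquireSpectrum(inst, 3000, seed = 1), "valid range")
})

test_that("barcoded cells are re-identified at every timepoint", {
  inst <- InstrumentModel()
  sc <- makeBarcodeScenario(6, c(3000, 3400), timepoints = 1:5,
                            instrument = inst, seed = 21)
  expect_identical(nrow(sc@cells), 6L)
  expect_true(all(diff(sc@cells$diameter) >= 40))
  db <- buildDatabase(2980, 3420, 1, psMat(), waterMat(),
                      seq(450, 700, by = 0.2))
  tr <- trackBarcodes(sc, db)
  expect_identical(nrow(tr$assignments), 30L)
  expect_identical(tr$confusionRate, 0)
  expect_true(all(tr$assignments$correct))
})

test_that("cells closer than the decoder precision are confused", {
  inst <- InstrumentModel()
  sc <- makeBarcodeScenario(2, c(3000, 3000.12), timepoints = 1:3,
                            instrument = inst, seed = 4, minSpacing = 0.05)
  db <- tinyDB(2995, 3005, 0.5, seq(450, 700, by = 0.2))
  tr <- trackBarcodes(sc, db)
  expect_gt(tr$confusionRate, 0)
})

test_that("scenario generation is seeded and capacity-checked", {
  inst <- InstrumentModel()
  s1 <- makeBarcodeScenario(3, c(3000, 3200), 1:2, inst, seed = 9)
  s2 <- makeBarcodeScenario(3, c(3000, 3200), 1:2, inst, seed = 9)
  expect_identical(s1@cells, s2@cells)
  expect_identical(intensities(s1@measurements[[1]][[1]]$raw),
                   intensities(s2@measurements[[1]][[1]]$raw))
  expect_error(makeBarcodeScenario(50, c(3000, 3200), 1, inst, seed = 1),
               "capacity")
})
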