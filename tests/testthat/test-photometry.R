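test_that("fluorophore signal is linear in concentration, yield and cross-section", {
  base <- FluorophoreModel(0.5, 0.01, 1e-4, effectivePath = 100)
  expect_equal(fluorophoreSignal(FluorophoreModel(0.5, 0.01, 2e-4, 100)),
               2 * fluorophoreSignal(base))
  expect_equal(fluorophoreSignal(FluorophoreModel(1.0, 0.01, 1e-4, 100)),
               2 * fluorophoreSignal(base))
  expect_equal(fluorophoreSignal(FluorophoreModel(0.5, 0.02, 1e-4, 100)),
               2 * fluorophoreSignal(base))
})

test_that("the calibrated path length solves the 700x anchor in closed form", {
  # scalar oracle: L = R / (700 * Phi * sigma * C * N_A / 1e24)
  Lref <- 0.035 / (700 * 0.92 * 0.0121 * 1e-4 * 6.02214076e23 / 1e24)
  expect_equal(calibrateEffectivePath(probeReflectance = 0.035), Lref)
  # package default anchors on the computed 8-um band-peak reflectance
  R8 <- peakReflectance(8000, psMat(), waterMat())
  expect_equal(brightnessRatio(R8, fluorescein(1e-4)), 700,
               tolerance = 1e-9)
})

test_that("brightness ratios follow the printed photophysics from the anchor", {
  R8 <- peakReflectance(8000, psMat(), waterMat())
  expect_equal(brightnessRatio(R8, fluorescein(5e-3)), 14,
               tolerance = 1e-9)
  # 700 * (0.92*0.0121)/(0.6*0.0091) * (1e-4/1e-5), scalar arithmetic
  oracle <- 700 * (0.92 * 0.0121) / (0.6 * 0.0091) * 10
  expect_equal(brightnessRatio(R8, egfp(1e-5)), oracle, tolerance = 1e-9)
  expect_equal(oracle, 14272, tolerance = 1e-4)
  # ratio scales inversely with concentration (exact)
  expect_equal(brightnessRatio(R8, fluorescein(2e-4)),
               brightnessRatio(R8, fluorescein(1e-4)) / 2)
  zero <- FluorophoreModel(0.5, 0.01, 1e-4, 100)
  zero@concentration <- 0
  expect_error(brightnessRatio(R8, zero), "zero")
})

test_that("multiplexing capacity counts spacing slots in the diameter range", {
  expect_identical(multiplexingCapacity(1000, 3), 333L)
  expect_identical(multiplexingCapacity(1000, 3, 2), 166L)
  expect_identical(multiplexingCapacity(0, 3), 0L)
  # monotone: non-increasing in precision, non-decreasing in range
  caps <- vapply(1:8, function(p) multiplexingCapacity(1000, p), integer(1))
  expect_true(all(diff(caps) <= 0))
  caps2 <- vapply(seq(100, 2000, 100), function(r)
    multiplexingCapacity(r, 3), integer(1))
  expect_true(all(diff(caps2) >= 0))
})

test_that("SNR is mean signal over background standard deviation", {
  bg <- c(1, 3, 1, 3)  # sd = 2 exactly? no: sd(c(1,3,1,3)) = 1.1547
  expect_equal(snr(10, bg), 10 / sd(bg))
  expect_equal(snr(c(8, 12), c(0, 4, 0, 4)), 10 / sd(c(0, 4, 0, 4)))
  expect_equal(snr(5 * c(8, 12), 5 * bg), snr(c(8, 12), bg))  # scale-free
  expect_error(snr(10, c(2, 2, 2)), "zero variance")
  expect_error(snr(10, 2), "at least 2")
})

test_that("exponential attenuation fits recover the 1/e length", {
  z <- seq(0, 200, by = 10)
  fit <- attenuationFit(z, 3 * exp(-z / 50))
  expect_false(fit$saturated)
  expect_equal(fit$length, 50, tolerance = 1e-6)
  expect_equal(fit$amplitude, 3, tolerance = 1e-6)
  expect_gt(fit$rSquared, 1 - 1e-10)
  set.seed(8)
  noisy <- 3 * exp(-z / 50) * (1 + rnorm(length(z), sd = 0.1))
  fitN <- attenuationFit(z, abs(noisy))
  expect_lt(abs(fitN$length - 50) / 50, 0.10)
  const <- attenuationFit(z, rep(2, length(z)))
  expect_true(const$saturated)
  expect_identical(const$length, Inf)
  expect_error(attenuationFit(z, -3 * exp(-z / 50)), "positive")
  expect_error(attenuationFit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Monte-Carlo precision is quantization-limited without noise", {
  db <- buildDatabase(3995, 4005, 0.1, silicaMat(), waterMat(),
                      seq(450, 700, by = 0.1))
  quiet <- InstrumentModel(noiseSd = 0, gridJitter = 0)
  rep0 <- precisionMonteCarlo(4000, quiet, db, n = 5, seed = 3)
  expect_lte(rep0@maxSpread, 0.1)  # database step
})

test_that("Monte-Carlo reports are deterministic and tighten as noise falls", {
  db <- buildDatabase(3995, 4005, 0.1, silicaMat(), waterMat(),
                      seq(450, 700, by = 0.1))
  inst <- InstrumentModel(noiseSd = 0.05)
  r1 <- precisionMonteCarlo(4000, inst, db, n = 8, seed = 11)
  r2 <- precisionMonteCarlo(4000, inst, db, n = 8, seed = 11)
  expect_identical(r1, r2)
  sds <- vapply(c(0.05, 0.01, 0), function(ns)
    precisionMonteCarlo(4000, InstrumentModel(noiseSd = ns), db,
                        n = 8, seed = 11)@sdDiameter,
    numeric(1))
  expect_true(all(diff(sds) <= 0))
  expect_error(precisionMonteCarlo(4000, inst, db, n = 1, seed = 1),
               "at least 2")
})
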