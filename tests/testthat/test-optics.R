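test_that("interface reflectance follows the normal-incidence Fresnel formula", {
  expect_identical(interfaceReflectance(1.33, 1.33), 0)
  # ((1.33 - 1.59) / (1.33 + 1.59))^2, worked out by hand
  expect_equal(interfaceReflectance(1.33, 1.59), 0.00792831675,
               tolerance = 1e-8)
  set.seed(11)
  a <- runif(50, 1, 2.5); b <- runif(50, 1, 2.5)
  expect_equal(interfaceReflectance(a, b), interfaceReflectance(b, a))
  expect_error(interfaceReflectance(-1, 1.5), "positive")
  expect_error(interfaceReflectance(1.5, 0), "positive")
})

test_that("transfer matrix agrees with the closed-form Airy single-film oracle", {
  set.seed(42)
  n <- 2000
  n0 <- runif(n, 1, 2); n1 <- runif(n, 1, 2.5); n2 <- runif(n, 1, 2)
  d <- runif(n, 100, 20000); lam <- runif(n, 400, 700)
  worst <- 0
  for (i in seq_len(n)) {
    st <- LayerStack(Layer(n0[i], Inf), Layer(n1[i], d[i]), Layer(n2[i], Inf))
    R <- stackRT(st, lam[i])$R
    worst <- max(worst, abs(R - airyReflectance(n0[i], n1[i], n2[i],
                                                d[i], lam[i])))
  }
  expect_lt(worst, 1e-10)
})

test_that("lossless stacks conserve energy: R + T = 1", {
  wl <- seq(450, 700, by = 0.5)
  st3 <- sphereStack(3000, psMat(), waterMat())
  rt <- stackRT(st3, wl)
  expect_lt(max(abs(rt$R + rt$T - 1)), 1e-10)
  st5 <- sphereStack(3000, psMat(), waterMat(), list(c(5, 1.50)))
  rt5 <- stackRT(st5, wl)
  expect_lt(max(abs(rt5$R + rt5$T - 1)), 1e-10)
  set.seed(3)
  stR <- LayerStack(Layer(1.4, Inf), Layer(runif(1, 1, 2), 750),
                    Layer(runif(1, 1, 2), 1300), Layer(runif(1, 1, 2), 90),
                    Layer(1.33, Inf))
  rtR <- stackRT(stR, wl)
  expect_lt(max(abs(rtR$R + rtR$T - 1)), 1e-10)
})

test_that("symmetric etalon reflectance vanishes at round-trip-integer wavelengths", {
  d <- 3000
  # solve 2 n(lambda) d = m lambda near 589 nm with the dispersive index
  m <- round(2 * refractiveIndex(psMat(), 589) * d / 589)
  g <- function(l) 2 * refractiveIndex(psMat(), l) * d - m * l
  lamStar <- uniroot(g, c(560, 620), tol = 1e-10)$root
  st <- sphereStack(d, psMat(), waterMat())
  expect_lt(stackRT(st, lamStar)$R, 1e-6)
})

test_that("fringe count over the band grows strictly with core thickness", {
  wl <- seq(450, 700, by = 0.1)
  counts <- vapply(c(1000, 2000, 3000, 5000, 8000), function(d)
    countFringes(reflectanceSpectrum(sphereStack(d, psMat(), waterMat()),
                                     wl)),
    integer(1))
  expect_true(all(diff(counts) > 0))
})

test_that("sphereStack builds mirror-symmetric stacks with the stated geometry", {
  st3 <- sphereStack(3000, psMat(), waterMat())
  expect_length(st3@layers, 3L)
  expect_identical(st3@layers[[2]]@thickness, 3000)
  st5 <- sphereStack(3000, psMat(), waterMat(), list(c(5, 1.50)))
  expect_length(st5@layers, 5L)
  th <- vapply(st5@layers, function(l) l@thickness, numeric(1))
  expect_identical(sum(th[is.finite(th)]), 3010)  # diameter grows by 10 nm
  # mirror symmetry of thicknesses and indices for arbitrary adlayers
  st7 <- sphereStack(2500, psMat(), waterMat(),
                     list(c(5, 1.50), c(12, 1.44)))
  th7 <- vapply(st7@layers, function(l) l@thickness, numeric(1))
  n7 <- vapply(st7@layers, function(l)
    refractiveIndex(l@material, 550), numeric(1))
  expect_identical(th7, rev(th7))
  expect_identical(n7, rev(n7))
  expect_error(sphereStack(-5, psMat(), waterMat()), "positive")
})

test_that("stack invariants are enforced", {
  expect_error(LayerStack(Layer(1.33, Inf), Layer(1.59, 3000)),
               "at least 3 layers")
  expect_error(LayerStack(Layer(1.33, 100), Layer(1.59, 3000),
                          Layer(1.33, Inf)), "semi-infinite")
  expect_error(Layer(1.5, -10), "positive")
})

test_that("simulated reflectance stays within [0, 1] and band peak is ~3.4%", {
  wl <- seq(450, 700, by = 0.1)
  sp <- reflectanceSpectrum(sphereStack(3000, psMat(), waterMat()), wl)
  expect_true(all(intensities(sp) >= 0 & intensities(sp) <= 1))
  expect_equal(max(intensities(sp)), 0.0338, tolerance = 0.01)
})
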