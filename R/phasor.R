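# Phasor representation: the reflectance spectrum of an etalon is sinusoidal
# in wavenumber k = 1/lambda with frequency equal to the round-trip group
# optical thickness (~ 2 n_g d). The phasor point (frequency as radius, phase
# at the 500-nm reference as angle) identifies the diameter uniquely.

.wrap2pi <- function(x) x %% (2 * pi)
.wrapPi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

# Linear LS fit of v ~ A + c*cos(2 pi f k) + s*sin(2 pi f k) for fixed f.
.cosFit <- function(k, v, f) {
  X <- cbind(1, cos(2 * pi * f * k), sin(2 * pi * f * k))
  co <- stats::.lm.fit(X, v)$coefficients
  res <- v - X %*% co
  list(coef = co, rss = sum(res^2))
}

#' Map a spectrum onto its phasor point
#'
#' Resamples the spectrum onto a uniform wavenumber grid, detrends with a
#' low-order polynomial in k to remove envelope residue, seeds the fringe
#' frequency from the peak of the zero-padded discrete spectrum, and refines
#' it by least squares on the model `R(k) = A + B cos(2 pi f k + phi0)`.
#' The reported phase is evaluated at the reference wavenumber
#' `kRef = 1/500 nm^-1` and wrapped to `[0, 2 pi)`.
#'
#' @param spectrum A [Spectrum-class] covering at least 3 fringe periods.
#' @param detrendOrder Polynomial order of the detrend in k (default 2).
#' @param kRef Reference wavenumber (default `1/500` nm^-1).
#' @return A [PhasorPoint-class].
#' @examples
#' st <- sphereStack(3000, getMaterial("polystyrene"), getMaterial("water"))
#' toPhasor(reflectanceSpectrum(st, seq(450, 700, by = 0.1)))
#' @export
toPhasor <- function(spectrum, detrendOrder = 2, kRef = 1 / 500) {
  wl <- spectrum@wavelengths
  v <- spectrum@values
  if (length(wl) < 32L) stop("spectrum too short for phasor analysis")
  k <- rev(1 / wl)
  v <- rev(v)
  ku <- seq(k[1], k[length(k)], length.out = length(k))
  vu <- stats::spline(k, v, xout = ku)$y
  # detrend for the frequency seed only
  X <- stats::poly(ku, detrendOrder)
  det <- stats::lm.fit(cbind(1, X), vu)$residuals
  nfft <- 8L * 2L^ceiling(log2(length(ku)))
  amp <- Mod(stats::fft(c(det, rep(0, nfft - length(ku)))))[1:(nfft %/% 2)]
  dk <- ku[2] - ku[1]
  freqs <- (seq_len(nfft %/% 2) - 1L) / (nfft * dk)
  pk <- which.max(amp[-1L]) + 1L
  f0 <- freqs[pk]
  span <- ku[length(ku)] - ku[1]
  if (f0 * span < 3)
    stop(sprintf(
      "spectrum covers only %.2f fringe periods in band (need >= 3)",
      f0 * span))
  # refine within one unpadded DFT bin around the seed
  obj <- function(f) .cosFit(ku, vu, f)$rss
  f <- stats::optimize(obj, interval = c(f0 - 1 / span, f0 + 1 / span),
                       tol = 1e-4 * dk)$minimum
  fit <- .cosFit(ku, vu, f)
  co <- fit$coef
  B <- sqrt(co[2]^2 + co[3]^2)
  tss <- sum((det - mean(det))^2)
  if (!is.finite(fit$rss) || B <= 0 || (tss > 0 && 1 - fit$rss / tss < 0.1))
    stop(sprintf(
      "phasor fit did not converge (f=%.4g nm, amplitude=%.3g, residual R^2=%.3f)",
      f, B, if (tss > 0) 1 - fit$rss / tss else NA_real_))
  phi0 <- atan2(-co[3], co[2])
  new("PhasorPoint", frequency = f,
      phase = .wrap2pi(2 * pi * f * kRef + phi0),
      amplitude = unname(B), offset = unname(co[1]))
}

#' Separation between two phasor points
#'
#' Signed differences `p1 - p2`: frequency difference in nm and phase
#' difference wrapped to `(-pi, pi]`. Antisymmetric:
#' `phasorSeparation(a, b) = -phasorSeparation(b, a)`.
#'
#' @param p1,p2 [PhasorPoint-class] objects.
#' @return Named numeric `c(dFrequency, dPhase)`.
#' @export
phasorSeparation <- function(p1, p2) {
  c(dFrequency = p1@frequency - p2@frequency,
    dPhase = .wrapPi(p1@phase - p2@phase))
}
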