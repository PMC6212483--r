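# Independent oracles and small fixture builders used across tests.

# Closed-form Airy reflectance of a single dielectric film n0 | n1(d) | n2 at
# normal incidence: amplitude reflectance
#   r = (r01 + r12 e^{2 i delta}) / (1 + r01 r12 e^{2 i delta}),
# delta = 2 pi n1 d / lambda. Independent of the transfer-matrix code path.
airyReflectance <- function(n0, n1, n2, d, lambda) {
  r01 <- (n0 - n1) / (n0 + n1)
  r12 <- (n1 - n2) / (n1 + n2)
  ph <- exp(2i * 2 * pi * n1 * d / lambda)
  Mod((r01 + r12 * ph) / (1 + r01 * r12 * ph))^2
}

psMat <- function() getMaterial("polystyrene")
waterMat <- function() getMaterial("water")
silicaMat <- function() getMaterial("fused_silica")

# small polystyrene-in-water database around 3 um
tinyDB <- function(dMin = 2990, dMax = 3010, dStep = 1,
                   wavelengths = seq(450, 700, by = 0.5))
  buildDatabase(dMin, dMax, dStep, psMat(), waterMat(), wavelengths)

# location of the local maximum nearest `target` (parabolic refinement);
# independent re-implementation for fringe-tracking checks
peakNearOracle <- function(wl, v, target) {
  i <- which(diff(sign(diff(v))) == -2) + 1L
  i <- i[which.min(abs(wl[i] - target))]
  wl[i] + 0.5 * (v[i - 1] - v[i + 1]) /
    (v[i - 1] - 2 * v[i] + v[i + 1]) * (wl[2] - wl[1])
}

# a ScanStack built directly from per-voxel total intensities (flat spectra)
stackFromTotals <- function(totals, dims = c(9L, 9L, 10L), nwl = 20L) {
  wl <- seq(500, 600, length.out = nwl)
  spec <- matrix(rep(totals / nwl, each = 1), nrow = length(totals),
                 ncol = nwl)
  new("ScanStack", dims = as.integer(dims), spacing = c(100, 200),
      spectra = spec, wavelengths = wl, meta = list())
}

voxelRow <- function(i, j, k, dims) i + (j - 1L) * dims[1] +
  (k - 1L) * dims[1] * dims[2]
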