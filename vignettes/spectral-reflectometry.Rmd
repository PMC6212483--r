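---
title: "Spectral reflectometry of microsphere probes: models and methods"
author: "SpeRe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral reflectometry of microsphere probes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpeRe)
```

## The measurement principle

A ray focused at the centre of a dielectric sphere strikes both surfaces at
normal incidence. Optically, the sphere is therefore equivalent to a
plane-parallel film whose thickness equals the diameter *d*: a Fabry–Pérot
etalon. Its reflectance spectrum, plotted against wavenumber $k = 1/\lambda$,
is very nearly sinusoidal,

$$R(k) \approx A + B\,\cos(2\pi f k + \varphi_0),$$

with fringe frequency $f \approx 2 n_g d$ set by the round-trip *group*
optical thickness ($n_g = n - \lambda\,dn/d\lambda$). Both the frequency and
the phase of the fringes move smoothly and monotonically with $d$, so a
measured spectrum pins the diameter to nanometre precision — three orders of
magnitude below the diffraction limit. The package implements the full
chain: forward simulation, database decoding, phasor coordinates,
microenvironmental sensing, photometric comparisons, and a synthetic
instrument that makes every stage testable offline.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do not
demonstrate about real measurements.

## Optics core

### Materials

Dispersion is modelled per material as Sellmeier, Cauchy, or constant, with
coefficients in a human-readable YAML registry
(`inst/extdata/materials.yaml`):

* **polystyrene** — a one-term Sellmeier fit ($B = 1.4435$,
  $C = 0.020216\,\mu m^2$), giving $n(589) = 1.5915$;
* **water** — a four-term visible-range Sellmeier fit, $n(589) = 1.3334$;
* **fused silica** — the standard three-term Sellmeier, $n(589) = 1.4584$;
* **streptavidin layer** (1.50) and **PDMS** (1.41) — non-dispersive
  constants. Protein layers and polymer matrices are characterised in the
  literature by single values at visible wavelengths; their dispersion is
  negligible at the 5-nm–scale thicknesses involved. The PDMS value is a
  literature constant, configurable through the registry.

Evaluation outside a material's declared validity range is an error naming
the material and its bounds. All wavelengths are vacuum nanometres.
`groupIndex()` uses the analytic derivative of each model.

### Transfer matrix

`stackRT()` multiplies the $2\times2$ characteristic matrices of the
internal layers,

$$M_j = \begin{pmatrix} \cos\delta_j & i\sin\delta_j/n_j \\
        i n_j \sin\delta_j & \cos\delta_j \end{pmatrix},
        \qquad \delta_j = \frac{2\pi n_j d_j}{\lambda},$$

between the two semi-infinite media. Only real (lossless) indices are
supported, so $R + T = 1$ holds to machine precision and is asserted in the
tests; absorbing materials are rejected by design. Normal incidence is taken
as exact — the centred-ray/slab analogy — and vector-diffraction corrections
are out of scope. The test suite checks the solver against an independently
coded closed-form Airy formula for single films (max $|\Delta R| <
10^{-10}$ over $10^4$ random parameter draws), and checks the symmetric
etalon anti-resonance ($R \to 0$ where $2 n(\lambda^*) d = m\lambda^*$).

The band-peak reflectance of a polystyrene sphere in water over 450–700 nm
computes to ~3.4%. The quoted "total reflectance ~3.5%" of such probes is
interpreted here as the peak constructive-interference reflectance
($\approx 4r^2$ evaluated where dispersion is strongest at the blue end of
the band), the reading that matches the number; band-averaged or
energy-integrated readings would be about half that.

## Spectrum database and decoder

`buildDatabase()` simulates one spectrum per diameter on a constant step.
The packaged defaults use the 450–700 nm measurement band at 0.1 nm and
whatever diameter window the analysis needs; full 1–20 µm builds are
supported but large, so the examples and tests bound their windows. A build
is deterministic and each row is bit-for-bit the direct simulation at that
diameter.

Decoding follows the measurement workflow:

1. **Centre selection** (`selectCenterSpectrum()`): the voxel with the
   maximum total intensity (sum of raw counts over wavelengths — the
   reduction is a package choice, as "maximum intensity" admits several) is
   taken as the sphere centre. If it lies on a face of the scan volume the
   centre was not captured and the dataset is excluded
   (`rejected_boundary`). Exact ties resolve to the lowest $(i,j,k)$
   lexicographically and are logged.
2. **Normalization** (`normalizeSpectrum()`): pointwise division by the
   mirror reference removes the source envelope. The reference must be
   strictly positive over an overlap of at least 100 nm (configurable).
3. **Correlation fit** (`decodeSpectrum()`): database rows are resampled to
   the measurement grid and scored by Pearson correlation over the fit band
   (default 450–700 nm); the argmax diameter wins. Correlation is invariant
   under affine rescaling, so uncalibrated detector units decode
   identically. Ties break toward the smaller diameter, deterministically.
   Best fits below the correlation floor (default 0.8, chosen below all
   realistic in-focus fits, whose $R^2$ exceeds 0.95) are
   `rejected_low_fit`. The reported $R^2$ is the squared Pearson r of
   spectrum versus fit, and is labelled as such.

Resampling direction: the smooth *simulated* rows are interpolated onto the
noisy measurement grid — never the reverse — so measurement noise is not
smeared by interpolation. The interpolant is a vectorised local cubic
(Catmull–Rom), chosen because decoding sweeps resample up to $10^4$ rows per
acquisition and a per-vector spline would dominate the runtime; on the
0.1-nm simulation grids its error is orders of magnitude below the noise
floor.

Sub-grid refinement (parabolic interpolation of the correlation over the
three bracketing diameters, clamped to that interval) is available but off
by default: grid-resolution fits are the reference behaviour, and the
refinement exists for precision studies.

Two decoder properties anchor the precision claims: noiseless spectra
sampled at 0.6 nm whose diameters differ by 3 nm or more always decode to
distinct database entries (swept over 3–4 µm), and the closed
generator–decoder loop is unbiased within the 0.1-nm database step at 1%
noise.

## Phasor representation

`toPhasor()` resamples the spectrum onto a uniform wavenumber grid (the
acquisition grid is uniform in wavelength, so it is *not* uniform in $k$),
removes a 2nd-order polynomial trend in $k$ (envelope residue; order
configurable), seeds the frequency from the peak of the zero-padded discrete
spectrum, and refines it by least squares on
$R(k) = A + B\cos(2\pi f k + \varphi_0)$ — a linear solve for
$(A, B\cos\varphi_0, B\sin\varphi_0)$ inside a 1-D search over $f$ within
one DFT bin of the seed. The phase is reported at the reference wavenumber
$k_{ref} = 1/500\,\mathrm{nm}^{-1}$, wrapped to $[0, 2\pi)$. Spectra
covering fewer than three fringe periods are rejected (the frequency would
be ill-conditioned); note a 1-µm sphere needs the full 400–700 nm
simulation band to show three periods, while the 450–700 nm measurement
band suffices from ~1.2 µm upward.

Growing diameters trace an outward spiral in the phasor plane: frequency
(radius) grows as $2 n_g \Delta d$ per step and phase winds monotonically.
The fitted phase change for a 10-nm diameter step at 3 µm computes to
0.397 rad ≈ π/8 — the phase is roughly 13× more sensitive than the relative
frequency change, which is why the phasor angle is the preferred barcode
coordinate at small separations. The naive estimate
$4\pi n_g \Delta d / \lambda_{ref}$ overshoots the fitted value by ~5%
because the fit averages the dispersion over the whole band rather than
evaluating it at the reference wavelength.

## Microenvironmental sensing

**Protein adlayer.** Binding of a protein (e.g. streptavidin, ~5 nm,
$n = 1.50$) adds a thin film on each side of the sphere; at surface density
$p$ the layer is modelled as an effective medium. The default mixing law is
linear volume-fraction index mixing,
$n_{eff}(p) = p\,n_{layer} + (1-p)\,n_{medium}$, which reproduces the
measured operating point self-consistently (a 0.57-nm redshift inverts to
~51% density while the full-density shift is ~1.16 nm); Maxwell-Garnett
mixing is available as an alternative and differs only slightly at these
index contrasts. The redshift metric is the displacement of the fringe peak
nearest 589 nm, located by parabolic interpolation on a 0.01-nm simulation
grid; a cross-correlation-shift alternative agrees within 0.1 nm and both
are tested. `invertDensity()` inverts the monotone shift curve by bisection
to $10^{-3}$ nm. The solvent term of the mixture is evaluated at the
tracking wavelength; the layer is 5 nm thick, so its dispersion is
irrelevant to the fringe position.

**Liquid crystal.** A nematic droplet in a polymer matrix presents the
ordinary index $n_o \approx 1.55$ with no applied field; a field reorients
the director and raises the effective index toward $n_e \approx 1.74$,
redshifting the fringes in proportion. The field-to-index mapping is
deliberately parametric — `lcSpectrum()` takes $n_{eff} \in [n_o, n_e]$
directly — because director-field physics (thresholds, anchoring) is a
separate modelling problem. With constant indices the fringe frequency
scales exactly as $n_{eff}$, which the tests verify through the phasor fit.

## Photometry

Fluorophore brightness is $\Phi\,\sigma\,C\,N_A\,L_{eff}$ (quantum yield ×
absorption cross-section × number density × path), with concentration
converted from mol/L to nm⁻³. The excitation/collection geometry is
condensed into a single calibrated path length $L_{eff}$, fixed by the
anchor that an 8-µm polystyrene probe in water is 700× brighter than 100 µM
fluorescein ($\Phi = 0.92$, $\sigma = 0.0121$ nm²); the package computes
$L_{eff} \approx 72$ nm from its own peak-reflectance figure at run time
rather than hard-coding it. Every other ratio then follows from printed
photophysics alone: 5 mM fluorescein gives exactly 700/50 = 14, and 10 µM
eGFP ($\Phi = 0.6$, $\sigma = 0.0091$ nm²) gives ~14,270. The probe-side
brightness input is the band-peak reflectance (see the 3.5% discussion
above).

Multiplexing capacity is `floor(range / (m × precision))`; the spacing
multiplier `m` exposes both conventions in circulation — `m = 1` for a
stated worst-case precision (333 per µm at 3 nm) and `m = 2` when the
precision is a ± standard deviation (166 per µm). SNR is mean signal over
background standard deviation. Attenuation profiles are fitted as
$A e^{-z/\ell}$ by `nls` seeded from a log-linear fit, with constant
profiles reported as saturated ($\ell = \infty$) rather than fitted.

`precisionMonteCarlo()` ties the pipeline together: $n$ seeded synthetic
acquisitions are decoded and summarised (mean, sd, maximum pairwise
spread, rejection count). With the default instrument, 21 replicates of a
4-µm silica sphere at 0.6-nm sampling spread by well under the 3-nm
theoretical limit set by the spectral resolution.

## The synthetic instrument

`acquireSpectrum()` emulates the confocal spectral-reflectometry
acquisition: the true reflectance is simulated on a fine 0.1-nm grid,
convolved with a Gaussian line-spread function (FWHM 0.6 nm, the grating
resolution), sampled on the 0.6-nm instrument grid with a uniform random
sub-sample offset (±0.3 nm) per acquisition, multiplied by a smooth
strictly-positive supercontinuum-like envelope (a quartic peaking near
550 nm), and given additive Gaussian noise whose sd is a fraction of the
fringe amplitude. The mirror reference is the envelope alone, so reference
division removes it exactly in the noiseless limit — an identity the tests
assert to $10^{-12}$.

The default noise fraction is 0.01. No noise figure is published for the
real detector, so this is a documented assumption chosen to put the
simulated 21-replicate spread in the same ≤3 nm regime as reported
measurements; the tests additionally sweep noise levels and assert only
monotone degradation, which does not depend on the chosen level.

`acquireStack()` builds the 9×9×10-voxel scan (100 nm lateral / 200 nm
axial spacing): each voxel's intensity and fringe contrast are attenuated
by a 3-D Gaussian confocal profile (σ = 200 nm lateral, 400 nm axial)
centred on the sphere position, with no spectral distortion — adequate for
exercising centre selection and the boundary-exclusion rule, which is what
the stack path needs. `makeBarcodeScenario()` assigns distinct diameters
(≥40 nm apart by default, capacity-checked against the range) and generates
measurements per cell per timepoint; `trackBarcodes()` re-identifies cells
by nearest-diameter matching and reports a confusion rate.

What the generator does **not** emulate: speckle, detector nonlinearity and
gain structure, off-centre spectral distortion, refractive-index
heterogeneity of cytoplasm, photobleaching of co-labels, and real scanning
artefacts. Passing the closed-loop tests therefore demonstrates the
correctness of the decoding chain and its quantization-limited precision
under the stated noise model — not the precision attainable on any
particular physical instrument, which is why experimentally reported
repeatability figures (e.g. sub-nanometre standard deviations) are not
asserted by the test suite.

## Numerical choices and degenerate inputs

* Databases require strictly increasing, constant-step diameters; loading
  checks a format version and fails loudly on truncated or versionless
  files.
* Decoding requires ≥16 overlapping samples in the fit band; fewer is a
  coverage error, as is a sub-100-nm normalization overlap.
* Correlation ties (exactly equal scores) go to the smaller diameter and
  are logged; parabolic refinement is clamped to its bracketing interval
  and skipped at the grid edges.
* The phasor fit fails explicitly (with diagnostics) if the cosine model
  explains less than 10% of the detrended variance.
* `adlayerShift()` errors if no fringe peak exists in the tracking window;
  `invertDensity()` errors on shifts above the full-density ceiling,
  reporting the ceiling.
* All stochastic operations take explicit seeds; the same seed reproduces
  results bit-for-bit.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale: databases of
$10^4$ rows (1-µm windows at 0.1-nm steps), $10^4$-draw oracle comparisons,
100-seed recovery loops and 21-replicate precision runs. These sizes
exercise every code path at full fidelity; the physics is identical at
larger windows, only the lookup breadth grows.

## Session info

```{r}
sessionInfo()
```
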