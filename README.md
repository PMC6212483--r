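# SpeRe: spectral reflectometry decoding of microsphere probes

Dielectric microspheres ("reflectophores") can serve as optical barcodes and
sensors: a broadband ray focused at the centre of a sphere meets both
surfaces at normal incidence, so the sphere behaves as a Fabry–Pérot etalon
of thickness *d* (the diameter). Its reflectance spectrum

R(k) ≈ A + B·cos(2π·f·k + φ₀),  k = 1/λ,  f ≈ 2·n_g·d

is sinusoidal in wavenumber with a fringe frequency equal to the round-trip
group optical thickness, so the diameter is encoded in the spectrum with
nanometre precision — far below the diffraction limit. This package is an
offline, fully testable implementation of that measurement principle for
researchers building or simulating spectral-reflectometry (SpeRe) readouts:

* **Optics core** — dispersive material models (Sellmeier/Cauchy/constant,
  in a YAML registry) and a lossless normal-incidence transfer-matrix solver
  for arbitrary layer stacks (`sphereStack()`, `reflectanceSpectrum()`).
* **Spectrum database** — one simulated spectrum per diameter on a constant
  grid (`buildDatabase()`, `saveDatabase()`/`loadDatabase()`).
* **Decoder** — centre-voxel selection from a volumetric confocal scan,
  mirror-reference normalization, and best-fit diameter search by Pearson
  correlation against the database, with optional sub-grid parabolic
  refinement (`decodeStack()`, `decodeSpectrum()`).
* **Phasor analysis** — fringe frequency and phase at the 500-nm reference,
  the polar "barcode coordinate" of a spectrum (`toPhasor()`).
* **Sensing** — protein-adlayer redshift and surface-density inversion, and
  liquid-crystal effective-index spectra (`adlayerShift()`,
  `invertDensity()`, `lcSpectrum()`).
* **Photometry** — brightness ratios against fluorophores, multiplexing
  capacity, SNR, exponential attenuation fits, Monte-Carlo precision
  (`brightnessRatio()`, `multiplexingCapacity()`, `precisionMonteCarlo()`).
* **Synthetic instrument** — a seeded generator of raw spectra, mirror
  references, scan stacks and barcoding scenarios with known ground truth
  (`InstrumentModel()`, `acquireSpectrum()`, `acquireStack()`,
  `makeBarcodeScenario()`).

## Worked example

Simulate one noisy acquisition of a 3000.4-nm polystyrene sphere in water,
normalize it by the mirror reference, and decode it against a 0.1-nm-step
database:

```r
library(SpeRe)
ps    <- getMaterial("polystyrene")
water <- getMaterial("water")

db   <- buildDatabase(2995, 3005, 0.1, ps, water)   # 450-700 nm @ 0.1 nm
inst <- InstrumentModel()                            # 0.6-nm sampling, 1% noise
acq  <- acquireSpectrum(inst, 3000.4, seed = 42)
spec <- normalizeSpectrum(acq$raw, acq$reference)

decodeSpectrum(spec, db)
#> DecodeResult: status=accepted, d=3000.400 nm, r=0.999786 (R^2=0.9996)

toPhasor(spec)
#> PhasorPoint: frequency=10008.35 nm, phase=4.7295 rad, amplitude=0.0156, offset=0.01586
```

The decoded diameter lands on the true value despite 1% detector noise and
0.6-nm sampling: the correlation fit uses every fringe in the band at once.
The phasor frequency, ~10,008 nm, is the round-trip group optical thickness
2·n_g·d (n_g ≈ 1.66 for polystyrene mid-band), and the phase is the fringe
position at the 500-nm reference.

Headline figures recomputed by the models:

```r
peakReflectance(3000, ps, water)        # 0.0338  (~3.4% peak reflectance in water)
adlayerShift(AdlayerModel(), 1)         # 1.159 nm  full-density streptavidin redshift
invertDensity(AdlayerModel(), 0.57)     # 0.508   density for a 0.57-nm redshift
multiplexingCapacity(1000, 3)           # 333     barcodes per um at 3-nm precision
```

## Command line

A thin launcher over the same functions is installed at
`inst/scripts/spere.R`:

```sh
Rscript inst/scripts/spere.R simulate --diameter 3000 --core polystyrene \
        --medium water --band 450:700:0.1 -o spectrum.csv
Rscript inst/scripts/spere.R build-db --dmin 2995 --dmax 3005 --dstep 0.1 \
        --core polystyrene --medium water -o db.bin
Rscript inst/scripts/spere.R decode --spectrum raw.csv --reference ref.csv \
        --db db.bin
```

Spectra are CSV with header `wavelength_nm,value`; scan stacks are TSV with
voxel columns `i, j, k` plus one column per wavelength; databases are a
single binary file with a JSON metadata sidecar. `show-config` prints all
defaults.

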