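# vhqpi

Single-shot quantitative phase imaging (QPI) reconstruction in R:
variational interferogram decomposition plus Hilbert spiral transform
demodulation.

## What problem this solves

Interferometric QPI systems (digital holographic microscopy, diffraction
phase microscopy and relatives) record one intensity raster

    I = a + b cos(θ) + n

— background `a`, fringes of amplitude `b` phase-modulated by the
specimen's optical path delay `θ` (object phase plus a carrier ramp
`2πx/T`), and noise `n`. Off-axis systems (small `T`) are easy: the
Fourier spectrum separates and a band-pass filter recovers `θ`. The
interesting regime is a *weak* carrier (quasi on-axis, large `T`), where
the spectral lobes overlap and linear filtering fails. This package
demodulates a single frame across the whole range by

1. splitting the interferogram into noise + background + zero-mean
   fringes with a wavelet denoiser and Chambolle's total-variation dual
   projection (`μ = 100`, `τ = 0.25`, data-driven stopping) —
   `uvid_filter()`;
2. estimating the local fringe direction map `β` (mod 2π) by windowed
   plane-fit orientation, angle-doubling unwrapping and sine–cosine
   smoothing, with the plane-fit window chosen automatically by
   minimising the mean unwrapped-phase gradient over `w = 3,5,…,13` —
   `select_window_and_demodulate()`;
3. computing the quadrature with the spiral Fourier multiplier
   `SPF(u,v) = (u+iv)/√(u²+v²)`:
   `q = Re[−i e^{−iβ} F⁻¹{SPF·F[fringes]}]`, taking the argument of
   `fringes + iq`, unwrapping it (quality-guided, congruent) and
   removing the residual carrier plane — `vhqpi()`;
4. optionally removing slowly varying instrumental aberrations by
   re-decomposing the unwrapped phase map — `correct_aberrations()`.

A fully synthetic red-blood-cell phantom generator (Evans–Skalak
thickness profile, seeded noise, exact ground-truth phase, direction and
decomposition) makes every stage testable without experimental data:
`synthetic_spec()`, `rbc_phase()`, `generate_interferogram()`,
`ideal_direction()`. Evaluation metrics (`rms_error()`,
`background_std()`, `error_map()`) score reconstructions the way the
field does: RMS against a reference after sign/piston alignment, and the
standard deviation of sample-free regions.

## Worked example

```r
library(vhqpi)
spec  <- synthetic_spec(size = 256, period = 20, noise_amp = 0.05, seed = 7)
truth <- rbc_phase(spec = spec)
sim   <- generate_interferogram(spec, truth)
fit   <- vhqpi(sim$interferogram)
fit
#> VHQPI phase reconstruction
#>   raster: 256 x 256
#>   decomposition: NI = 2000 projections (mu = 100, tau = 0.25)
#>   direction window: w = 13 (mean gradient 0.3186 rad/px)
#>   phase range: [-0.906, 1.966] rad
mask <- interior_mask(dim(truth), border = 16)
rms_error(fit$phase, truth, mask)
#> [1] 0.0607
```

The reconstructed phase map tracks the 5·z phantom (peak-to-valley
about 2.9 rad here) to 0.06 rad RMS despite the Gaussian background,
the 0.05 noise and a 20-px carrier. `plot(fit)` shows the phase;
`plot(fit, "fringes")` the filtered fringe term;
`summary(fit)` prints the per-window gradient table of the direction
search.

A command-line interface (`inst/cli/vhqpi`) wraps the same functions:

```sh
Rscript inst/cli/vhqpi simulate --size 512 --period 20 --noise 0.05 --seed 1 \
    --out interferogram.tif --truth truth/
Rscript inst/cli/vhqpi run interferogram.tif --out phase.tif --report report.json
Rscript inst/cli/vhqpi evaluate phase.tif --reference truth/phase.tif --json metrics.json
```

Rasters are float32 TIFF (radians as stored); integer export requires an
explicit `--quantize`-style request through `write_raster()`.

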