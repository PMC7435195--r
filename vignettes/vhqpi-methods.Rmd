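---
title: "Single-shot phase demodulation by variational decomposition and the Hilbert spiral transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot phase demodulation by variational decomposition and the Hilbert spiral transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative phase imaging encodes the optical path delay of a
transparent specimen in an interference pattern

$$ I(x, y) = a(x, y) + b(x, y)\cos\theta(x, y) + n(x, y), $$

where $a$ is the incoherent background, $b$ the fringe amplitude,
$\theta$ the phase carrying the specimen information on top of a carrier
ramp $2\pi x/T$, and $n$ detector noise. Recovering $\theta$ from one
frame is easy when the carrier is strong (off-axis holography: the
Fourier spectrum separates and a band-pass filter does the job) and hard
when the carrier is weak (quasi on-axis: the spectral lobes overlap and
no linear filter can separate them). This package implements a
demodulation pipeline that works across that whole range, plus a fully
synthetic red-blood-cell interferogram generator so that every stage can
be validated against analytic ground truth without any experimental
data.

## Pipeline

### 1. Variational decomposition (`uvid_filter`)

The interferogram is split additively into noise, background and
zero-mean fringes.

*Noise* is separated first by a translation-invariant single-level Haar
soft-threshold (`denoise`), with the noise level estimated from the
median absolute deviation of the diagonal Haar detail — robust against
the fringe content itself. The noise raster is *defined* as input minus
denoised, so the decomposition conserves intensity exactly. The denoiser
is pluggable; the interface reserves a slot for a block-matching 3D
backend, and raises an informative error when it is requested but not
available.

*Background and fringes* are separated by Chambolle's dual projection
for the ROF functional
$\min_u \mathrm{TV}(u) + \lVert u - g\rVert^2 / (2\mu)$
with $\mu = 100$ and dual step $\tau = 0.25$ — fixed, versatile values
that need no per-image adjustment when fringe amplitudes are of order
one. Two properties make this work as a fringe filter:

* the dual variable grows fastest where the image curvature is largest,
  so the oscillatory fringe content is expelled from the structure
  estimate $u$ within the first tens to hundreds of projections, while
  the smooth field-scale background erodes orders of magnitude more
  slowly;
* the divergence-form update makes the texture term exactly zero-mean
  (telescoping sums), which is precisely the condition the subsequent
  Hilbert transform needs.

The iteration therefore stops, data-adaptively, once the structure
increment has decayed below `tol = 1e-3` of the first increment
(`auto_stop`), with a cap of `max_iters = 2000` projections. Partial
fringe expulsion is harmless: whatever fraction of the fringe amplitude
reaches the texture, its *phase* is unchanged — only background leakage
would bias the phase, and the stopping rule halts long before the
background moves. The projection loop is compiled code; 2000 projections
on a 512-by-512 raster take a few seconds.

### 2. Fringe direction (`estimate_orientation`, `unwrap_orientation`, `sincos_filter`)

The two-dimensional quadrature transform requires the local fringe
direction map $\beta$ (the angle of the fringe normal against OX,
modulo $2\pi$). It is built in three steps:

1. **Orientation, modulo $\pi$.** A plane is least-squares fitted to the
   intensities of a $w \times w$ neighbourhood (equivalently, the image
   gradient is smoothed by the plane-fit kernel), and the structure
   tensor of these plane-fit gradients, averaged over the same window,
   gives the orientation of the fringe normal. Small windows resolve
   dense fringes but transmit noise; the sweep in step 4 arbitrates.
2. **Direction, modulo $2\pi$.** The $\pi$-ambiguity is resolved by
   angle doubling: the doubled orientation is treated as a wrapped phase,
   unwrapped, halved, and reduced modulo $2\pi$. Orientation noise
   plants spurious residues in the doubled field which a naive path
   unwrapper converts into regional half-turn flips, so the doubled
   field is first smoothed as a complex phasor and the unwrapping order
   is guided by the phasor coherence (near one where the orientation
   field is consistent, low at noise and at genuine direction vortices).
   The unwrapper itself is a quality-guided region-growing scheme in
   compiled code.
3. **Sine–cosine smoothing.** $\sin\beta$ and $\cos\beta$ are filtered
   separately and the direction reassembled by `atan2`, which respects
   the circular topology and is equivariant under global rotations of
   the field. Each of the `n_modes = 3` passes removes the locally
   highest-frequency detail component, computed as the difference
   between the field and its 3×3-median-then-Gaussian smoothing — an
   empirical, data-driven high-frequency peel-off.

A global half-turn ambiguity of $\beta$ is intrinsic to single-shot
demodulation of carrier-free patterns (conjugate phase); it is accepted
and quotiented out in the evaluation metrics rather than resolved.

### 3. Hilbert spiral transform (`hilbert_spiral_transform`, `analytic_signal`)

The quadrature of the zero-mean fringes $f$ is

$$ q = \mathrm{Re}\left[-i\,e^{-i\beta}\,
   \mathcal{F}^{-1}\{\mathrm{SPF}\cdot\mathcal{F}[f]\}\right],\qquad
   \mathrm{SPF}(u, v) = \frac{u + iv}{\sqrt{u^2 + v^2}}, $$

the spiral (vortex) Fourier multiplier with its DC value set to zero.
The real-part projection is the standard vortex-demodulation convention:
the quadrature must itself be a real fringe raster. The analytic fringe
pattern $f + iq$ then has argument equal to the wrapped phase. Rasters
are mirror-padded to twice their size around the transform to suppress
periodic-extension ringing. Frequencies are laid out in DFT order with
the Nyquist bin of even dimensions in the negative half; this fixes the
parity of the multiplier.

For a pure carrier and $\beta = 0$ the transform reduces to the
classical 1D Hilbert quadrature ($\cos \mapsto \sin$), and in the
off-axis regime the whole pipeline agrees with classical
Fourier-transform demodulation (`ft_demodulate`), which the test suite
uses as an independent oracle. The method assumes the fringe amplitude
is slowly varying relative to the carrier; amplitude demodulation of
detail-rich amplitude objects is out of scope.

### 4. Window search (`select_window_and_demodulate`)

For every window $w \in \{3, 5, \dots, 13\}$ the full chain
(orientation → direction → sine–cosine filter → spiral transform →
unwrap) is run and the mean magnitude of the unwrapped-phase gradient is
recorded; the window with the smallest mean gradient wins, ties going to
the smaller window. Direction errors necessarily create spurious phase
jumps, which the gradient detects, so oversized windows that over-smooth
curved fringes (and thereby introduce artificial direction
discontinuities) are rejected automatically. Windows above 13 px are not
searched: they only ever add such artifacts.

### 5. Unwrapping, plane removal, aberration correction

Phase unwrapping uses the same quality-guided region-growing unwrapper,
ordered by local wrapped-gradient smoothness. Each pixel is made
congruent modulo $2\pi$ with its best unwrapped neighbour, so rewrapping
the output reproduces the input exactly and residue-free inputs unwrap
exactly; the residue count is reported as an attribute. `remove_plane`
then subtracts the least-squares piston-plus-tilt — the residual carrier
term.

`correct_aberrations` re-applies the structure–texture split *to the
unwrapped phase map*: slowly varying instrumental backgrounds
(astigmatism, defocus) land in the structure and are discarded, while a
compact specimen's detail survives in the texture. No denoising stage is
involved there — an unwrapped phase map has no meaningful pixel-noise
term left. Plane removal is ordered before aberration correction. The
scale separation this relies on is genuinely scale-dependent: with
$\mu = 100$ the split distinguishes a field-scale saddle from an object
a few tens of pixels across on a 512-pixel raster; objects approaching
the field size would partially migrate into the structure and be
over-corrected.

## The synthetic generator and what it does (not) emulate

`generate_interferogram` composes
$I = a + \cos(5z + 2\pi x/T) + 0.05\,G$ on a 512-pixel grid by default:
a centred Gaussian background (amplitude 1, $\sigma$ = field/3 — chosen
once as a typical incoherent background), a cosine fringe term whose
phase is five times the Evans–Skalak red-blood-cell thickness profile

$$ z = D_0\sqrt{1 - \tfrac{4r^2}{D_0^2}}
   \left(a_0 + a_1\tfrac{r^2}{D_0^2} + a_2\tfrac{r^4}{D_0^4}\right), $$

with $D_0 = 7.82\,\mu m$, $a_0 = 0.0518$, $a_1 = 2.0026$,
$a_2 = -4.491$, and seeded unit-variance Gaussian noise of amplitude
0.05. Outside the support disk the height is defined as zero (cell on a
flat substrate), keeping the phantom real and continuous. Carrier
periods from 4 px (Nyquist-safe floor) to $\infty$ (carrier-free) are
supported. The exact ground-truth decomposition, phase and direction map
(`ideal_direction`) accompany every phantom.

**Pixel pitch.** The height profile is in micrometres; its footprint on
the raster is set by `pixel_pitch`. The default images the *central
region* of the cell at high magnification (cell diameter equal to twice
a 512-pixel field, pitch $D_0/1024$). This is a deliberate modelling
choice: the profile's rim has unbounded slope (the square-root edge), so
any raster that includes the rim contains zones where the object
gradient locally reverses the carrier. Inside such fringe-reversal zones
the true direction map flips by $\pi$ while the fringe *orientation*
does not rotate at all — the flip is invisible in principle to any
orientation-based direction estimator, and demodulation there is
ill-posed for the entire class of methods this package implements. With
the default pitch every visible gradient of the $5z$ object stays below
the weakest carrier of the 4–150 px study range
($\max|\nabla(5z)| \approx 0.021 < 2\pi/150$ rad/px), which is the
regime in which direction estimation is well-posed across the whole
sweep. Tests that need a compact cell in a wide field (the
aberration-correction scenario, mimicking a small cell under a large
field of view) set the pitch explicitly.

What the generator does **not** emulate: partially coherent
illumination, speckle, amplitude objects violating the slowly-varying
envelope assumption, camera nonlinearity, or optical aberrations beyond
the low-order polynomial backgrounds of `aberration_background`.
Passing the synthetic suite therefore demonstrates correctness of the
numerics under the stated fringe model, not robustness to every
experimental artifact.

## Numerical choices

* Chambolle step $\tau = 0.25$ (the largest empirically stable step for
  the projection), weight $\mu = 100$; stopping at a relative increment
  decay of $10^{-3}$, cap 2000 projections.
* Wavelet threshold $2.5\,\hat\sigma$ with
  $\hat\sigma = \mathrm{MAD}(\text{Haar HH})/0.6745$.
* Degenerate-gradient threshold for orientation validity:
  $10^{-6}$ of the raster dynamic range; orientation maps with less than
  half their pixels valid are refused.
* Phasor smoothing before orientation unwrapping: Gaussian
  $\sigma = 3$ px; sine–cosine filter: three passes of 3×3 median
  followed by Gaussian $\sigma = 1$ px.
* All RMS evaluations exclude a 16-px border (mirror-padding transients)
  and, for closed-fringe phantoms, a 10-px disk around the direction
  vortex, where single-shot demodulation is intrinsically singular.
  Before scoring, the global sign and piston are aligned to the
  reference — the conjugate/offset ambiguities of the problem, not
  errors of a particular run.
* Problem sizes in the tests: unit tests run on 64–256 px rasters;
  the end-to-end accuracy checks use the full 512-px study raster, with
  the carrier sweep at $T \in \{8, 16, 30, 60, 100, 150\}$.

## Known limitations

* Fringe-reversal zones (object gradient locally cancelling the
  carrier) are not demodulated correctly with an *estimated* direction
  map; they require either a stronger carrier or prior knowledge of the
  direction (see the pixel-pitch discussion above).
* The $\pm\beta$ branch of carrier-free patterns is reported modulo a
  global half turn; the corresponding phase is determined up to
  conjugation.
* The ROF scale separation ties "background" to "much slower than the
  fringes"; backgrounds sharing the fringe scale (severe speckle) will
  leak.
* Processing is deterministic but not real-time: a full 512-px pipeline
  run with the window search takes on the order of a minute on one CPU
  core.
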