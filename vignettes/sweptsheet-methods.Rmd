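---
title: "Models and methods behind sweptsheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sweptsheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweptsheet)
```

# Scope

`sweptsheet` is a desk-scale simulator and planning toolkit for axially
swept light-sheet microscopy (ASLM) with a dual-foci rolling-shutter mode.
In ASLM a thin Gaussian light-sheet waist is translated along its
propagation axis in lockstep with the rolling shutter of an sCMOS camera,
so that only in-focus waist light is recorded by the narrow band of
simultaneously active rows. The dual-foci variant holds two waists at a
fixed separation of half the chip (1024 rows on a 2048-row camera), each
synchronized with its own rolling shutter over half the field of view.
This halves the rows each focus must sweep, which can be spent either on
a twofold longer per-row dwell (twice the signal at the same frame rate)
or on a fourfold shorter exposure (40 fps full-frame instead of 10 fps).

The package models the pieces of that system that are computational:
Gaussian-beam optics and multi-immersion pixel scaling, rolling-shutter
row schedules and focus-actuator waveforms, frame formation with an sCMOS
noise model, tile-grid planning with time and data budgets, tile
informativeness classification (an intensity rule and a small
convolutional network), and resolution quantification from bead stacks.
Hardware control, stitching internals and tissue optics are out of scope.

# Optics

The illumination sheet is modeled as a Gaussian beam with waist radius
$w_0 = \lambda/(\pi\,\mathrm{NA})$ and Rayleigh range
$z_R = \pi w_0^2 n/\lambda$; its FWHM thickness at a propagation offset
$x$ from the waist is $\sqrt{2\ln 2}\,w_0\sqrt{1+(x/z_R)^2}$. The
system's illumination NA is not an independent input: the default
configuration back-solves it so that the sheet-waist FWHM equals the
measured 0.97 µm system resolution at 488 nm (NA ≈ 0.189). This is a
calibration to the instrument's measured performance, not a
first-principles prediction, and it is configurable.

The detection path uses a multi-immersion objective whose magnification
grows linearly with the immersion refractive index (RI). The model is
anchored at the measured 15.28× in water (RI 1.33), giving a 0.425 µm
sample-space pixel from the 6.5 µm camera pitch and an 870 µm field of
view over 2048 pixels. The same linear scaling converts resolutions
between media: 0.97 µm measured in water is equivalent to 0.83 µm at
RI 1.56. The camera pitch default (6.5 µm, the Orca Flash 4.0 class)
is a configurable hardware constant.

The system PSF is approximated as a separable 3D Gaussian: lateral FWHM
from the detection path, axial FWHM from the sheet waist; with the
calibrated defaults both are 0.97 µm, i.e. the PSF is isotropic.
Aberrations and vectorial effects are not modeled. Rendered kernels are
normalized to unit mass and refuse voxels coarser than FWHM/3 unless the
caller explicitly overrides the check (needed when a kernel must match
an acquired stack's grid for deconvolution).

# Shutter timing and synchronization

Exposure time $T$ is defined as the transit time of the shutter's leading
edge across the rows swept per shutter ($R$: all $N$ rows in single mode,
$N/2$ per focus in dual mode). Row $r$ of a shutter is active while the
leading edge lies in $[r, r+A)$, with $A = 40$ active rows, so every row
dwells for $AT/R$. Both dual-mode shutters start simultaneously and sweep
top-to-bottom (the camera reads in one direction only), which keeps the
foci separation fixed at $N/2$ rows throughout the sweep. At equal $T$
the dual/single dwell ratio is exactly 2; dual at 25 ms collects half the
per-row dwell of single at 100 ms while running four times faster.

The focus actuator follows a sawtooth: a linear ramp over the exposure
and a linear return over the flyback. The flyback default (10 ms) is a
system-dependent placeholder — the value is hardware-specific and
configurable. The ideal focus trajectory keeps the waist at the center of
the active window; actuator nonlinearity is represented by a constant row
lag plus an optional seeded sinusoidal wobble. This lag model is a
stand-in, not a fit: the real actuator's loss of sync at high speed is
not quantified anywhere we could calibrate against. Synchronization error
is the maximum over rows of the waist-to-row distance at each row's
activation midpoint, and "in sync" means the error stays within half the
active window ($A/2 = 20$ rows), i.e. the waist never leaves the active
band. Trajectory positions are quantized to $2^{-20}$ rows (≈ a
micro-row, far below any physical scale) so that the dual-foci
separation is exact in floating point at every sample.

# Frame formation and noise

For a volume phantom, each detector row integrates the phantom plane at
the current focal depth for its dwell time, weighted axially by a
Gaussian whose width is the sheet thickness at that row's waist offset —
desynchronization therefore appears as axial thickening of the recorded
section, which is the mechanism behind the swept-line synchronization
test. The detection PSF blurs laterally. Phantoms that carry a point-
emitter list (bead phantoms) are instead rendered analytically, by
evaluating the separable Gaussian image of each emitter at the pixel
centers; this avoids the voxelisation broadening a rasterized point
source would suffer and makes bead-based PSF recovery unbiased. Beads at
or below the pixel size are treated as points.

Counts follow a standard sCMOS abstraction: Poisson shot noise on the
expected photon count, Gaussian read noise in electrons, a fixed offset
(default 100 counts) and linear gain, clipped to 16 bits with a
saturation warning. The source system reports no noise model, so this is
a package choice; consequently the measured ~17% SNR drop of dual-25 ms
versus single-100 ms operation on real tissue is *not* a simulation
target — it depends on the unreported noise regime. The simulator instead
exposes the two analytic limits: the shot-noise bound (SNR ratio
$1/\sqrt2$, a 29% drop) and the read-noise-dominated limit (ratio 1/2).
SNR is defined as (mean foreground − mean background)/sd(background);
the source's exact SNR definition is inherited from its references and
not restated, so this common form is a documented choice.

The swept-line test renders a camera snapshot mid-exposure: only rows
inside each shutter's active window record the focal line, so an in-sync
sweep shows one sharp line per focus spanning every column with vertical
extent bounded by the 40-row window, while a 100-row desync moves the
focus out of the window and collapses the recorded intensity.

# Acquisition planning

Tile grids are laid from the box corner with per-axis step
`size × (1 − overlap)` and count `1 + ceil((L − size)/step)`, row-major
XYZ order (traversal order is not specified by the source system; this
is a convention). "Total frame acquisition time" is frames × exposure
only; this is the quantity whose single-100 ms / dual-25 ms ratio is
exactly 4 and which reproduces the printed whole-sample pairs
(19.73/4.93 h and 25.63/6.40 h) as ratios — including flyback would not.
"Total imaging time" adds flyback per frame and a per-tile stack delay
(stage, filter wheel, writing), which pulls the realized speedup below
fourfold. Data sizes are decimal terabytes of 16-bit frames. Per-sample
frame counts for the published specimens are not stated, so printed hour
totals are checked only as ratios, never as absolute hours.

# Tile informativeness classification

The intensity rule follows five steps: axial MIP; smoothing by 20×20 and
40×40 uniform filters; their signed difference (background removal);
the percentage of pixels above 2.5 counts; and a 0.1% cutoff below which
a tile is non-informative. Unstated details are fixed as: half-sample
symmetric (reflect) padding, difference order small-minus-large, signed
(not absolute) difference, strict ">" at 2.5 applied to raw counts
(the threshold's magnitude suggests count units, so images are not
normalized first), and "score ≥ 0.1%" labeled informative (scores
*less than* 0.1% are non-informative). With reflect padding the score is
exactly invariant to adding a constant to the image. The box filters use
integral images; no installed filtering routine offered reflect-padded
uniform windows, so they are implemented directly and tested against an
independent nested-loop oracle.

The convolutional classifier follows the screening protocol: balanced
corpus, stratified 80/20 train/validation split (stratification is a
package choice), batch size 32, early stopping monitoring validation
accuracy with patience 10, per-epoch accuracy/loss log, and the
best-validation checkpoint retained. The network is 3 convolution blocks
(3×3 convolution, ReLU, 2× max-pool) with widths 8/16/32, global average
pooling and one sigmoid unit, on tiles block-mean downsampled to 32×32.
Only "convolution blocks with twofold max-pooling" is specified by the
protocol; the depth, widths and input size are package choices sized so
that a presence/absence screen trains on a single CPU in minutes — the
corpus is low-resolution screening data, and 32×32 retains the
structures that distinguish tissue from empty medium. No R deep-learning
framework is assumed: the network (im2col convolutions as BLAS matrix
products, Adam, backpropagation) is implemented in vectorized base R and
verified against numerical gradients. The probability threshold default
is 0.5 (the protocol applies "a threshold" without stating one). ROC
curves and AUC are computed by the trapezoid rule over all thresholds,
which equals the Mann–Whitney pair statistic; this equality is
property-tested against brute-force pair counting.

# Synthetic data

The tile corpus emulates the screening training set: 2080 informative
and 2080 non-informative 128×128 tiles by default. Non-informative tiles
are camera offset (100 counts) plus Gaussian noise (sd 5);
informative tiles add structured foreground — Gaussian blobs (nuclei-like,
4–16 per tile, peak amplitudes 30–120 counts, radii 2.5–7 px) or smooth
random curves (vessel-like). These are invented stand-ins for tissue
content, deliberately simple: the corpus is linearly separable by design
(the intensity rule classifies it with ≥99% accuracy), which is what
makes the ≥99% network-accuracy criterion meaningful, but passing on it
says nothing about scattering, shadowing, debris or the intensity
statistics of real cleared tissue. The dimensions and downsampling of
the real screening tiles are unreported; 128×128 is a package choice.
All generators are deterministic given a seed.

Bead phantoms place point emitters uniformly at random with a minimum
separation and face margin (rejection sampling with a bounded retry
budget), mirroring 500 nm beads in agarose.

# PSF quantification

Bead detection takes local maxima above an intensity percentile,
non-maximum suppressed by a minimum separation and excluded from a 5 px
margin. Per bead, axis-aligned profiles through a center-of-mass-refined
sub-voxel centroid (trilinear interpolation) are fitted with a
four-parameter Gaussian-with-offset, initialized from moments
(`minpack.lm` Levenberg–Marquardt); FWHM $= 2\sqrt{2\ln2}\,\sigma$.
Profiles are sampled at integer grid positions along the profiled axis
(interpolation happens only orthogonally, where it merely rescales a
separable peak's amplitude): interpolating *along* the axis would
convolve the profile with a triangle kernel and bias the recovered FWHM
upward by several percent.
Fits recover σ to ~1e-9 on noiseless profiles and within a few percent
under 5% noise. Aggregates report per-axis mean ± sd over beads.

Richardson–Lucy deconvolution uses the standard multiplicative update
starting from the observed image (a flat start transiently *broadens*
structures during the first iterations), with the normalized PSF, FFT
convolutions, and edge correction by
renormalizing both the forward blur and the update with the in-volume
PSF mass, so a flat field is a fixed point and flux is conserved for
interior objects. The iteration count default is 20 (none is reported);
the published ~17% sharpening of real beads is treated as descriptive —
the package asserts only that deconvolving simulated beads with the true
PSF shrinks their FWHM monotonically over the first ten iterations.

# Numerical choices and problem sizes

Tests and the acceptance script run the simulators at reduced scale
chosen to keep the full suite in the minutes range while leaving every
contract intact: rendering tests use 64–160-row chips (the schedule and
dwell arithmetic are size-exact, so nothing is lost), PSF recovery uses
32 beads in a 48×48×36 µm volume at 0.3 µm voxels (0.3 µm satisfies the
FWHM/3 sampling bound that the 0.425 µm water pixel does not),
deconvolution checks use two-bead stacks, and the swept-line and
trajectory checks run at the full 2048-row geometry since they are
closed-form. The classifier criterion runs at the full corpus size
(4160 tiles). Where a boundary convention, tie-break or padding mode was
open, the choice is stated next to the code and exercised by an oracle
test rather than left implicit.

# Known limitations

- The lag/wobble actuator model is a placeholder for unquantified
  mechanical nonlinearity; it supports "what breaks sync" experiments
  but cannot predict a specific actuator's speed limit.
- The noise model omits sCMOS fixed-pattern noise, pixel-dependent gain
  and dark current; tissue scattering, attenuation and shadowing are not
  modeled at all.
- The corpus generator's separability means classifier results
  demonstrate protocol correctness, not field performance.
- Magnification-versus-RI linearity is anchored to two printed operating
  points; real multi-immersion objectives deviate slightly between them.
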