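---
title: "Simulation and reconstruction methods for planar-scan photoacoustic mesoscopy"
author: "PAmeso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and reconstruction methods for planar-scan photoacoustic mesoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PAmeso)
```

# The imaging problem

Photoacoustic (PA) mesoscopy of the mouse brain with a Fabry-Pérot (FP)
ultrasound sensor works by firing nanosecond laser pulses into tissue;
absorbed optical energy (mostly in hemoglobin) launches ultrasound by
thermoelastic expansion, and a point-like optical sensor raster-scanned in
a plane above the head records one pressure time series per scan position.
An inverse problem — acoustic reconstruction — then maps the recorded
waveforms back to a 3D image of the initial pressure, whose contrast
follows optical absorption and therefore vasculature.

`PAmeso` implements the complete computational chain for this instrument
class in simulation: phantom generation, the acoustic forward model, the
sensor bench computations, 3D image reconstruction with one or two speeds
of sound, and the downstream image analyses (resolution fitting, depth-coded
projections, vessel segmentation, fluence compensation and dual-wavelength
artery/vein contrast). Everything is computed in SI units; display
conversions (µm, MHz) happen only in reports.

# Forward model

## Source model

Every absorber is a collection of uniformly heated spheres. A sphere of
radius $a$ and absorbed-energy amplitude $A$ observed at distance $d$
radiates the classical bipolar N-wave

$$p(t) \;=\; A\,\frac{d - c t}{2 d}, \qquad |d - ct| < a,$$

zero elsewhere: peak magnitude $A a / 2d$, centred on the arrival time
$d/c$, integrating to zero over its support. This closed form is
implemented in `spherePressureWaveform()` and cross-checked in the test
suite against an independent spherical-means (Poisson) solution of the wave
equation.

Wires are dense chains of overlapping spheres (centre spacing no larger
than the sphere radius) rather than analytic cylinders: one forward
primitive serves every phantom, and at that spacing the chain ripple is far
below the noise floor. Vessels are sphere chains along randomly branching
centrelines; each vessel's amplitude at wavelength $\lambda$ is
proportional to total hemoglobin times
$s\,\varepsilon_{\mathrm{HbO_2}}(\lambda) + (1-s)\,\varepsilon_{\mathrm{Hb}}(\lambda)$
with $s$ the oxygen saturation. The packaged extinction constants enforce
equality of the two coefficients at 800 nm (the isosbestic point) and an
oxyhemoglobin excess at 1,064 nm, which is the physical basis of the
artery/vein contrast; the exact numbers are package constants, not measured
values, and only their ordering matters for the analyses.

## Sampling the N-wave

At the default 125 MS/s a 9 µm wire sphere's N-wave lasts less than one
sample period, so pointwise sampling would alias most of its energy away.
`simulateSignals()` therefore stores in each sample the *exact average of
the waveform over that sample bin*, computed from the closed-form
antiderivative. This is equivalent to an ideal integrate-and-dump
anti-aliasing stage ahead of the digitiser and preserves both the arrival
time and the (signed) pulse energy; `binAverage = FALSE` restores strict
pointwise sampling for analytical comparisons.

## Sensor model

The FP sensor is modelled by

* a sampled impulse-response kernel: a Gaussian low-pass plus an
  exponentially decaying ringing tail that starts at the main pulse,
* a frequency-independent directivity gain per incidence angle
  (the FP sensor's coverage is close to 180°, so the default is unit gain
  across the aperture; `cosineDirectivity()` provides narrower profiles),
* additive white Gaussian noise with standard deviation equal to the
  full-band noise-equivalent pressure (NEP), 65.8 Pa by default. Only a
  full-band NEP is specified for the instrument, so no coloured-noise
  model is attempted.

The kernel is *designed*, not measured: given a target −3 dB amplitude
bandwidth (23 MHz by default) the Gaussian width is solved numerically
(`uniroot` on the FFT magnitude of the complete kernel, tail included) so
that the estimator in `frequencyResponse()` recovers the design bandwidth
exactly — a deliberate design round trip.

The tail parameters matter for axial resolution. A bandwidth-limited
estimate of the axial line spread for a 23 MHz sensor is roughly half of
what the instrument actually resolves (~90 µm axial), and the accepted
explanation is ringing of the sensor, aggravated by envelope detection.
We therefore calibrated the default tail once, before freezing the test
suite, so that the *simulated end-to-end* axial line-spread FWHM of a
sub-resolution wire matches the instrument's reported ~90 µm axial
response: amplitude 0.30 of the main peak, 100 ns decay, ringing at the
23 MHz band edge (the tail is associated with the sharp roll-off of the
response, so band-edge ringing is also the physically coherent choice —
and it is the only regime in which the −3 dB root solve converges to
exactly 23 MHz). All three parameters remain user-visible knobs of
`makeSensorModel()`.

Default sampling (125 MS/s, 720 samples per record in the wire experiment)
is a package choice satisfying Nyquist with generous margin at 23 MHz; the
instrument's digitiser settings are not part of the model.

# Sensor bench computations

`frequencyResponse()` normalises the FFT magnitude of a waveform to its
peak and reads the −3 dB point by linear interpolation between frequency
bins, with a rectangular window (records are short pulses). The *amplitude*
ratio convention is adopted for −3 dB; the bench figure does not state
whether amplitude or power was meant, and the convention is flagged here so
users comparing against power-ratio numbers can shift accordingly.
A spectrum that never falls 3 dB below its peak (a discrete delta) reports
the Nyquist frequency.

`directivityMap()` stacks per-angle magnitude spectra of a goniometric
sweep (181 waveforms from −90° to 90° at 1° steps on the bench). Gains are
normalised per frequency to the peak over angles — directivity is relative
gain versus angle — and the angular coverage is the widest contiguous angle
span whose gain stays above a threshold across a stated band. Instruments
of this class report near-180° coverage without stating a threshold, so the
package fixes it at gain 0.5 (the −6 dB power point), records it in the
result, and leaves it configurable.

`estimateNEP()` is the standard deviation of a calibrated signal-free
record: the full-band NEP, matching how the bench value is defined.

# Image reconstruction

## Universal back projection

`ubpReconstruct()` implements 3D universal back projection over the planar
aperture: every voxel $r$ accumulates the filtered term

$$b(t) \;=\; 2p(t) \;-\; 2t\,\frac{\partial p}{\partial t}$$

evaluated at the analytic time of flight from each detector, weighted by
the solid angle each detector cell subtends at the voxel,
$\cos\theta\,\Delta^2 / d^2$ (pitch $\Delta$, distance $d$, obliquity
$\theta$), normalised by the total weight over the aperture. Numerical
choices the algorithm description leaves open are resolved as:

* time derivative by central differences (one-sided at the record edges);
* delayed samples by linear interpolation between the two straddling
  samples;
* the far-field cosine form of the solid angle (exact spherical-cap
  weighting is negligible at pitch ≪ distance);
* times of flight outside the record contribute zero, and the truncated
  fraction is reported (`truncFrac` attribute) rather than silently
  dropped;
* voxels closer to a detector than half a voxel are excluded;
* the output stays signed — envelope detection is an explicit separate
  stage, mirroring the instrument pipeline.

## Dual speed of sound

For deep targets the head region is modelled as a single axis-aligned
ellipsoid of different (typically higher) speed inside a homogeneous
background. Time of flight is computed analytically on straight rays: the
quadratic for the ray/ellipsoid intersection gives the interior chord
$L_\mathrm{in}$, and

$$\mathrm{TOF} = \frac{L_\mathrm{in}}{c_\mathrm{in}} +
\frac{L - L_\mathrm{in}}{c_\mathrm{bg}}.$$

Straight rays (no refraction) are the only reading consistent with an
analytic two-speed time of flight; tangent and missing rays have zero
interior chord. An arbitrary-orientation ellipsoid is deliberately not
supported — a rotation would complicate the quadratic without an
instrument-side specification of how the orientation would be set. When
the two speeds are equal the code short-circuits to the homogeneous
expression, so single-SOS and degenerate dual-SOS reconstructions agree
bit for bit (a property the tests assert).

## Envelope detection

`hilbertEnvelopeZ()` replaces every (x, y) column by the magnitude of its
analytic signal along z (FFT method), eliminating the bipolar artefact.
The envelope is non-negative and pointwise dominates the absolute input;
both properties are asserted in the tests.

# Image analysis

* **Resolution** (`estimateResolution()`): per wire, the intensity peak is
  located in a search window, axial (z) and lateral (x) profiles through
  the peak are fitted with a Gaussian plus constant offset
  (Levenberg-Marquardt), and FWHM $= 2\sqrt{2\ln 2}\,\sigma$ is reported.
  Fits with $r^2 < 0.5$ flag the wire unusable and exclude it from the
  lateral-vs-depth trend. `pulseLimitedResolution()` is the
  stress-confinement bound, pulse duration × speed of sound (25 ns × 1500
  m/s ≈ 38 µm).
* **Depth-coded MIP** (`depthCodedMIP()`): per projected pixel, maximum
  intensity and arg-max depth along the ray, ties broken towards the first
  (shallowest) index; the depth layer is mapped through a colormap and
  modulated by normalised intensity.
* **Segmentation** (`segmentVessels()`): hysteresis thresholding — seeds at
  or above the high threshold grow into 26-connected voxels at or above the
  low threshold — followed by a minimum-size filter and relabelling by
  decreasing size. The instrument publication does not specify its
  segmentation method; hysteresis thresholding is the simplest reproducible
  choice and both thresholds are configuration values.
* **Fluence** (`computeFluence()`): the depth decay of illumination below
  an arbitrary surface profile follows the diffusion approximation,
  $\Phi = \exp(-\mu_\mathrm{eff}\, z_\mathrm{below})$ with
  $\mu_\mathrm{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}$. A closed-form slab
  model was chosen over photon-transport Monte Carlo deliberately: it is
  desk-verifiable, fast, and swappable behind the same interface; the
  optical coefficients used by the instrument's own fluence run are not
  published, so they are free parameters here. `fluenceCompensate()`
  divides by the fluence clamped below at a floor, capping the deep-tissue
  gain at 1/floor.
* **Dual-wavelength difference** (`dualWavelengthDifference()`): both
  envelope volumes are normalised by total energy and subtracted,
  $D = \hat V_{1064} - \hat V_{800}$; positive $D$ is artery-like, negative
  vein-like. "Total energy" is ambiguous between an L1 and L2 reading; the
  package uses the **L1 sum** of envelope amplitudes because it preserves
  the mean-amplitude comparison semantics of the per-vessel analysis, and
  the choice is recorded in the analysis output. No registration between
  wavelength volumes is attempted: the scan hardware bounds the positioning
  error well below the resolution, and pixel-accurate inter-run alignment
  is explicitly out of scope.

# What the synthetic data does and does not emulate

The generator reproduces the experiment's *structure*: scan geometry
(128 × 128 points at 100 µm pitch in the full protocol), one pulse per
point at 10 Hz, a ~23 MHz sensor with near-180° coverage and 65.8 Pa
full-band noise, sub-resolution wire targets at graded depths, and
branching artery/vein trees with extinction-weighted dual-wavelength
amplitudes. It does **not** model acoustic attenuation or dispersion,
refraction at the speed-of-sound boundary, skull or coupling-membrane
acoustics, breathing motion, or full-wave propagation — so passing tests
demonstrate the correctness of the computational chain under its own
forward model, not instrument-grade realism. In particular, quantitative
oxygen-saturation estimation is out of scope (it was not achieved on the
instrument either).

# Problem sizes and reproducibility

The package's standard desk-scale experiments are chosen to keep a full
test run in the minutes range on one CPU: the wire study uses a 32 × 32
scan (1,024 waveforms), three wires at 2/4/6 mm, 720 samples per record at
125 MS/s and a 101 × 21 × 251-voxel grid at 20 µm; the vessel study uses a
24 × 24 scan and a 51 × 51 × 54-voxel grid at 60 µm. Wire amplitude is set
so peak signals are tens of times the noise floor, reflecting the strong
optical contrast of tungsten targets. All randomness (phantom geometry,
noise) flows from explicit integer seeds; `runPipeline()` derives fixed
per-stage substreams from one master seed so that re-running a
configuration reproduces every artifact bit for bit, and the manifest
records MD5 checksums to prove it.

# Known limitations

* The ringing-tail parameters are calibrated to reproduce one scalar
  (axial line-spread width), not the full measured waveform; the spectral
  phase of the real sensor is not modelled.
* The diffusion fluence model underestimates near-surface fluence
  structure (no boundary term, no source profile).
* Hysteresis segmentation merges vessels that touch at the reconstruction's
  resolution; the per-vessel analyses therefore classify labels by overlap
  with the generating geometry when ground truth is available.
* The limited-view geometry of a planar aperture blurs structures whose
  wavefronts miss the scan plane; localization accuracy is asserted only
  inside the ~60° acceptance cone.
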