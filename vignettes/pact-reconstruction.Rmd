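---
title: "Back-projection reconstruction for photoacoustic computed tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-projection reconstruction for photoacoustic computed tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pactrecon)
```

## The imaging problem

In photoacoustic computed tomography (PACT) a short laser pulse deposits
energy in optically absorbing tissue; thermoelastic expansion launches an
acoustic wave whose initial pressure $p_0(\mathbf{r})$ is proportional to
the local optical absorption.  An array of $N$ ultrasound transducer
elements at positions $\mathbf{d}_i$ records time-resolved pressure traces
$p_i(t)$, and image reconstruction inverts these traces back to
$p_0(\mathbf{r})$.

`pactrecon` implements the two standard time-domain inversions.
Delay-and-sum (DAS) assigns every reconstruction point the
solid-angle-weighted sum of the detector signals at that point's
time-of-flight delay:

$$
p_0(\mathbf{r}) \;=\;
\frac{\sum_{i=1}^{N} p_i\!\left(t = \frac{|\mathbf{d}_i - \mathbf{r}|}{c}\right)\,\Delta\Omega_i}
     {\sum_{i=1}^{N} \Delta\Omega_i},
$$

where $c$ is the speed of sound and $\Delta\Omega_i$ the solid angle the
$i$-th element subtends at $\mathbf{r}$, proportional to
$\cos\theta_i / l_i^2$ with $l_i = |\mathbf{d}_i - \mathbf{r}|$ and
$\theta_i$ the angle between the element normal and the direction to the
point.  Filtered back-projection (FBP) back-projects the integrand
$q_i(t) = p_i(t) - t\,\partial_t p_i(t)$ instead of the raw pressure,
which sharpens boundaries.

For a planar aperture at $z = 0$ with all normals $(0,0,1)$,
$\cos\theta = z_j / l_{ij}$, so the per-element weight reduces to
$z_j / l_{ij}^3$ where $z_j$ is the depth of reconstruction point $j$.
The discrete forms drop the constant $\sum_i \Delta\Omega_i$ denominator
for a large planar array; the flag `normalize_solid_angle` restores it.
**Recommendation:** leave it off for planar scans (where the total solid
angle is nearly constant over the field of view) and turn it on for
strongly curved apertures such as the hemisphere, where the uncompensated
$1/l^2$ weighting visibly tilts the image toward the array (see
"Numerical behavior" below).

## The data model

The acquisition is described by a YAML configuration whose core keys are
the speed of sound `vs` (m/s), sampling frequency `fs` (Hz), the channel
/ scan-step / time-sample counts, the grid spacing `res` (m), the raw
data directory and its sample type.  Raw data arrive as one headerless
little-endian binary file per scan step, channel-major within the file;
`import_raw_data()` concatenates them into a signal matrix with row index
$s \cdot n_{\text{channels}} + c$ (zero-based) for channel $c$ of step
$s$ — the same ordering in which `build_planar_synthetic_array()`
enumerates the equivalent 2-D matrix-array elements, so row $i$ of the
matrix always belongs to element $i$ of the array.  Files are ordered by
the numeric token in their filename, never by directory listing order.

Preprocessing applies, in order: an optional zero-phase bandpass
(3rd-order Butterworth run forward and backward, so the filter adds no
group delay at the cost of squaring its magnitude response); optional
rational resampling (zero-stuffing followed by a centered FIR low-pass
and decimation — the installed `signal::resample` port produced incorrect
output in our validation, so the resampler is implemented in the
package); and finally the first and last sample of every trace are set to
exactly zero.  That last step is load-bearing: the beamformer clamps any
out-of-record delay index onto those boundary samples, so geometry that
falls outside the recorded time window contributes exactly nothing
without per-voxel branching.

## Detector geometries

Two builders cover the geometries treated here:

* `build_planar_synthetic_array()` — a linear probe of `num_channels`
  elements (pitch along $x$) scanned over `num_steps` positions (step
  along $y$) is equivalent to one large planar matrix array at $z = 0$,
  centered on the origin, imaging the half-space $z > 0$.  The element
  pitch of a physical probe is hardware-specific and therefore a required
  parameter with no default.
* `build_fibonacci_hemisphere()` — $n$ elements on the lower hemisphere
  ($z \le 0$) of radius $R$ using the golden-angle lattice
  $z_i = -R\,(i + 0.5)/n$, $\varphi_i = i\,\pi(3 - \sqrt 5)$, which
  distributes points nearly uniformly and avoids the ring artifacts of
  latitude–longitude layouts.  Normals point at the hemisphere center.

The reconstruction grid stores an origin (center of the first voxel),
isotropic spacing, and voxel counts `round(extent / res)` per axis;
voxel centers are symmetric about the requested center.  Voxels are
linearized $x$-fastest, $z$-slowest, making constant-depth slabs
contiguous — the layout the partitioned driver exploits.

## The analytical forward model

The simulator produces band-unlimited point-detector recordings of
uniform spherical absorbers.  For a sphere of radius $R_s$ and initial
pressure $p_0$ at distance $d$ from an ideal detector, impulsive heating
yields the bipolar N-wave

$$
p(t) = p_0\,\frac{d - c\,t}{2\,d}
\quad\text{for } |d - c\,t| \le R_s,\qquad 0 \text{ otherwise},
$$

with constant material prefactors absorbed into $p_0$.  Each trace is the
instantaneous value of this waveform at $t_k = k / f_s$ (no aperture or
bandwidth integration — the ideal-detector assumption), phantoms
superpose linearly, and optional additive Gaussian noise is seeded so
fixtures are bit-reproducible.

What this emulates — and what it does not: the generator reproduces the
geometry-dependent delays, $1/d$ amplitude decay, and the N-shaped
signature that drive back-projection, but real data additionally carry
transducer bandpass response, finite element apertures, acoustic
heterogeneity and system noise.  Tests passing on these fixtures
therefore validate the reconstruction *operator* (delays, weights,
derivative term, partitioning, I/O), not robustness to real-system
distortions.

## Numerical choices

* **Delay rounding.**  Nearest-sample indexing rounds half away from
  zero; linear interpolation between the two bracketing samples is
  available behind `interpolation: linear`.  Both clamp into
  $[0, T - 1]$, landing out-of-range delays on the zeroed boundary
  samples.
* **Temporal derivative.**  The FBP integrand uses central differences
  (one-sided at the record ends, then boundary re-zeroed).  For the
  piecewise-linear N-wave the central difference is exact away from the
  support edges; at the edges it concentrates the jump into a two-sample
  transient, which is the discrete analogue of the derivative-of-step
  delta and is what localizes boundaries.
* **Accumulation.**  Per-voxel sums accumulate in 64-bit floating point
  (R's native numeric); volumes are written to disk as 32-bit floats with
  a YAML sidecar.  R has no in-memory 32-bit array type, so the in-memory
  representation is double throughout.
* **Backward half-space.**  Points behind a detector's plane
  ($\cos\theta < 0$) receive weight 0.
* **Degenerate inputs.**  A voxel coincident with a detector is an error
  for the scalar weight helper; the beamformer never evaluates it because
  grids are validated to have positive extent away from elements in
  practice, and a zero distance would raise on the $1/l^2$ evaluation.

## Depth-slab partitioning

The space-separation strategy splits the grid into `num_devices`
contiguous depth slabs (thicknesses differing by at most one plane,
remainder planes to the earliest slabs), dispatches one back-projection
subtask per slab to a pool of forked worker processes, and concatenates
the slab volumes in order.  Each worker receives the full signal matrix
and detector array — partitioning the detectors instead would force every
worker to hold the whole volume, which is the memory-bound axis for large
grids.  Because per-voxel arithmetic is independent of slab membership
(slab grids carry an integer plane offset so voxel coordinates are
computed by the *same* floating-point expression as in the monolithic
grid), the partitioned result is bit-identical to the monolithic one for
every worker count; the suite verifies this for 1, 2, 3 and $n_z$
workers.  On platforms without `fork`, slabs run sequentially — the
contract is the partition/merge semantics, not the scheduling mechanism.

## Postprocessing

Back-projected volumes are bipolar.  Three rectifications are provided:
absolute value, squaring, and envelope detection (magnitude of the
analytic signal, computed along depth lines — the acoustic time-of-flight
direction, where the RF-like oscillation lives).  `normalize_volume()`
maps the result affinely onto $[0, 1]$, and `mip()` takes per-pixel
maxima along a chosen axis; `write_mip_png()` exports 8-bit grayscale.

## Numerical behavior of the sphere study

The package's reference simulation is a 1024-element Fibonacci hemisphere
of radius 100 mm viewing a 1 mm uniform sphere at its center, 5 mm cube
field of view at 0.2 mm spacing, 40 MHz sampling, reconstructed with FBP.
The record length is 2900 samples so the farthest voxel's time of flight
(≈ 2790 samples) stays inside the record.

Two behaviors of this study are worth understanding before reading the
tests:

* **The interior plateau.**  For the N-wave, the FBP integrand
  $q = p - t\,\partial_t p$ equals $p_0 / 2$ *everywhere inside* the
  support — the exact inverse of a uniform sphere is constant inside the
  sphere.  Consequently every voxel deeper than about one sampling
  interval inside the sphere back-projects to the same value, and "the
  maximum voxel" is a plateau of ≈ 360 voxels, not a point.  With
  solid-angle normalization the center voxel ties the global maximum to
  ~$10^{-13}$ relative; without it the $\cos\theta / l^2$ weighting tilts
  the plateau by ~1.6 % toward the array and the unique maximum sits
  ≈ 0.9 mm below center.  The suite therefore asserts that the center
  voxel *attains* the maximum (normalized FBP) and that the full width at
  half maximum of the central profile recovers the 2 mm sphere diameter;
  point-localization properties (translation tracking, DAS/FBP peak
  agreement) are tested with point-like one-voxel absorbers, where a
  peak is well defined.
* **DAS is bipolar.**  Raw DAS back-projects the N-wave itself, whose
  value at the sphere center is zero; its raw maximum sits at the sphere
  boundary.  After envelope detection DAS and FBP localize a point-like
  absorber to the same voxel, which is how the agreement property is
  stated.

## Problem sizes in the test suite

Unit and property tests run on grids of $5^3$–$15^3$ voxels with 12–128
detectors; the end-to-end study uses the full 1024-element hemisphere on
the $25^3$ field of view, and partition invariance is exercised with 256
elements on the same grid.  These sizes keep the whole suite under half a
minute while exercising every code path at full record length
(2900 samples); the operator is $O(N \cdot n_{\text{voxels}})$, so
correctness established at these sizes transfers unchanged to larger
grids.

## Known limitations

* No finite transducer aperture, per-element directivity, or bandpass
  response in the forward model; no heterogeneous speed of sound.
* No iterative / model-based or frequency-domain reconstruction.
* The FBP edge transient is resolution-limited by the sampling interval;
  quantitative edge amplitudes depend on the derivative discretization.
* "Devices" map to forked CPU worker processes; GPU execution and
  multi-device memory policy are outside the package's scope.
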