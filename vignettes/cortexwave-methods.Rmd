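---
title: "cortexwave: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortexwave: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where genuine design freedom was resolved by a choice
rather than by necessity.

## The model

The pipeline treats a wide-field imaging movie as a scalar oscillation
field $V(x, y, t)$ whose delta-band (0.5–4 Hz) component carries
propagating waves. The central object is the **phase velocity field**
(PVF): the per-pixel velocity at which contours of constant instantaneous
phase move. The underlying assumption is monotone spatiotemporal phase
propagation within the band — phase isolines deform smoothly between
consecutive frames. Everything downstream (pattern classification,
singularity tracking, modal decomposition, spatial statistics) consumes
the PVF, so its estimation dominates the package's numerical design.

### Coordinates and conventions

Row 1 is anterior (rostral); columns increase laterally to the right.
Velocity fields are stored as complex matrices $v = u + i\,w$ with $u$
the column (x) velocity and $w$ the row (y) velocity, in pixels/frame.
Propagation direction $\theta$ is measured counterclockwise from +x with
anterior taken as $-$row, so posteroanterior propagation falls in
$(\pi/4, 3\pi/4)$ and anteroposterior in $(5\pi/4, 7\pi/4)$; both bands
are open intervals, and boundary angles fall into the disordered class.
Pixel indices are 1-based, following R convention throughout (subpixel
critical-point locations are reported on the same grid).

## Preprocessing

**Coarse-graining** uses cubic convolution (Keys kernel, $a = -0.5$, the
weighted average of the nearest 4×4 neighborhood) applied separably; at
scale 0.5 an 88×104 frame becomes 44×52. The kernel reproduces
polynomials up to quadratic exactly, so smooth fields survive; edges use
replicate padding, so gradients flatten within two pixels of the border.

**Bandpass** is a Chebyshev type II design whose order comes from the
standard inverse-Chebyshev order rule: 40 dB stopband attenuation with
stopband edges at half the low passband edge and twice the high edge
(0.25 and 8 Hz for the default band). The zero-phase forward–backward
pass is applied as the filter's squared-magnitude response on the FFT
grid of reflection-padded traces. This is numerically exact in its two
defining properties — zero group delay and symmetry under time reversal —
and is stable even for the very narrow relative bandwidths this analysis
needs (0.5–4 Hz at a 150 Hz frame rate), where high-order time-domain
IIR recursions in transfer-function form are fragile. Config keys:
`band.low`, `band.high` (Hz), `cheby.attenuation_db`.

**Artifact masking** thresholds the *spatial-mean* trace of the filtered
movie at `artifact.k_sd` (default 3) standard deviations, flagging the
offending frames plus a guard margin of `artifact.guard_s` (default
0.5 s) on either side for filter ringing. The statistic could equally be
computed per pixel; the spatial-mean reading matches the notion of
excluded *periods* (movement affects the whole frame) and is the
documented interpretation here. Masking never alters data, only the
per-frame valid mask. A threshold that flags everything raises an error
rather than silently returning an empty analysis.

**Instantaneous phase** is the angle of the per-pixel analytic signal
(FFT Hilbert transform). Two reliability rules guard its failure modes:
the first and last $1/f_{low}$ seconds are flagged unreliable
(analytic-signal end transients), and pixels whose envelope falls below
$10^{-6}\times$ the median envelope are excluded (phase undefined at
zero amplitude). Unreliable pixels are dropped from the PVF data term
but smoothed over.

## PVF estimation

For a frame pair the flow minimises

$$E(v) = \sum_{x,y} \rho\!\left(\Delta\varphi_t + u\,\varphi_x +
w\,\varphi_y\right) + \alpha\left(\lVert\nabla u\rVert^2 +
\lVert\nabla w\rVert^2\right)$$

with every phase difference computed circularly as the argument of a
phasor product, which makes the estimate invariant to phase wrapping by
construction. Spatial phase gradients are central differences (one-sided
at borders) averaged over the two frames.

Choices the underlying references leave open, fixed here and exposed in
`flowSettings()`:

* **Penalty**: Charbonnier $\rho(r) = \sqrt{r^2 + \epsilon^2}$ with
  $\epsilon = 10^{-3}$ rad by default (robust to phase jumps at low
  envelope); quadratic available and used by the solver-equivalence
  tests.
* **Smoothness weight** $\alpha = 0.5$. The data term selects only the
  normal-flow component along $\nabla\varphi$; $\alpha$ resolves the
  aperture ambiguity toward the minimal-norm solution. On planted plane
  waves the estimate matches $\omega \mathbf{k}/\lVert\mathbf{k}\rVert^2$
  to under 5° in direction and 10% in speed (interior pixels), so the
  default is not eating signal.
* **Solver**: red–black Gauss–Seidel sweeps with an exact 2×2 block
  solve per pixel; the Charbonnier penalty enters through lagged
  half-quadratic weights, a majorise–minimise scheme, so the energy is
  non-increasing across sweeps (a tested invariant). Convergence
  requires both a relative energy change below `tol` (default $10^{-6}$)
  and a maximum velocity update below $\sqrt{tol}$; the second condition
  ties the stopping rule to solution accuracy rather than energy
  flatness. On 8×8 problems the converged fixed point matches a dense
  direct solve of the Euler–Lagrange system to $10^{-8}$.
* **Multiscale**: `nScales` (default 3) coarse-to-fine levels are used
  purely as initialisation (prolongation of the coarse solution, no
  warping). The energy is convex for both penalties, so the fine-scale
  minimiser is unique and the pyramid only accelerates convergence.
* **Boundaries**: replicate padding for derivatives; smoothness edges
  simply drop out-of-grid terms.

## Pattern identification

The frame-level classifier follows a fixed precedence: the standing-wave
criterion (mean speed more than `standing_k` = 2 SD below the mean of
the speed history over the analysed period) is checked *before* the
plane-wave criterion (order parameter $\ge$ `plane_thresh` = 0.85),
because a near-stationary field can have an arbitrary, meaningless
direction distribution. Everything else is `other`. For segmentation
into large-scale direction states the order-parameter threshold relaxes
to 0.5, trading purity for coverage of big-but-imperfect waves.

Critical points are intersections of the bilinearly interpolated
nullclines of $u$ and $w$. Because a bilinear function on a cell is a
convex combination of its corners, only cells whose corners straddle
zero in both components are candidates; within a cell the elimination is
a quadratic, so up to two intersections per cell are possible and both
are kept. The Jacobian at the subpixel location comes from the same
bilinear cell; classification follows the $(\tau, \Delta)$ chart, with a
scale-free degeneracy epsilon ($10^{-9}$ of the field's RMS gradient)
below which a point is reported untyped and excluded.

The **pattern radius** $r$ needed by the $(d, r)$ detection threshold has
no canonical definition; the rule here is: the largest $R$ such that
every pixel ring at Chebyshev distance $1..R$ has $\ge 80\%$
(`ring_agreement`) of pixels matching the type's directional signature —
the sign of the radial velocity component for sources/sinks, and for
saddles the quadrant sign pattern of $\hat r^\top J \hat r$. This is an
interpretation, exposed in config, and the reported radii should be read
relative to it.

**Tracking** is greedy nearest-neighbour linking of same-type points
across consecutive frames within `link_tol` = 2 px, ties broken by
distance, then lowest row, then lowest column — deterministic and
adequate for slowly drifting singularities; the tolerance makes explicit
how much spatial drift still counts as "the same location" for the
duration counter $d$. Raising $(d, r)$ can only shrink the surviving
set (a tested monotonicity), and the detection-probability surface is
normalised to its $(1, 1)$ value.

The census statistics (coexistence combinations, total Poincaré index
deltas) read directly off the filtered tracks. Pairwise
creation/annihilation of a source or sink with a saddle keeps the total
index constant (Poincaré–Hopf); nonzero deltas flag patterns crossing
the field boundary.

## SVD modes

Fields are embedded as real vectors (row-major real parts, then
imaginary parts, length $2HW$; 4576 for 44×52) and stacked into the
frames × $2HW$ matrix decomposed as $w = T\Sigma R^*$. Variance
fractions use the full singular spectrum as denominator even when only
`k_max` modes are kept. Mode signs are fixed so each mode's
largest-magnitude entry is positive, with projections flipped to match —
output is then deterministic across BLAS implementations. The
dominant/opposite direction split of a mode weights frames by *squared*
projection (energy) rather than counting frames; frame counting is the
other defensible reading, and the squared weighting is the documented
choice. Cross-dataset mode alignment is greedy maximisation of absolute
Pearson correlation between flattened modes.

## Spatial statistics

Reversal scenarios count source/sink tracks present in rostral/caudal
boxes (top and bottom 30% of rows by default — the boxes are a drawn
convention, not derivable, so they are config) during the last quarter
of a disordered episode or the first quarter of the following coherent
wave; quarters are floor-rounded with a 1-frame minimum. Counts are
normalised by the number of following waves of each direction and by
overall source/sink totals; the two normalisations commute only
approximately, so both orders are implemented behind `normOrder` and raw
counts are always emitted.

Emergence-probability maps divide track occupancy (locations rounded to
the nearest pixel) by the number of *artifact-valid* frames — the other
candidate denominator, total recording frames, would deflate
probabilities by an amount that depends on how twitchy the animal was.

The hierarchy correlation is a plain Pearson $r$ over regions with a
two-sided $t$-distribution p-value ($n-2$ df), plus a permutation null:
pixel locations of the probability map are shuffled, regionally
averaged and re-correlated `n_perm` = 1000 times. The synthetic region
fixture constructs its probability map so the regional means have
*exactly* the target correlation (residual projection plus affine
scaling, with within-region noise centred per region), then verifies to
±0.02. One subtlety: a fixture built with target 0 has correlation
exactly zero by construction, which is *not* a random draw from the
null — its null rank concentrates near ½. Uniformity of the observed
rank therefore has to be tested on maps exchangeable with their
permutation null (an extra pixel shuffle before ranking), which is how
the exchangeability test in the suite is phrased.

## The synthetic generator

`generateMovie()` sums kinematic wave templates — plane
($\varphi = \mathbf{k}\cdot\mathbf{x}$), radial source/sink
($\varphi = \pm k_r\lVert\mathbf{x}-\mathbf{c}\rVert$), spirals (radial
term plus polar angle), separable standing waves — plus white Gaussian
noise. Saddles are generated *implicitly* as two same-sign radial
components whose interaction region contains a saddle, reflecting how
saddles actually arise between interacting waves; an exact linear saddle
remains available via `generateLinearField()` for oracle tests. Default
amplitude 1 and `noiseSd` 0.2 are package conventions (the recordings
this emulates come with no published SNR), set once and not tuned.

What the generator does **not** emulate: hemodynamic and movement
artifacts with realistic structure (the bandpass is the pipeline's
stated noise defence, so the generator only needs spectrally flat
noise), curvature of the imaged cortical surface, regionally varying
SNR, and any biophysical (neural-mass) dynamics — templates are
kinematic. Passing tests therefore demonstrate correctness of the
*analysis* under its own assumptions, not that real cortex satisfies
those assumptions.

## Problem sizes and determinism

The test suite and examples run at deliberately modest scales chosen to
exercise every code path with comfortable margins: grids of 8×8 to
44×52, movies of 40–400 frames, 2 Hz carriers sampled at 20 Hz for
short-movie tests (several full cycles keep the analytic signal well
conditioned) and 150 Hz where the frame-rate convention itself matters,
1000-draw permutation nulls, and 100–120 seeds for distributional
checks. All generators and permutation tests are pure functions of their
seed; the pipeline manifest records config, package version and file
checksums so a run is reproducible from the manifest alone.

## Known limitations

* The PVF inherits optical flow's aperture problem: only the normal
  component of phase motion is observed; the smoothness term fills in
  the rest, so speeds in strongly curved flows are regularised
  estimates, not measurements.
* Critical-point detection at cell boundaries can report duplicate
  locations from adjacent cells; deduplication rounds to $10^{-6}$ px.
* Greedy tracking has no motion model; crossing singularities closer
  than `link_tol` within one frame step can swap identities.
* The standing-wave criterion is relative to the analysed period's speed
  history; segments dominated by standing activity shift their own
  baseline.
* TIFF export stores min–max normalised 32-bit floats (the writer's
  [0, 1] constraint); the serialized container is the lossless path.
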