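# cortexwave

Phase-velocity-field analysis of cortex-wide propagating waves in
wide-field voltage-imaging movies.

Slow (delta-band, 0.5–4 Hz) oscillations in cortex are not static: phase
contours travel across the cortical sheet as plane waves, stall as
standing waves, and organise locally around singular points — sources
(phase leads its neighborhood, flow diverges), sinks (flow converges) and
saddles. `cortexwave` is for researchers analysing such movies (voltage
or calcium imaging, or any scalar oscillation field on a grid) who want a
tested, scriptable pipeline from raw movie to wave-pattern statistics,
with a synthetic-data generator that makes every stage verifiable against
planted ground truth.

## The method

Given a movie `V(x, y, t)` at frame rate `fs`:

1. **Preprocess** — optional spatial coarse-graining (bicubic, scale 0.5;
   an 88×104 field of view becomes 44×52), zero-phase Chebyshev-II
   bandpass to 0.5–4 Hz, exclusion of frames whose spatial-mean amplitude
   deviates more than 3 SD (movement artifacts), and the per-pixel
   analytic signal giving instantaneous phase `φ(x, y, t)` and envelope.
2. **Phase velocity field (PVF)** — per frame pair, the flow
   `v_φ = (u, w)` minimising

   ```
   E(v) = Σ_pixels ρ(φ_t + u φ_x + w φ_y) + α (‖∇u‖² + ‖∇w‖²)
   ```

   (phase constancy + spatial smoothness; all phase differences circular;
   ρ quadratic or Charbonnier), solved by Gauss–Seidel iteration of the
   Euler–Lagrange equations. Vectors point in the direction of wave
   propagation, in pixels/frame.
3. **Pattern classification** — the order parameter
   `v̄_φ(t) = |Σ v_φ| / (N v₀)` detects plane waves (`v̄_φ ≥ 0.85`);
   standing waves are frames whose mean speed falls 2 SD below its
   time-series mean (checked first). Critical points are intersections of
   the bilinear nullclines of `u` and `w`; the local Jacobian's trace τ
   and determinant Δ classify them (source τ > 0, sink τ < 0, saddle
   Δ < 0; node vs focus by real vs complex eigenvalues) with Poincaré
   index +1/+1/−1. Tracks of singularities are filtered by a `(d, r)`
   detection threshold (lifetime ≥ d frames, pattern radius ≥ r pixels;
   default (5, 3)).
4. **Modes** — the flattened field sequence `w = TΣR*` (SVD) yields
   principal spatial modes, variance fractions `σ_k²/Σσ_i²` and per-frame
   projections `M = wR`.
5. **Statistics** — large-scale direction states (posteroanterior
   π/4 < θ < 3π/4, anteroposterior 5π/4 < θ < 7π/4 at `v̄_φ ≥ 0.5`, else
   disordered), reversal-scenario counts of sources/sinks around
   direction changes, per-pixel emergence-probability maps, regional
   averages, and Pearson correlation with a per-region hierarchy index
   against a 1000-fold pixel-permutation null.

Two surrogate generators validate that detected structure is not a
processing artifact: per-pixel spectrum-preserving temporal phase
randomisation and frame-consistent spatial pixel permutation.

## Worked example

A synthetic 44×52 movie (2 Hz, sampled at 20 Hz) carrying a plane wave
plus a stronger radial source at (14, 40), with additive noise:

```r
library(cortexwave)

spec <- movieSpec(
  shape = c(120, 44, 52), frameRate = 20, noiseSd = 0.2, seed = 1,
  components = list(
    waveComponent("plane", wavevector = c(0.12, 0.2), freq = 2),
    waveComponent("source", center = c(14, 40), radialWavenumber = 0.45,
                  freq = 2, amplitude = 1.5)))
movie  <- generateMovie(spec)
filt   <- maskArtifacts(bandpass(movie, band = c(0.5, 4)))
phase  <- instantaneousPhase(filt, bandLow = 0.5)
fields <- estimatePVFSeries(phase)

pts      <- do.call(rbind, lapply(fields, criticalPoints))
filtered <- filterTracks(trackPatterns(pts), d = 5, r = 3)
filtered$tracks
#>   trackId   type  d minRadius centroidRow centroidCol tStart tEnd
#> 1       1 source 39        11    13.91886    39.96084     41   79

ms <- svdModes(fields, kMax = 5)
round(varianceFractions(ms), 3)
#> [1] 0.989 0.002 0.001 0.001 0.001
```

The planted source is recovered as a single track covering all 39
analysable frame pairs (the first/last 2 s are analytic-signal edge
transients), centred within 0.1 px of the planted (14, 40), with a
pattern radius of 11 px — comfortably past the (5, 3) detection
threshold. The SVD concentrates 98.9% of the variance in one spatial
mode, as expected for a movie with a single persistent flow pattern. The
coherence statistic separates real from surrogate data: the median
gradient-of-PVF rises from 0.272 on the structured movie to 0.348 after
temporal + spatial shuffling (and by >5× for noiseless movies, see the
test suite).

A full run with intermediates and a checksummed manifest:

```r
runPipeline(pipelineConfig(seed = 1), outDir = "run1")
```

or from the shell: `inst/exec/cortexwave run-all --out run1 --seed 1`.

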