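---
title: "Digital spindle methods: simulation, detection, tracking, registration and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital spindle methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`digispindle` turns volumetric time-lapse movies of EB1–GFP comets in
dividing cells into classified microtubule growth trajectories, and ships
a simulator that generates movies with known ground truth so every stage
of that digitization can be validated quantitatively. This vignette
documents the models, the parameters that matter, the numerical
conventions, and what the simulation does and does not establish about
real data.

## The imaging model

A growing microtubule plus end decorated with EB1–GFP is modelled as a
line emitter: a tip at the true position with an exponential intensity
tail behind it, along the negative of the instantaneous velocity,
truncated at the tail length. Defaults: tail length 500 nm (the envelope
of what EB1 comets show), decay shape 3 (intensity falls to ~5% at the
truncation point), short-axis diameter 25 nm. Because 25 nm is far below
both the voxel pitch and the optical resolution, the cross-section of the
rendered comet is entirely PSF-limited; the tail is sampled every 50 nm
and each sample convolved with the PSF analytically.

The PSF is a separable Gaussian with FWHM 230 nm laterally and 370 nm
axially — the dithered-mode resolution of lattice light-sheet microscopy.
Intensities are expected photon counts: each comet contributes
`peak_signal` photons per frame (default 1000, a well-exposed comet
movie), the two centrosomes are rendered as bright point foci (5× a
comet), and a constant background (default 10 photons/voxel) is added.
Photobleaching multiplies the *signal* (not the background) by
`exp(-bleach_rate * t)`; default 0.004 /s, i.e. ~20% loss over a 56.6 s
movie, consistent with the gentle bleaching that makes light-sheet imaging
attractive. Noise is Poisson on signal + background, followed by zero-mean
Gaussian read noise (sd 2), clamped at zero. A noise-free mode returns the
expected counts and is bit-reproducible.

Arrays use `dim = (nx, ny, nz)` with z the optical axis and the centre of
voxel `[1,1,1]` at physical position (0,0,0) µm, so tables (µm) and
volumes round-trip without ambiguity. The renderer samples the Gaussian
at voxel centres; at the calibration pitch of 0.05 µm this reproduces the
configured FWHM to within the sampling bias of linear half-maximum
interpolation (~1%).

## The synthetic cell

Acquisition defaults follow whole-cell dithered-mode imaging of mitosis:
75 volumes at 0.755 s (56.625 s), a 20 × 16 × 10 µm field of view, voxel
pitch 0.104 µm lateral / 0.25 µm axial. Four phase presets set the spindle
length d (prometaphase 7, metaphase 10, anaphase 12 with slow pole
separation, telophase 14 µm) and birth-zone densities. These geometry
values are package defaults chosen to look like typical cultured-cell
spindles; they are not measured values from any particular dataset.

The spindle drifts: the centrosome midpoint performs a Gaussian random
walk (default RMS 0.05 µm/s) and the axis direction a small-angle random
walk (default 0.5°/s), emulating the rotation and reorientation of
dividing cells. Comet trajectories are born as a Poisson process (desk
default 5.3 births/s ≈ 300 per movie; paper scale 100/s, which takes one
cell above 10,000 comet detections and 2,000 tracked trajectories — the
throughput regime of whole-cell LLSM digitization). Each trajectory starts
volume-uniformly within a spherical zone around a randomly chosen pole
(zone drawn from the configured densities, weighted toward the spindle
body), then moves in a straight line at constant speed drawn from its
zone's normal distribution, clipped to [0, 1] µm/s, with direction drawn
from a von Mises–Fisher distribution about the pole-to-opposite-pole axis
(default concentration 2; 0 gives isotropic growth). Zone mean speeds
default to a shallow gradient from 0.50 µm/s near the pole to 0.40 µm/s
at the periphery with sd 0.12, keeping most comets in the 0.3–0.6 µm/s
range typical of EB1 analysis. Lifetimes are exponential (mean 5 s);
trajectories truncate at the movie end and at the field-of-view boundary
(0.3 µm margin), and need at least two in-bounds positions to exist.

What the simulator does *not* emulate: lattice/Bessel illumination
optics, deskewing of sample-scanned raw data, depth-dependent aberrations,
motion blur within a volume scan, comet shape changes (catastrophe
intermediates), curved trajectories, and any cytoplasmic background
structure. Tests passing on this synthetic data therefore establish the
correctness and calibration of the pipeline's geometry and statistics, not
detector performance on real movies with structured background.

## Detection

Comets are detected per volume with a scale-normalized
Laplacian-of-Gaussian filter matched to the PSF (per-axis sigma converted
to voxel units, so anisotropy is handled; ratios above 10 are rejected
with advice to resample). Bright blobs give positive maxima; the filter is
linear and offset-free. 26-connected local maxima above a robust threshold
(median + k·MAD of the response, default k = 8, stable under bleaching;
noise-free volumes fall back to a floor of 1e-9 of the intensity scale to
ignore numerical ripple) pass greedy non-maximum suppression within a
minimum separation (default 0.4 µm, clamped to one voxel), then are
refined per axis by quadratic interpolation through the maximum (offsets
clamped to ±0.5 voxel; border axes left unrefined).

The comet tip is taken to be the intensity maximum. The tail pulls the
maximum slightly behind the true tip (on the order of 0.1 µm); this bias
is aligned with the velocity and roughly constant along a track, so it
cancels in the step lengths that feed speed estimates — which is why speed
recovery is much tighter than single-point localization. In the full
pipeline, detections within 0.5 µm of a known centrosome are discarded:
the centrosome foci are inputs to registration, not comets.

## Tracking

Consecutive frames are linked by a globally optimal one-to-one assignment
minimizing summed squared displacement among candidate pairs within a
gate, with birth/death alternatives priced at gate². The default gate is
`1 µm/s × Δt + 2 × lateral pitch`: the top of the expected speed scale
plus a localization allowance. The assignment is solved exactly
(Jonker–Volgenant shortest augmenting paths) per connected component of
the gated candidate graph; ties break deterministically by detection
order. There is no gap closing — a missed detection terminates the track,
matching the interpretation of comet disappearance as catastrophe — and no
merge/split handling. Tracks shorter than 4 points are discarded (a
package default; real studies may filter differently).

Mean travel speed is path length over elapsed time, the per-step growth
rate semantics of EB1 analysis; the net-displacement speed is reported
alongside it in every summary. At the default density, a birth landing
within the gate of a death in the adjacent frame occasionally chains two
trajectories into one track; the tests bound this at a few per cent of
trajectories.

## Registration (drift correction)

Each frame's detections are mapped into the canonical spindle frame by
the rigid transform that sends the centrosome midpoint to the origin and
the pole-1 → pole-2 direction to +x, so the poles sit at (±d/2, 0, 0).
Two centrosomes leave the roll about the spindle axis undetermined; it is
fixed for temporal smoothness by applying, at each frame, the minimal
rotation relative to the previous registered frame (first frame: minimal
rotation from the lab frame). An exactly antiparallel axis is resolved by
a deterministic 180° rotation about +z. Pole identity is fixed at the
first frame and propagated by proximity so the axis never flips. Each
frame's transform is a strict isometry (verified to 1e-9 µm); speeds are
exactly preserved when the pose is static, while under drift the
registered speeds differ from lab-frame speeds precisely because the
drift component has been removed — that is the purpose of the correction.
Centrosome positions come from simulation ground truth or a user-supplied
two-pole CSV; detecting centrosomes from images is out of scope.

Cells of the same phase can be merged in the canonical frame with
provenance retained; optional normalization divides each cell's
coordinates by its mean d (off by default, since it changes physical
units to spindle-relative ones).

## Classification

Speeds are binned into 10 half-open classes [k/10, (k+1)/10) µm/s, the
last closed above; out-of-range tracks are reported, never dropped. A
small epsilon (1e-9) in the bin arithmetic keeps exact edge values (0.3)
in the correct class despite floating-point division. Zones use spheres of
radius d centred on each pole, 10 shells of thickness d/10; a track is
assigned to the nearer pole by its start point (exact ties to pole 1 —
the spheres overlap mid-spindle since each radius is d, and the overlap
must be resolved somehow), shell index `ceil(10 r / d)` with r = 0 in
zone 1 and r > d labelled "outside". Travel angles are measured against
the directed pole → opposite-pole axis (0–180°, distinguishing poleward
from anti-poleward growth); the folded 0–90° version against the
undirected axis is emitted as a second column rather than guessing which
convention a given display used. Zero net displacement gives an undefined
angle, flagged and excluded from summaries. Random subsampling (e.g. the
~13% or ~20% used to thin trajectory displays) is uniform without
replacement, `round(fraction × n)`, seed-reproducible.

## Determinism and problem sizes

One global seed deterministically derives per-stage substreams
(geometry, trajectories, per-frame noise, subsampling), so stages can be
re-run in isolation and full runs are bit-reproducible; all derived seeds
stay below 2³¹. The test suite validates against exact oracles wherever
one exists (brute-force assignment enumeration, per-point zone
distance checks on 10⁴ random points, Monte-Carlo angle expectations) and
uses desk-scale simulations (~300 trajectories, 20 × 16 × 10 µm at
0.104/0.25 µm pitch, 75 frames) for end-to-end properties; the paper-scale
bound runs one metaphase cell at a coarser 0.15/0.3 µm pitch.

## Known limitations

- Detection assumes blob-like comets; it does not fit comet orientation
  or shape, and very close comets (≲ one lateral FWHM) merge.
- Linking has no motion model; fast comets crossing within a gate radius
  can swap identities.
- Registration trusts the supplied centrosome positions; errors there
  propagate rigidly into every classified coordinate.
- The simulator's straight-line, constant-speed trajectories make speed
  recovery easier than curved real trajectories would.
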