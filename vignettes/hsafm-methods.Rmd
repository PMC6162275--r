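---
title: "Models and methods behind hsafm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hsafm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions in `hsafm`: a pipeline for high-speed AFM (HS-AFM) topography of
a tetrameric channel in 2D-crystals, built around a synthetic scene
generator so that every analysis stage can be validated as parameter
recovery.

## The scene generator

### What it emulates

A topograph is a calibrated height map (nm) on a square pixel grid
(x right, y down, z up; angles in degrees, clockwise positive as
displayed). The generator composes three layers:

1. **Geometry.** Molecules are parametric footprints: a set of protrusions
   (spherical caps or Gaussian bumps) arranged with four-fold symmetry
   about the molecular axis. The surface is the pointwise **maximum** of
   all protrusion surfaces over the membrane plane at 0 nm — the tip
   contours the outer envelope of hard bodies; densities do not add.
   Crystals place footprints on a lattice: the activated (cAMP) preset is
   a square *a* = *b* = 11.6 nm cell with two tetramers (corner and
   centre), the centre molecule rotated 25° and raised 0.3 nm; the resting
   (cGMP/apo) preset an 8.1 nm cell with one tetramer. A circular patch
   mask produces a crystal patch with exposed membrane and a border.
2. **Tip dilation.** The imaged surface is the grayscale morphological
   dilation of the true surface by the reflected spherical apex,
   `out(x) = max_s[in(x+s) − t(|s|)]`, `t(d) = R − sqrt(R² − d²)`. The
   default radius is 2 nm: tip sharpness is not reported for this kind of
   data, and 2 nm represents the sharp end of what such imaging requires;
   it is a config parameter, not a fitted value. Dilation is extensive and
   monotone and preserves apex heights of isolated features — which is why
   peak-height morphometry survives it unchanged.
3. **Scan artifacts.** Cumulative per-frame drift (subpixel Fourier shift,
   so the injected value is exact ground truth for registration tests),
   per-scan-line Gaussian offsets (rows are fast-scan lines), and
   per-pixel Gaussian noise. Defaults: pixel size 0.35 nm (a 200–300 px
   frame over 100–250 nm, as in practice), pixel noise 0.05 nm, line
   offsets 0.02 nm, 1 s frame interval.

### Footprint presets

The presets encode the measured morphometry rather than any atomic model —
the analysis consumes only protrusion positions and heights:

| preset | protrusions | key numbers |
|---|---|---|
| intracellular, activated | 4 CNBD lobes + central C-linker disk | lobes 4.3 nm tall at 3.4 nm radius, rotated 25° CW; disk 3.2 nm |
| intracellular, resting | same topology | lobes 5.05 nm at 3.0 nm radius, unrotated |
| extracellular (both) | 4 pore-domain turrets | caps 0.3 nm tall at 2.4 nm radius |

With the activated lattice's 0.3 nm packing offset this produces the
extracellular 0.3/0.6 nm and intracellular 4.3/4.6 nm height classes. The
resting lobe height of 5.05 nm deserves a note: the experimentally
reported per-molecule height differences against the two activated classes
are 0.4 and 0.8 nm, which no single resting height reproduces exactly
(they imply 5.0 and 5.1 nm). 5.05 nm splits the difference and gives
site-wise differences of 0.45/0.75 nm — mean 0.6 nm, the conservative
vertical-displacement estimate. A consequence worth knowing: the
difference between the two *single-tetramer state averages* is
4.3 − 5.05 = −0.75 nm (the lower activated class against the resting
level), while the *class-mean* vertical change is −0.6 nm. The package
reports both; they answer different questions.

### What the generator does not emulate

No cantilever dynamics, feedback/parachuting artifacts, or electrostatic
tip–sample interactions; no mid-transition lattice repacking (transitioned
molecules are rendered with the target-state footprint at their original
positions; an optional `final_scene` renders fully transitioned frames
from the repacked lattice); protomers switch state as one concerted
tetramer. Passing tests therefore demonstrate that the analysis recovers
known geometry under realistic noise — not that it would survive every
artifact of real recordings.

## Preprocessing

**Flattening** subtracts a least-squares plane. By default the plane is
refit twice on the lowest 35% of residual pixels, so it tracks the exposed
membrane instead of being tilted by the protruding crystal; on a pure
plane both variants return all zeros, and the operation is idempotent.
Flattening is applied per frame — whether such processing is better done
per frame or globally is an open choice, and per frame is the safer
default for drifting data.

**Drift estimation** takes the translation maximizing the FFT
cross-correlation of mean-subtracted frames, refined to subpixel by a
separable 3-point parabolic fit, either frame-to-frame (accumulated) or —
the default — against the running average of already-registered frames,
which is more robust at low signal-to-noise. Frames whose normalized
correlation peak falls below 0.2 are flagged unreliable.
**Registration** shifts each frame by the negated track (Fourier
interpolation). The band swept in from the edge contains no data: it is
overwritten with the frame median and excluded via a recorded per-frame
valid region, which the state classifier respects. Re-estimating drift on
the registered movie must be done on the common valid crop — the moving
band edge otherwise biases the correlation.

## Lattice analysis

**Detection** reads the lattice vectors off the real-space
autocorrelation. Numerical details that matter:

- peaks are 3×3 local maxima inside a 4–20 nm annulus; only peaks within
  90% of the strongest survive, which removes the pseudo-peaks produced by
  partial motif overlap (the centred sublattice of the alternating
  packing, and half-lattice lobe coincidences of the resting packing);
- collinear families (fundamental + harmonics) collapse to their shortest
  member; among the remaining candidates the pair is chosen to prefer
  gamma closest to 90° and then the most equal lengths (both observed
  cells are square);
- subpixel refinement is parabolic with the correction clamped to ±0.5 px.
  The fftshift convention places zero displacement at
  `floor(n/2) + 1` for both parities — an off-by-one here costs a full
  pixel on one axis and ~1.7° on gamma, which is why the shift is tested
  explicitly;
- with no significant peak the result is a "no lattice" value, not an
  error.

**Site enumeration** fixes the lattice phase by maximizing, over a 25×25
phase grid in the unit cell, the mean of a ring-consistency statistic:
the minimum over the four half-strips (E/W/N/S, reach 3.0 nm, central gap
1 nm) of the local height maximum. A C4 molecule centre has a protrusion
on every side; a single off-centre protrusion or bare membrane leaves a
strip empty. The centred (two-per-cell) basis is accepted when candidate
centred sites score at least 70% of the corner sites. This test is
deliberately conservative — a centred sublattice whose motif barely clears
the noise floor (the 0.3 nm extracellular turrets) can be reported as a
one-molecule cell, and `detect_lattice(n_basis = 2)` exists for that case.
Phase accuracy is at the protrusion-ring scale (~1–2 nm); per-molecule
measurement windows tolerate that, but ground-truth site tables are the
better choice when they exist, and the simulator always provides them.

**Correlation averaging** aligns particles to an evolving mean by
translation only (molecules in a crystal share one orientation; the two
differently rotated tetramers of the activated cell are separated by
basis class instead). Three refinement passes, shifts bounded to a sixth
of the window. **Symmetrization** averages the map with its rotations;
quarter-turn orders (1, 2, 4) use exact array operations so volume is
conserved to machine precision, other orders use bilinear resampling
(volume within 0.1% for motifs with interior support).

## Morphometry

Heights are referenced to the membrane: the lowest mode of the height
kernel density with at least 20% of the peak density (fallback: 1st
percentile, with a warning). Per-molecule peak height is the mean of the
top 5 pixels in the site window — not the single maximum — for robustness
at the 0.05 nm noise floor; windows are 8 nm for the intracellular face
(lobes at 3.0–3.4 nm radius) and 6 nm for the extracellular face (turrets
at 2.4 nm; a wider square window would clip into the taller neighbour's
dilation skirt through its corners).

Class splitting is k-means at quantile initialization plus per-class
Gaussian statistics, with two collapse rules: adjacent means closer than
one pooled sd are inseparable, and for two classes a Gaussian-mixture BIC
comparison (`mclust`) must actually prefer two components — a k-means
split of a unimodal sample always *looks* separated (the halves of a
normal sit ~2.7 pooled sds apart), so the model comparison is what keeps
plain scatter from being reported as two states.

Radial distances use the centre of mass of the map thresholded at half
maximum and the four highest local maxima at a minimum separation of a
quarter of the map width, refined to subpixel; the statistic is invariant
to image rotation within 2%.

## Transition kinetics

The domino model is a continuous-time Markov process on the site graph
(neighbours within 1.3× the smallest inter-site distance; border sites
have fewer than four neighbours). An untransitioned site has hazard
`k0·c^m` with `m` transitioned neighbours; with border nucleation
(default) interior sites have zero hazard until a neighbour has switched,
so the wave necessarily starts at the border, where the molecules are held
by only 2–3 lattice contacts. Simulation is exact (Gillespie);
fixed-frame sampling happens only when rendering movies. The default
preset `sthk_domino_model()` (k0 = 0.0045 /s, c = 3 on a 20×20-site patch)
is calibrated so the transition half-time is ~150 s, the observed
timescale of the crystal wave; c = 3 sets the per-neighbour hazard ratio
that the exposure-time estimator in `neighbor_rate_analysis()` recovers.
Note that with border nucleation the zero-neighbour hazard bucket mixes
border sites (hazard k0) with gated interior sites (hazard 0), so that
bucket underestimates k0 by construction; parameter-recovery checks of the
estimator use the ungated model. These crystal kinetics are lattice-
limited and deliberately not comparable to solution gating rates.

State classification measures per-frame, per-site heights (circular 7 nm
windows), removes the known packing z-offsets, and thresholds at the
midpoint of the two state levels with a 0.1 nm hysteresis band against
flicker. The levels are calibrated from the pooled height histogram of the
movie itself (two-class split), which absorbs the shared measurement
biases — pixel sampling, tip dilation, membrane referencing; when the
movie contains a single state the split collapses and fixed template
heights (4.45/5.05 nm) are used. `t50` and the 10–90% rise time are
model-free linear-interpolation summaries, as no functional form for the
wave is established.

## Rotation fitting and mechanics

`fit_rotation()` scans the model against the observation in 0.5° steps
(circularly masked, zero-meaned, translation-optimal normalized
cross-correlation via FFT), then refines the best angle parabolically on
the periodic score curve. For a C4 molecule the angle is reported modulo
90° as the smallest-magnitude equivalent — the convention under which the
activation rotation is +25° (CW), not −65°. Cross-correlation over the
full topography is used rather than matching the four peak centres of
mass alone, which is ambiguous near quarter-symmetry degeneracies; the
centres of mass remain available (`peak_centers_of_mass()`) as the
volume-integral localizer.

The lever calculator works in degrees throughout (matching the arc
relation Δx = 2π·r·φ/360) with α = 0.5 as the typical amplitude-reduction
split in the force formula. The stiff-lever limit is the only case
implemented: no stiffness value exists for the C-linker, so the soft
linker remains a qualitative scenario.

## Electrophysiology

A two-state C↔O scheme is deliberately minimal: only Po and the unitary
amplitude are reproduced downstream. Defaults k_open = 15 /s,
k_close = 45 /s give Po = 0.25 with ~1100 gating cycles per 100 s trace,
so the time-weighted Po estimate lands within ±0.02 by design of the
recording length. Dwells are sampled exactly (exponential), channels are
independent, noise is Gaussian (0.4 pA) and the low-pass is a generic
causal 2nd-order Butterworth at 1 kHz — the exact phase response of the
hardware filter is irrelevant to Po. Idealization assigns
`round(current/amplitude)` (half-amplitude thresholds), then merges events
shorter than the dead time (default two filter time constants) into their
longer neighbour, operating on run-length vectors. The closed-state
regime (Po ~3×10⁻⁴) produces only ~45 openings per 3000 s, so long
recordings at a reduced 5 kHz sampling are used for the 1000-fold-scaling
check; the log-log slope of estimated Po versus k_open runs over three
decades.

## Problem sizes and determinism

The study-scale defaults are 6×6-cell activated and 8×8-cell resting
crystals (72/64 molecules, ~230 px frames), 20-particle averages for the
state maps, a 20×20-site kinetic patch, and 100 s recordings at 20 kHz —
sizes at which every stage's estimate sits well inside its tolerance while
a full pipeline run stays interactive. All stochastic stages take explicit
seeds; `run_pipeline()` derives stage seeds from one master seed and is
reproducible to the byte.

## Known limitations

- Site enumeration from images is heuristic (ring-consistency phase
  search); its basis-count test is conservative on low-relief faces.
- The generator's molecules are rigid two-state objects on a fixed
  lattice; occupancy defects, partial protomer transitions, and
  mid-transition repacking are not modelled.
- The fitted rotation is only defined modulo the molecular symmetry; the
  ±45° reporting window assumes the true motion is the small-magnitude
  branch.
- Drift registration assumes pure translation; scan-distortion
  (nonlinear) registration is out of scope.
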