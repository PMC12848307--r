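---
title: "vesselmech: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vesselmech: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmech)
```

vesselmech studies how endothelial cells (ECs) narrow a developing blood
vessel: by deforming (each cell becomes narrower), by rearranging (fewer
cells span the circumference), or both. The package has three layers —
tissue-scale strain decomposition, image-derived quantifications, and a
coarse-grained simulation of the actomyosin cortex — plus seeded generators
that emulate every input, so the whole pipeline runs and is tested without
microscopy data.

## 1. Strain decomposition

For any positive geometric quantity $X$ measured at two timepoints, the
strain is $\varepsilon_X = (X_2 - X_1)/X_1$. An unwrapped EC with area $a$
and aspect ratio $r$ (axial over radial) has radial width $w=\sqrt{a/r}$ and
axial length $l=\sqrt{ra}$, so $wl=a$ and $l/w=r$ exactly. The number of
cells needed to span the vessel is the effective cell number,

$$N_\mathrm{eff}^{(\mathrm{radial})} = \frac{\pi D}{w}, \qquad
  N_\mathrm{eff}^{(\mathrm{axial})} = \frac{L}{l},$$

with $D$ the vessel diameter and $L$ its length. Between two timepoints the
vessel strain factors exactly into a cell-deformation part and a
cell-number (rearrangement) part:

$$ 1+\varepsilon_D = (1+\varepsilon_w)\,(1+\varepsilon_{N,\mathrm{rad}}),
 \qquad
 1+\varepsilon_L = (1+\varepsilon_l)\,(1+\varepsilon_{N,\mathrm{ax}}). $$

Two design choices make these identities hold to machine precision, and both
deserve a note. First, strains are computed from *group means*: cells are
not tracked across days in the kind of longitudinal imaging study this
package models, so per-stage population averages are the natural estimand.
Second, $N_\mathrm{eff}$ is recomputed from the mean $D, L, w, l$ at each
timepoint rather than averaged per cell; averaging per-cell ratios would
break the factorisation by Jensen-type gaps. The identity residual is
carried in every output table (`strains.csv`) as a built-in self-check.

`labelMechanism()` turns the six strains into descriptive tags
(contributing / opposing / neutral per axis) using a dead-band of 0.02 —
strains smaller than 2 % are treated as noise-level. The dead-band is a
reporting choice only; no downstream computation depends on it.

```{r strain-example}
g <- genCellShapeTable(nCells = 30, noiseCv = 0.05, seed = 1)
strainAnalysis(g$vessels, g$cells)[[1]]
```

## 2. Image-derived quantifications

**Diameter from wall profiles.** A line drawn across a fluorescently
labelled vessel gives a profile with two wall peaks. The baseline is the
median of the outer 10 % of samples on each side (robust to noise; the
measurement itself is then invariant under intensity gain and offset). The
two most prominent peaks are the walls; for each, the two half-maximum
crossings — half-maximum meaning baseline $+ 0.5\,(\mathrm{peak} -
\mathrm{baseline})$, located by linear interpolation — define the wall
centre as their midpoint, and the diameter is the centre-to-centre
distance. The "half the maximum" prescription is ambiguous between
outer-edge and centre conventions; the centre convention is used because it
is unbiased by the thickness of the membrane label and symmetric under
mirroring. Repeated profiles of one vessel are averaged; three or more are
expected, as in standard practice.

**Normalisation.** Intensity traces are background-subtracted, clipped from
below at `floorFraction` (default 1e-4) of the series maximum (log of
non-positive values is otherwise undefined after background subtraction; a
warning is emitted), log10-transformed, and max–min scaled to [0, 1] so
channels with different gains are comparable.

**Junction/cortex ratio.** Mean ROI intensities along junctions and over
cortical actin, background-subtracted, ratioed and reported as log10 —
positive values mean junctional enrichment. The canonical ROI counts
(6 junction, 10 cortex, 2 background) are defaults with a consistency
warning, not hard limits.

**Recoil velocimetry.** After laser ablation the cortex retracts, opening a
gap that is tracked on a kymograph. Gap edges are found per time column at
the half-threshold between the intensity minimum and its flanking maxima
(sub-pixel by linear interpolation) — mirroring how a manual annotator
traces the bright edges; columns with insufficient contrast give `NA`, never
zero. The recoil velocity is the gap change over the first 10 s divided by
the elapsed time; for uniform sampling this equals the mean of per-frame
velocities, and a least-squares slope is returned as a cross-check. Three
line-ROI velocities are averaged per ablation.

**Cross-correlation lag.** Normalised correlation over integer-frame lags
with parabolic sub-sample refinement; positive lag means the first series
leads. `widthAlignmentLag()` detrends both series linearly before
correlating — slow drift from filament turnover otherwise biases the lag.

**Actin-organisation classifier.** The global structure tensor of the image
(energy-weighted gradient outer products) gives a dominant orientation and
a coherence in [0, 1]. Coherence below 0.2 is called mesh (M); otherwise
the dominant angle within ±30° of the vessel axis is longitudinal (L),
within ±30° of the perpendicular circumferential (C), in between M. This is
deliberately a *global, approximate* baseline: it reproduces clean C/M/L
textures and the circumferential-to-longitudinal trend, but a global
analysis cannot resolve mixed organisations (C-M on one half, M-L on the
other) the way a human annotator working per-region can; mixed classes
should be combined from per-view calls via `combineViews()`.

## 3. The coarse-grained cortex model

ECs lining a vessel are thin, so the cortex is modelled in 2D on a
rectangle of 8 µm (x, circumferential) × 30 µm (y, longitudinal), periodic
in y. Actin filaments are polar bead–spring chains (0.5 µm segments,
inserted with 2–6 segments and free to polymerise at the plus end up to
10; harmonic stretching; harmonic bending with stiffness 0.5 pN µm² — the
effective rigidity of bundled cortical filaments, far above a single
filament's, chosen because pN-scale tension paths buckle and the virial
cancels locally at single-filament stiffness). Two-headed motors walk
toward filament plus ends with a linear force–velocity relation clamped at
stall and detach at the plus end. Passive crosslinkers are springs that in
addition carry a nematic aligning stiffness (2 pN µm) between their two
host segments — a fascin-like parallel-bundling term, the ingredient that
lets the anchored filaments template bundle orientation; its forces are
equal-and-opposite within each host segment, conserving momentum and
torque, and are validated against finite-difference energy gradients.
Filaments depolymerise at the minus end between length bounds, and whole
free filaments turn over (delete and reinsert uniformly, count-conserving).

A small number of filaments (1 % in the `paper_like` configuration; 2 µm
long, about a quarter of the vessel width) are anchored: their plus-end
base segment is rigidly clamped — at membrane beads/wall points on
alternating sides in facing pairs (circumferential anchoring, so a bundle
can bridge straight across) or at fixed midline points (longitudinal
anchoring). Plus-end anchorage is the sarcomere geometry: plus-directed
motors then load anchored chains with tension, where minus-end anchorage
makes the same activity extensile. Anchored filaments also carry a higher
binding weight for reservoir attachment (junction-anchored scaffolds
recruit the bundling machinery). Phase 1 uses fixed walls; phase 2
replaces them with deformable membrane chains (stretching, bending, an
elastic foundation toward the rest position, pinned endpoints), and vessel
width is the mean left–right membrane gap.

Dynamics are overdamped explicit Euler–Maruyama: forces, then bead motion
$\Delta x = F\,\mathrm{d}t/\gamma + \sqrt{2 k_B T\,\mathrm{d}t/\gamma}\,\xi$,
then stochastic kinetics with per-step probabilities
$1-e^{-\mathrm{rate}\cdot \mathrm{d}t}$, in that fixed order on a single
RNG stream, so trajectories are bit-reproducible per (parameters, seed).

**Readouts.** The virial stress over a region of area $A$ is

$$\sigma_{\alpha\beta} = \frac{1}{A} \sum_{i>j}
  \langle f_{ij,\alpha}\, r_{ij,\beta} \rangle,$$

summed over interacting pairs whose midpoint lies in the region, tensile
positive; three-body bending terms are decomposed into centre-to-neighbour
pairs (which preserves forces and total torque). The time average
$\langle\cdot\rangle$ is realised as a sliding 30 s window — the
instantaneous virial of a thermal network is dominated by noise.
Circumferential alignment is $N_x^2 = \sum_{i \in R} n_{i,x}^2$ over unit
segment orientations, with $N_x^2 + N_y^2 = S$ (the segment count) exactly;
$N_x^2/S$ is 0.5 for an isotropic network and 1 for a perfect
circumferential bundle. The central region is the middle 8 µm band in y —
the band in which the anchored filaments sit — restricted to the interior
in x (2 µm in from either wall): stiff filaments near a wall align with it
sterically, and including those wall strips lets boundary-parallel chains
mask the bundle signal. Both the band and the inset are configurable.

**Numerical choices.** All parameters live in µm/s/pN and are configurable
(`cortexParams("paper_like")`, overridable per group, echoed into every
run's provenance record). dt = 1 ms with a per-bead drag of 0.5 pN s/µm
keeps dt below the explicit-Euler stability bound $\gamma/(4 k_\max)$ for
the stiffest springs (filament stretching, 100 pN/µm); the class validity
enforces the bound. Motor/crosslinker links and wall confinement use
20 pN/µm — springs attached to a shared bead stack their stiffness, so
these softer values keep clustered configurations inside the stability
margin. A per-step displacement limiter (0.1 µm) additionally tames rare
stiff transients; it is inactive during normal motion. Stochastic kinetics
are evaluated every 4 ms (operator splitting; beads move under 2 nm per
1 ms step, so this is an excellent approximation). The fluctuation
temperature is kT = 0.02 pN µm — an *effective active* temperature, since
cortical fluctuations are dominated by motor activity rather than thermal
motion; it sets the positional search rate by which filaments find binding
partners.

**What the anchors do.** Bundle orientation is controlled by where
filaments are anchored, which is the mechanism under study: with anchors on
opposite walls (facing pairs at the same height, so a bundle can bridge
straight across), circumferential bundles assemble and the circumferential
stress $\sigma_{xx}$ exceeds $\sigma_{yy}$ in the central region; with
midline anchoring the bundle and the stress anisotropy rotate by 90°. The
mechanics behind the sign are worth stating: a freely floating contractile
bundle averages zero stress (it is force-balanced), so directional stress
requires a load path — wall-to-wall through the anchors for the
circumferential case, and around the periodic boundary for the
longitudinal one. With a deformable membrane the circumferential tension
pulls the walls inward near the anchored band, and vessel width falls
while central alignment rises — the signature is a negative
width–alignment cross-correlation at positive (alignment-leading) lag. The
membrane foundation (0.3 pN/µm per bead) and drag (90 pN s/µm) give the
wall a minutes-scale response; they stand in for the unmodelled
compliance and dissipation of the vessel wall and surrounding tissue,
matching the minutes-scale width dynamics the model is meant to
reproduce. Lag estimates from single runs are noisy (the width responds
to a stochastic sequence of bundle episodes); ensemble analyses should
pool the cross-correlation curves across seeds before locating the
extremum, which is what the package's reproduction script does.

**Problem sizes.** The `paper_like` preset (400 filaments, 800 motors, 800
crosslinkers, anchored fraction exactly 1 %) is the reference
configuration; `reduced_test` (160/320/320 with 6 anchors, identical
physics constants) is used for seed ensembles. The reduced counts were
chosen so the network stays above the 2D stick-percolation threshold —
below it no force path can span the domain and anchoring cannot direct the
stress at all. The package's own analyses use ensembles of reduced runs of
10–60 simulated minutes with a 100 s burn-in; these sizes are stated here
as the package's choice of study scale. Anisotropy is assessed after
burn-in because anchored bridges assemble early from the uniform initial
condition, while long runs progressively coarsen the free network into
clusters.

**Limitations.** The model is 2D, neglects excluded volume (filaments may
cross), hydrodynamics, and biochemical signalling; motors and crosslinkers
do not bind membranes; all parameter values are declared package defaults
loosely calibrated to published coarse-grained actomyosin models rather
than fitted to data. Emergent quantities (bundle timing, lag magnitudes)
are stochastic and scale with the preset; tests therefore assert
directions, orderings and seed-majorities, not point values.

## 4. Synthetic data: what it does and does not show

Every generator returns machine-readable ground truth next to its data and
is deterministic per seed. They emulate the *statistical structure* each
estimator assumes — two-peak wall profiles with Gaussian noise, lognormal
(mean-corrected) cell-shape scatter, a linearly widening blurred gap,
autocorrelated lagged series, oriented stripe/cross-hatch textures — not
the appearance of real microscopy. Passing parameter-recovery tests
therefore demonstrates estimator correctness (absence of bias, sub-pixel
interpolation accuracy, invariances), not robustness to real-data
pathologies: uneven illumination, motion, segmentation errors, or
wall-thickness asymmetries are out of scope and would need study-specific
validation.

## 5. Decisions made where the design was open

- Aspect ratio is taken as axial/radial, so $l \ge w$ when $r > 1$; the
  convention is stated on every accessor that uses it.
- Vessels may be paired across days or sampled independently per stage;
  group-mean strains (the default) support both, and the tables carry IDs
  so a paired analysis can be layered on top.
- Episode detection uses normalised alignment $N_x^2/S$ with threshold 0.65
  and a 60 s minimum duration: raw $N_x^2$ scales with the segment count,
  so a scale-free criterion is required; 0.65 sits well above the isotropic
  level 0.5 and below full alignment.
- The recoil velocity is defined as window displacement over window
  duration (the least-squares slope is reported alongside); for uniform
  sampling and linear recoil the two coincide, and the tests assert it.
- Motor and crosslinker counts, rates and stiffnesses were chosen once so
  that the default configuration operates in the bundle-forming regime the
  model exists to study (anchor-controlled stress anisotropy); they are
  deliberately conservative and fully overridable.
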