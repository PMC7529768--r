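---
title: "Agent-based models of stem-cell patterning and the SCAPD metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agent-based models of stem-cell patterning and the SCAPD metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scapd)
```

## The biological setting

Mouse embryonic stem cells cultured on adhesive micropatterns — discs of
radius 97.5 um or ellipses of semi-axes 195.5 x 49 um — self-organise over
48 h. Cells primed for differentiation (brachyury-positive, T+) end up
preferentially at the disc edge or the ellipse tips, while naive (T-) cells
stay near the centre. This package asks how little cell-level behaviour is
needed to reproduce that pattern: it simulates colonies under combinations
of four motility rules and measures, with a purpose-built pattern distance
(SCAPD), how closely the simulated aggregate density matches a reference
data set.

## The agent-based model

Each colony is ~6 cells (half T+, half T-) seeded uniformly at random at
least 2 um apart, evolving for 192 timesteps of 15 min (48 h). The four
rules, toggled in all 16 combinations (model 1 = none, model 7 = i+iii,
model 14 = i+iii+iv, model 16 = all), are:

* **i — differential velocity.** T+ cells move at 100 um/h, T- at 40 um/h
  (measured values); without the rule both types use 40 um/h.
* **ii — differential persistence.** A cell keeps its heading for its
  persistence time (T+ 105 min = 7 steps, T- 15 min = 1 step) before
  re-polling a direction; without the rule both types re-poll every step.
* **iii — neighbour forces.** Every neighbour within the sensing radius R
  exerts a force of magnitude 1/D^2 along the joining axis — pushing T+
  cells away, pulling T- cells closer. The heading is the angle of the
  vector sum plus Gaussian noise with standard deviation sigma (degrees);
  a zero net force yields a uniform random heading (no information implies
  isotropy).
* **iv — border turning.** A move that would leave the micropattern turns
  the heading by a fixed angle alpha (default 20 degrees) in the sense that
  rotates it away from the direction of the nearest exterior point.

Movement is executed in 1 um sub-steps so that confinement and the 2 um
minimum separation are enforced along the path, not only at the endpoint:
a sub-step that would collide truncates the move, and one that would exit
the pattern triggers the rule-iv turn. Cells update in randomised order
each step.

The velocity-ratio refinement (used by the calibrated models) scales the
speed by |sum F| / sum |F|, so a cell in a balanced force field slows down
and a cell with aligned forces moves at full speed; with no neighbour in
range the ratio is defined as 1.

### Confinement without rule iv

The source material does not say how models lacking the border rule keep
cells inside the pattern. We initially truncated blocked moves at the
boundary, but that pins force-directed cells at the nearest wall: the
random model then accumulates cells at the rim instead of staying uniform,
and on the ellipse the pushed T+ cells stick to the long side walls rather
than reaching the tips — contradicting the emergent behaviour the models
are known to produce. We therefore use the standard agent-based idiom: a
blocked sub-step re-orients the cell uniformly at random (up to 20 tries,
else it stays put). This leaves an unbiased walk uniform over the pattern
and lets directed cells slide along the boundary.

### Interactions between rules

With rules ii and iii both active, the force-derived heading is re-polled
only when the persistence timer expires; with iii alone it is re-polled
every step. This keeps both rules' stated meanings but is one of several
defensible readings.

### Parameter defaults

| Parameter | Default | Why |
|---|---|---|
| sensing radius R | 100 um | neighbourhood analysis of the imaging data supports 50 um and above; 100 um spans the colony scale and lies in the calibration grid |
| direction noise sigma | 3 degrees | middle of the calibration grid {1, 3, 5} |
| border-turn angle alpha | 20 degrees | outputs are insensitive to alpha in 10-40 degrees |
| min separation | 2 um | nuclei projected from 3D to 2D |
| timestep / duration | 15 min x 192 | imaging cadence and 48 h endpoint |

## The SCAPD metric

For each cell type separately, pooled positions are turned into a density
map by Gaussian-kernel density estimation on a fixed 256 x 256 grid (the
pattern's bounding box inflated by 10% per side, shared by all maps of a
pattern so grid sums are comparable), with the diffusion (Botev) plug-in
bandwidth selected per axis; grid values are renormalised to sum to 1.
The high-density area (HDA) is thresholded at the mid-range
T = (max g + min g) / 2, its border points are extracted as iso-contours,
and a circle (disc) or ellipse (ellipse pattern) is least-squares fitted to
them — Kasa's algebraic fit for circles, the direct constrained conic fit
for ellipses. Because colonies are seeded at random, fitted borders are
symmetrised: disc circles move to the origin keeping their radius; ellipse
tip pairs become axis-aligned mirrored ellipses at (+/- mean |x|, 0)
sharing the per-axis maximum semi-axes.

The reference total density T_e of a type is the sum of its map's grid
values inside its HDA region; a model's T_m integrates the *model's* map
(estimated with the reference's bandwidths — "same estimator settings")
over the *reference's* borders. The distance is

SCAPD = |T_e,T+ - T_m,T+| + |T_e,T- - T_m,T-|,

zero exactly for the reference against itself and at most 2.

### HDA topology choices

The pipeline needs to know which side of a fitted border is the HDA:

* disc T-: one central circle, HDA inside;
* disc T+: the HDA is the rim annulus. Its border circle is fitted to the
  contour points lying **inside the density ridge** (the radius of the
  density maximum). Fitting to all contour points instead places the
  circle mid-ring, which makes the reference annulus mass numerically
  close to the uniform share and destroys the metric's ability to
  distinguish rim-concentrated from uniform patterns;
* ellipse T-: one central ellipse, inside;
* ellipse T+: a mirrored tip pair, inside; contours are assigned to a tip
  by the sign of their centroid's x.

The chosen side is auto-checked (the HDA side must be the denser side of
the border) and flips with a warning if the topology was mis-identified —
a guard for degenerate inputs such as uniform controls.

Multiple contours at level T are pooled before fitting (the marked border
points are what is fitted); contours with fewer than 6 points are dropped
as noise.

## Baseline metrics

For benchmarking, the package also implements the three distribution
distances the SCAPD approach is compared against: exact earth mover's
distance between density maps (Euclidean ground metric in um; maps are
block-sum down-sampled to 64 x 64 before the network-simplex solve — the
full 65 536-point transport is impractical), Kullback-Leibler divergence
with 1e-12 additive smoothing (kernel maps contain exact zeros), and the
ensemble CRPS of per-run density values against the reference, averaged
over grid points. These metrics are validated against an LP solve, closed
forms, and a brute-force estimator respectively.

## Synthetic reference data

The imaging data behind the study (186 disc and 152 ellipse colony images)
are not deposited, so the package generates synthetic stand-ins that
emulate the *qualitative* organisation: T- cells follow an isotropic
Gaussian at the centre (SD 0.35 of the smallest half-dimension); T+ cells
follow a rim-weighted radial beta law on the disc (r/R ~ Beta(5, 1.5)) and
a two-component Gaussian mixture at the ellipse tips (centres at
+/-(a - 30) um, SD 20 um); both are rejection-sampled to the 2 um interior
margin and 2 um separation, 6 cells per colony, half T+.

What the stand-ins do **not** reproduce: the empirical reference total
densities of the central HDAs (~0.82-0.85). A mid-range threshold cuts any
Gaussian-like blob at its half-maximum contour, which encloses about half
its mass regardless of scale, so synthetic central T_e values sit near
0.4-0.5; the empirical densities must be flatter-topped than any member of
this law family. The disc annulus T_e (~0.74 synthetic vs 0.7407
empirical) is reproduced well. Consequently, passing tests demonstrate the
pipeline's correctness and the models' relative behaviour under these
conditions, not a quantitative reconstruction of the unpublished data.

## Numerical choices

* Containment boundaries are inclusive; the ellipse interior margin
  shrinks each semi-axis by the margin (193.5 x 47 for the default 2 um).
* The nearest-exterior direction on the disc is radial (closed form); on
  the ellipse it is found by 1D minimisation over the boundary
  parametrisation, agreeing with dense boundary sampling to < 0.5 degrees.
* The diffusion bandwidth fixed point is bracketed on a log grid and
  solved by Brent's method; if no bracket exists (tiny or pathological
  samples) the estimator falls back to Silverman's rule with a warning.
* The transportation solver uses a spanning-tree (network simplex) basis
  with candidate-list block pricing and is exact up to degeneracy
  tolerances of 1e-11 on reduced costs; it matches an independent LP solve
  to ~1e-13 on random 8 x 8 problems.
* Grid searches and angle sweeps use common random numbers across
  combinations so that comparisons are low-variance; ties break towards
  smaller R, then smaller sigma.
* Simulation problem sizes in the test-suite and acceptance script: 50
  pooled colonies per model score, 50-100 per angle setting, 15-20 per
  grid-search combination, 60-186 reference colonies per ground truth.

## Known limitations

* Cell division, apoptosis, differentiation, cell shape and substrate
  mechanics are deliberately out of scope, as in the modelling framework
  this follows.
* SCAPD at 50 pooled colonies has a sampling noise floor of a few
  hundredths; model comparisons closer than ~0.05 should be treated as
  ties at that run count.
* The 16-model ranking on synthetic references reproduces the key
  qualitative result (force-based models with differential velocity beat
  the random model; the border rule helps on the ellipse), but fine
  ordering among the force-based models depends on how sharply the
  synthetic reference concentrates — an artefact of the stand-in, not of
  the metric.
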