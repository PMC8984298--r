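---
title: "The nutrient-coupled FUCCI spheroid model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nutrient-coupled FUCCI spheroid model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spheroidr` simulates the growth of three-dimensional avascular tumour
spheroids whose cells carry FUCCI cell-cycle labels: red in G1, yellow in
early S, green in S/G2/M. This vignette records the model, its numerical
treatment, and the design decisions taken where more than one reasonable
choice existed. Everything quantitative stated here is computed by the
package's own test suite or acceptance script; nothing is asserted that the
code does not reproduce.

## The model

Cells are point agents at off-lattice positions in a cubic domain of side
`L`, with no volume, adhesion or exclusion: crowding acts only through the
shared nutrient field. Each agent carries a FUCCI phase and competes three
exponential clocks, with per-capita rates set by the non-dimensional local
nutrient concentration `c` in [0, 1]:

* **cycle progression** — the G1 (red) to early-S (yellow) commitment fires
  at `Rr(c) = Rr_max c^eta1 / (c_a^eta1 + c^eta1)`, an increasing Hill
  function that vanishes at starvation (the model's representation of
  G1 arrest) and half-saturates at the arrest concentration `c_a`. The
  yellow-to-green and green-to-red transitions are nutrient-independent
  constants `Ry` and `Rg`; the green-to-red event is mitosis and replaces
  the parent by two red daughters placed `sigma/2` on either side of it
  along an isotropic random direction.
* **migration** — a step of fixed length `mu` in an isotropic random
  direction, at rate `m(c)` rising from `m_min` to `m_max` with
  half-saturation at `c_m`.
* **death** — at rate `d(c)` falling from `d_max` (starvation) to
  essentially `d_min` (well-fed), with a steep Hill switch (`eta3 = 15`) at
  the death concentration `c_d`. A dead cell is removed; its position and
  time are kept in a ledger, mirroring how unlabelled necrotic material
  accumulates in the core of a real spheroid.

The nutrient obeys a reaction--diffusion balance whose diffusion timescale
is much shorter than the tissue-growth timescale, so the transient equation
is replaced by its quasi-steady limit `0 = lap(c) - alpha * v * c`, with
`c = 1` far away (Dirichlet on the domain boundary) and `v` the local cell
density. Only the ratio `alpha = kappa / D` of consumption to diffusivity
enters; the two are deliberately never stored separately.

The hybrid loop alternates exact stochastic simulation with field updates:
within each window of duration `t_star` every agent's rates are frozen at
the concentration it cached at the last field update, and events are drawn
with the Gillespie algorithm (exponential waiting times, selection
proportional to propensity, `O(log N)` via a Fenwick tree). At the window
boundary the density is re-binned (nearest-node control volumes), the field
re-solved, and every agent re-caches `c` at its current position. Daughters
born mid-window sample the *frozen* field at their own birth positions —
the field, not a lineage value, is what the window holds constant. The
waiting-time draw that overshoots the window end is discarded, which is
exact for a frozen-rate process by memorylessness.

## Parameters

The defaults (`default_params()`) are the calibrated WM793B melanoma
configuration: `N0 = 30000` cells in a ball of radius 245 um split
20911/995/8094 across red/yellow/green, `T = 240` h, `t_star = 1` h,
`alpha = 0.15` um/cell, `c_a = 0.4`, `c_m = 0.5`, `c_d = 0.1`,
`Rr_max = 0.047`, `Ry = 0.5`, `Rg = 0.062` per hour, migration between
0.06 and 0.12 per hour, death between 5e-4 and 2 per hour, and a 201^3
grid over a 4000-um cube (`h = 20` um). `d_max = 2` per hour is an
assumption of the source calibration, taken as given. All units are
micrometres, hours and cells throughout; there is no unit-conversion layer.

`desk_preset()` shrinks the domain to `L = 1500` um with `I = 76`
(preserving `h = 20` um) and changes nothing biological. This is the
configuration the acceptance layer simulates: three full-horizon
realizations fit on a single CPU in well under twenty minutes. The price
is a nearer far-field boundary (750 um from the centre against a final
outer radius near 300 um), which enriches the nutrient supply relative to
the full domain. The effect is not cosmetic: solving the field for the
same day-4 cell configuration on both domains raises the core minimum
concentration from about 0.11 to 0.13, and because the death switch is so
steep (`eta3 = 15` around `c_d = 0.1`) that cuts the core death rate
roughly tenfold. The visible consequence in our runs is that the necrotic
core first registers on day 5--6 of the reduced-domain simulations,
rather than the approximately day 4 expected of the full configuration;
the final outer diameter is unaffected (it lands in the 500--600 um
range either way). Users who need quantitative onset timing should run
the full domain and budget hours, not minutes, per realization. A
dedicated test pins the mechanism (the same cell ball solved on a
reduced and an extended domain always has the richer core on the reduced
one).

## Numerical choices

* **Field solver.** Seven-point finite-volume stencil on the uniform node
  grid; boundary nodes carry `c = 1` and are eliminated into the
  right-hand side, leaving a symmetric positive definite M-matrix. It is
  solved by conjugate gradients with an IC(0) incomplete-Cholesky
  preconditioner to a relative residual of 1e-8, warm-started from the
  previous window's field (the field evolves slowly, so the warm start
  saves a few dozen iterations per window). Correctness is pinned by two
  oracles: a dense direct solve of the identical linear system on grids up
  to 21^3 (agreement to 1e-10), and a finely resolved (dr = 1 um)
  spherically symmetric finite-difference solve for a uniform ball of
  cells (agreement within 2%; at matched coarse resolution the radial
  oracle's own truncation error at the density discontinuity dominates,
  so the oracle — never the solution under test — is the one refined).
  The discrete maximum principle guarantees `0 < c <= 1`; excursions
  beyond round-off (ten times the solver tolerance) are an error, smaller
  ones are clipped.
* **Direction sampling.** Migration and dispersal directions are uniform
  on the sphere: azimuth uniform on [0, 2 pi), polar cosine uniform on
  [-1, 1]. Sampling the polar angle itself uniformly would bias motion
  toward the poles and break the spherical symmetry the model otherwise
  preserves.
* **Arrest classification.** The model has no explicit arrested state; a
  red agent is counted as G1-arrested when its cached concentration is
  below `c_a`, the level at which the commitment rate has fallen to half
  its maximum. The classification is instantaneous, not time-averaged.
* **Boundary breaches** (an agent stepping outside the cube) abort the run
  with a diagnostic rather than clamping or reflecting: the domain is
  defined to be large enough that cells never reach it, so a breach means
  the configuration, not the cell, is wrong.
* **Seeds.** One master seed per realization drives every draw (all
  compiled code uses R's RNG stream), so runs are bit-reproducible;
  ensembles give realization `i` the seed `master + i - 1`.

## The quantification layer

Cross-sections mimic confocal imaging: agents within 6 um (half a cell
diameter) of the plane are drawn as 12-pixel discs at 1 um/pixel into
red/yellow/green/dead channels. The equatorial plane is `z = 0`; upper and
lower planes default to half the outer radius above and below it. Radii
are estimated from the image under an assumption of approximate circular
symmetry:

* the **outer radius** is the median over 360 rays from the foreground
  centroid of the outermost living-foreground crossing;
* the **necrotic radius** is the largest central disc whose living-pixel
  coverage stays below 10%. Viable tissue at realistic densities keeps
  roughly half of every central pixel covered, while a true necrotic core
  contains at most the odd straggler that has wandered in and not yet
  died; a per-ray innermost-crossing rule was tried first and is defeated
  by exactly one such straggler disc sitting near the centroid, which a
  cumulative coverage criterion shrugs off. Voids smaller than one cell
  diameter (14 um floor) are reported as zero — a "core" smaller than a
  cell is sampling noise, not anatomy;
* the **arrested radius** is the half-maximum crossing of the cycling
  (yellow + green) coverage profile on 6-um annuli, relative to its rim
  level. The half-maximum localizer is unbiased under the symmetric
  smearing introduced by drawing point cells as discs, where a low
  absolute threshold sits exactly at the smearing-leakage level and
  flickers between annuli. When no central non-cycling region exists the
  arrested radius is undefined (`NA`), so early-time plots show
  `ra` appearing only once arrest is real.

The ordering `ro > ra >= rn` is enforced on every emitted estimate, and
radial profiles are reported against depth from the periphery
`p = ro - r` so that growing spheroids can be overlaid: agent shell
densities share one global normalization (the maximum over all
subpopulations, shells and requested times), while the nutrient profile is
the shell average of `c` itself.

## The synthetic fixtures

`make_annulus_spheroid()` builds point clouds with the layered anatomy of
a late-stage spheroid — empty core, red-only arrested shell, colour-mixed
proliferative rim — at a default density of 1e-3 cells/um^3, the density a
mature simulated spheroid actually reaches. The fixtures exercise the
whole imaging pipeline against known ground truth (radii recovered within
a disc radius plus a couple of pixels across random seeds). What they do
not emulate: microscope noise, point-spread functions, fluorescence
bleed-through, or the gradual density and composition gradients of real
tissue — so passing fixture tests validates the geometry of the
estimators, not their behaviour on experimental images.

## What the tests do and do not show

The Gillespie engine is checked against analytic exponential waiting times
and, with consumption switched off (`alpha = 0`, so `c = 1` everywhere),
against the exact mean of the well-mixed branching process — the linear
three-compartment ODE including the residual death rate `d(1)` (about
5e-4 per hour; over 48 h that removes ~2% of cells, which matters at the
three-standard-error tolerance the comparison uses). These validate
event-level exactness and compartment bookkeeping, not the spatial
coupling, which is exercised by the full-horizon desk runs: red-dominated
core by about day 2, necrotic onset on day 5--6 (delayed from ~4 by the
reduced domain, as discussed above), outer radius growing approximately
linearly (R^2 > 0.95 on the ensemble mean over days 4--10) to a final
diameter in the 500--600 um range.

Problem sizes used by the checks: the stochastic suites use 1e4 waiting
times, 20 well-mixed realizations of 1000 cells over 48 h, and 20 fixture
seeds; the full-horizon checks use 3 desk-preset realizations of 30000
initial cells over 240 h with daily radii extraction. These sizes were
chosen so the whole suite runs comfortably on a laptop while keeping
Monte-Carlo error well inside every tolerance used.

## Known limitations

* No volume exclusion or mechanics: density can exceed close-packing, and
  the late-time cell density (~1e-3 cells/um^3) is an emergent number of
  the point-agent model, not a measured one.
* One nutrient species, symmetric far-field supply; no vessels, no
  multiple signals, no chemotactic bias.
* The image-processing operators are this package's own reconstruction of
  a confocal-style pipeline (ray median, cumulative coverage, half-maximum
  edge), stated here precisely so results are interpretable; they are not
  a reimplementation of any specific microscopy toolchain, and they
  process simulated images only.
* Parameter values are taken as given; the package deliberately ships no
  parameter-estimation machinery.
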