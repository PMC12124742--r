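---
title: "Grid-based overlap resolution in individual-based microbial models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based overlap resolution in individual-based microbial models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Individual-based models (IbMs) of microbial growth treat every cell as an
explicit agent: cells take up substrate, grow, divide, and push each other
apart.  The mechanical step — *shoving*, the restoration of a physically
feasible arrangement after growth and division have created overlaps — is
the classical bottleneck.  Pairwise approaches need neighbor searches
(arrays are O(N^2); a kd-tree improves a query to O(log N) but the
population sweep is still O(N log N) and the tree must be rebuilt as cells
move).

`dorasim` implements a grid-based alternative that resolves all overlaps in
a population with O(N) work plus grid-local operations, together with a
kd-tree relaxation shover as the pairwise comparator and a minimal IbM
(Monod growth, substrate diffusion, colony and biofilm scenarios) to
exercise both resolvers under realistic growth dynamics.

## The grid-based resolver

The resolver works in three phases on an occupancy lattice of `W x H` units
of size `w x h` (about 1 um, the scale of a cell radius).

**Forward translation.**  Each circular cell of radius `r` centered at
`(xc, yc)` (grid units) is approximated by its bounding square,
`x_left/right = xc -/+ r/w`, `y_bottom/top = yc -/+ r/h`.  Every grid unit
covered by the square receives the fractional overlap area (the product of
the clipped horizontal and vertical extents).  Summing over cells gives the
occupancy matrix `Omega`: a unit with `Omega > 1` is over-occupied — cells
overlap there.  For an interior cell the contributions sum to
`(2r/w)(2r/h)` exactly, and the normalization by the unit area cancels when
the bounds are expressed in grid units.

**Overlap resolution.**  The excess `E = max(0, Omega - 1)` is redistributed
iteratively towards the von Neumann neighborhood,

    Omega' = Omega - alpha * (E - (1/4) * sum_{neighbors} E),

a diffusion-like update acting only where excess exists (a Moore variant
uses 8 neighbors with weight 1/8).  `alpha` is a numerical diffusivity
factor in (0, 1]; every such step conserves total occupancy on a periodic
grid because each unit's quarter-shares are exactly the shares its
neighbors receive.  While the occupancy relaxes, a four-layer motion tensor
`M` accumulates the directional outflow per unit,
`M[i][j][d] += alpha/4 * max(0, E_ij - E_kl)` for the neighbor `(k, l)` in
direction `d` (down, right, up, left).  Iteration stops when the largest
per-unit occupancy change falls below a threshold or an iteration cap is
reached; residual excess is reported, not treated as an error, because the
next resolver call (IbMs call the resolver every movement step) continues
the job.

**Back-translation.**  Each unit's movement vector is
`v = (M_right - M_left, M_up - M_down)`.  A cell sums the vectors of the
units it covers.  Units covered by several cells split their directional
magnitudes: of the `N` covering cells, `round(N * M_right / (M_right +
M_left))` move rightward (vertical analogously), each mover receiving an
equal share.

## Design choices in the open parts of the scheme

Several details of the scheme admit more than one reading; the package
fixes them as follows.

* **Motion-layer clamping.**  Accumulating the signed flow
  `alpha/4 * (E_ij - E_kl)` can *decrement* a layer when the neighbor has
  the higher excess, making layers lose their meaning as "displacement
  toward direction d".  Layers therefore accumulate only non-negative
  outflow, and direction is recovered by the differences in the
  back-translation; signed accumulation is available via
  `resolution_config(signed_motion = TRUE)` and is equivalent in symmetric
  two-cell configurations.
* **Which cells take which direction.**  The ratio rule fixes *how many*
  cells a unit sends each way, not *which*.  Assigning by cell id alone
  turned out to systematically swap overlapping cells (the left cell of a
  pair could be flung past the right one), so movers in the positive
  direction are the cells furthest along that axis within the unit, with
  ties broken by ascending id.  Exact ties (coincident cells) thus still
  split deterministically, the lower id taking the positive direction.
  The rounding in the ratio rule is round-half-away-from-zero.
* **Accumulation across iterations.**  The motion tensor accumulates over
  all iterations of one resolver call and is reset at the start of every
  call; displacements are therefore "per movement step", matching how the
  IbM invokes the resolver.
* **Gradient normalization.**  The update uses the conservation-preserving
  form `E - (1/4) sum E_N`; the unnormalized difference `E - sum E_N`
  would not conserve occupancy.
* **Tuning constants.** `alpha = 0.5` converges quickly without
  oscillation in two-cell experiments (any value in (0, 1] conserves);
  the convergence threshold is `1e-4` on the per-unit occupancy change
  with an iteration cap of 200.  All are exposed in
  `resolution_config()`.
* **Degenerate inputs.**  A cell larger than the domain is rejected; radii
  below 5% of the unit size trigger a warning (the rasterization becomes
  noisy at that scale).  Cells entirely outside a non-periodic domain
  rasterize to nothing, with a warning.
* **Displacement cap.**  The motion accumulated while a deep local
  overlap relaxes (one or two hundred iterations after a division inside
  a crowded region) can overshoot by several cell diameters and throw a
  cell onto a neighbor — an instance of the discretization artifact
  inherent in translating continuous grid-level motion back to cells.
  Each resolver call therefore clamps every cell's displacement to
  `max_move` times its own radius (default 1; `Inf` disables), keeping
  the direction and limiting the magnitude to the physical scale of one
  shoving event.
* **Boundaries.**  Periodic edges wrap rasterized mass, excess flow and
  positions.  At solid edges nothing is reflected: excess flowing off-grid
  is truncated and cell centers are clamped one radius inside the wall at
  apply time.  An optional seeded Gaussian pre-displacement
  (`jitter_sigma`, in grid units, default off) injects stochastic motion
  before forward translation.

The kd-tree comparator is the classical relaxation shover: sweeps in
ascending id order, each overlapping pair displaced symmetrically by half
the overlap depth along the center line (momentum-neutral; the cited
literature leaves open whether only the focal cell moves), the tree rebuilt
every sweep, termination when the deepest overlap falls below `1e-3` um or
after 50 sweeps.  Coincident centers separate along a direction drawn from
the seeded RNG.

## The individual-based model

Cells grow as `m' = m * exp(mu * dt)` with the Monod rate
`mu = mu_max * S / (Ks + S)` evaluated at the substrate concentration of
the field unit containing the cell center (nearest-unit binning).  Biomass
maps to geometry through an areal density, `m = pi * r^2 * density`; a cell
reaching its division threshold splits into two half-biomass daughters
placed tangentially — centers one daughter radius either side of the
mother, along a uniformly random (seeded) axis — so division itself
introduces no overlap between the siblings.  (Placing daughters closer,
e.g. overlapping at one daughter radius between centers, creates an
instantaneous 20-30% pairwise overlap; a single redistribution pass
relieves most but not all of it, regardless of the convergence threshold,
and the remainder would be visible in the overlap-ratio samples of small
colonies.  Tangent placement is the usual choice in shoving-based IbMs
for exactly this reason.)
Substrate consumed is `(m' - m) / yield`, debited from the field as a sink.
The field obeys Fick's law, integrated with the explicit forward-time
central-space (FTCS) scheme on its own, coarser grid; the two-timescale
scheduler runs diffusion at a fast step of 5e-4 min and everything else
(growth, division, one resolver call, metric sampling) every 0.01 min.

Scenario geometry follows the two study designs: *colony* — 600 x 600 um,
periodic on all sides, one founding cell at the center; *biofilm* —
800 x 200 um, solid bottom (zero-flux for substrate), Dirichlet top held at
the bulk concentration, periodic lateral edges, 40 founding cells along the
bottom.  Bulk nutrient levels of 100, 10 and 1 mg/L span the regimes from
compact growth to strong nutrient limitation.

### Parameter defaults and their calibration

The kinetic constants are not dictated by the algorithm; the package
defaults are chosen once, at typical heterotroph scales, and exposed in
`growth_params()`:

| parameter | default | units | note |
|---|---|---|---|
| `mu_max` | 0.02 | 1/min | doubling time ~35 min |
| `Ks` | 2.5 | mg/L | half-saturation |
| `yield` | 0.5 | pg biomass / pg substrate | |
| `division_radius` | 2 | um | daughters have r ~ 1.41 um |
| `division_noise` | 0.1 | fraction | per-cell threshold spread (uniform) |
| `split_sd` | 0.05 | fraction | asymmetry of the biomass split at division |
| `initial_radius` | 1 | um | founding cells |
| `density` | 1e-4 | pg/um^2 | biomass-area link |
| `D` | 4e4 | um^2/min | small-solute diffusivity in water |
| field `dx` | 10 | um | substrate grid spacing |
| field `depth` | 20 | um | nutrient layer thickness |

Two of these require comment.

*Field spacing.*  With `D = 4e4 um^2/min` and the 5e-4 min fast step, the
2-D FTCS stability bound `D * dt / dx^2 <= 1/4` requires `dx >= ~9 um`; the
field therefore defaults to 10 um spacing (`D * dt / dx^2 = 0.2`), and the
bound is enforced when a scenario is built.  Finer substrate grids are
possible by shortening the fast step.

*Biomass scale.*  The colony domain is closed (periodic, no resupply), so
the substrate inventory `S0 * area * depth` caps the population at roughly
`inventory * yield / m_cell`.  The areal density default is calibrated so
that the nutrient-limited regimes still support population-scale colonies
at desk scale: the quarter-scale (150 x 150 um) domain holds ~250 cells at
1 mg/L and ~2.5e3 at 10 mg/L — comparable to the colony sizes those
regimes are reported to produce — while the 100 mg/L runs are
duration-limited well below their capacity, consistent with a population
still growing when a high-nutrient experiment ends.  The calibration
matters for the overlap metric itself: in a colony of only a few dozen
cells a single division event is several percent of total cell area, and
no resolver could keep the sampled ratio below 1%.  Biomass units are
otherwise arbitrary: the resolvers ignore biomass entirely, and only the
ratio of inventory to per-cell demand shapes the dynamics.

*Division stochasticity.*  Cell reproduction carries intrinsic
variability, and representing it matters mechanically: with deterministic
division every descendant of a founder shares the same biomass clock on a
well-mixed field, the entire colony divides in lockstep, and the overlap
ratio spikes at burst steps.  Two noise sources are modeled.  Each cell
draws a persistent division threshold uniformly within +/-10% of
`division_radius` at birth (`division_noise`).  Threshold noise alone,
however, cannot desynchronize lineages: the cumulative time over `k`
generations is `[k ln 2 + 2 ln(thr_k) - 2 ln(thr_0)] / mu` — the
intermediate thresholds telescope out, because a late-dividing mother
makes large daughters that divide correspondingly early.  Lineage timing
only decorrelates through the biomass split asymmetry (`split_sd`): the
first daughter receives a `0.5 + N(0, 0.05)` fraction of the mother's
biomass (truncated to `[0.35, 0.65]`), adding a random-walk term per
generation.  Setting both to 0 restores fully deterministic reproduction,
complete with its synchronized division bursts.

### Problem sizes used in the shipped checks

The automated checks run the colony scenario at quarter scale
(150 x 150 um): the high-nutrient run to 2,000 cells with overlap sampled
every 0.1 simulated minutes, and the 10 and 1 mg/L runs to 500 cells or
substrate exhaustion (exhaustion is detected when the largest local
concentration falls below 0.5% of `Ks`, i.e. growth everywhere below 0.5%
of `mu_max`).  The trajectory-shape check uses an eighth-scale domain so
that the full exponential-then-saturating arc completes quickly.  These
sizes exercise every mechanism (division bursts, substrate gradients,
resolver load) at a scale a laptop reproduces in minutes.  The
trajectory-shape check runs a 5 mg/L colony on a 90 x 90 um domain well
past substrate exhaustion: at that concentration a carrying-capacity
population fills only about two thirds of the occupancy grid, so the
settled end state is feasible and quiet, whereas at 10 mg/L the square
footprints of a capacity population exceed the grid itself and the
resolver grinds against irreducible excess forever — a useful reminder
that the square approximation inflates the packing by 4/pi.

## What the metrics measure

The accuracy metric is the *overlap ratio*: the summed pairwise
circle-circle intersection (lens) area divided by the total cell area
`sum(pi r^2)`.  Candidate pairs come from the kd-tree; an O(N^2) scan is
kept as a verification path and the two agree exactly on every tested
population.  Two conventions are worth noting: triple overlaps are counted
pairwise (an upper bound on the true excess area), and the denominator is
total cell area rather than the union or hull area — the alternatives
differ by a bounded factor near one at the low ratios of interest, and the
cell-area denominator gives the ratio a clean interpretation.
`edge_roughness()` summarizes colony morphology as the coefficient of
variation of boundary-cell radial distances (top decile per angular bin,
36 bins) about the population centroid.

## What the synthetic scenarios do and do not show

The packing generator (`generate_packing()`) produces disjoint packings by
rejection sampling and reaches a requested overlap ratio by contracting the
configuration towards the domain center (bisection on the contraction
factor against the measured ratio).  It emulates the *mechanical* input to
a resolver — a supersaturated packing — not any biological process.
The IbM scenarios emulate growth-driven crowding, division bursts and
nutrient-gradient morphologies.  They do not model rod-shaped or
deformable cells, rotational forces, EPS mechanics, detachment, lysis
kinetics (removal below a starvation threshold is available but off by
default), or three-dimensional growth; conclusions from passing tests are
about the resolver and scheduler mechanics at these scales, not about any
particular organism.

With the default (water-like) diffusivity the quarter-scale domain is
effectively well-mixed — the diffusion time across 150 um is minutes while
a doubling takes ~35 — so nutrient-limited runs at this scale slow down
globally rather than developing strong edge gradients, and colony shape is
insensitive to the nutrient level.  The morphology-contrast check
therefore uses a strongly diffusion-limited configuration (effective
D = 1 um^2/min, the scale of a dense gel matrix) in which local depletion
outpaces resupply and rough, ragged edges emerge at low nutrient at desk
scale; with moderately reduced diffusivity (tens of um^2/min) the
contrast is still absent, which brackets where the regime boundary lies
for these domain sizes.

## Numerical notes

* The compiled redistribution loop confines each iteration to the bounding
  box of positive excess grown by one stencil step (occupancy can only
  change within one neighbor of positive excess), an exact optimization
  that makes resolver cost scale with the size of the congested region
  rather than the grid.
* The reference single-step implementation (`diffuse_step()`) is plain
  vectorized R; the test suite checks the compiled loop against it
  iteration by iteration.
* FTCS with Dirichlet edges re-pins the edge rows after every substep;
  Neumann edges use mirrored ghosts.  Sink-driven negative concentrations
  are floored at zero and the floored mass is logged as a deficit on the
  field object.
* All randomness (division axes, jitter, shover fallback directions,
  fixture generation) flows from the session RNG, so a single `set.seed()`
  — or the scenario `seed` — makes runs byte-reproducible; replicate seeds
  derive as `seed + replicate - 1`.  Wall-clock instrumentation
  (`resolver_seconds`) is the one metrics column excluded from the
  determinism contract.

## Known limitations

* The square approximation means a circle-disjoint packing can still carry
  over-occupied units; the resolver then nudges cells apart even though no
  circles intersect.  Conversely the resolver's idempotence guarantee is
  on occupancy-feasible states, not circle-disjoint ones.
* Deep overlaps (fresh divisions) can overshoot: the accumulated motion of
  a long relaxation can separate daughters beyond contact.  Nothing pulls
  cells back together, so the effect is cosmetic at the population level,
  but per-pair trajectories are not those of a force-based integrator.
* With `division_noise = 0` all descendants of a single founder share a
  biomass clock on a well-mixed field and divide in synchronized bursts
  that briefly spike the overlap ratio; the default threshold
  randomization exists to remove this artifact.
* Rare division geometries (daughters separating along a nearly
  grid-aligned axis) can take several movement steps to resolve instead of
  one; in a population of hundreds of cells the transient contribution to
  the overlap ratio is well below the percent level.
* A population that globally exceeds grid capacity (total occupancy above
  `W x H`) cannot be made feasible; the excess then equilibrates to a
  uniform residual and the resolver reports it.
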