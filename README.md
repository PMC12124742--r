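# dorasim

Individual-based models (IbMs) of microbial growth simulate every cell as
an explicit agent that takes up nutrients, grows, divides — and shoves its
neighbors aside.  That last step, resolving spatial overlaps between
circular cells, is the classical computational bottleneck: pairwise
approaches cost O(N^2) with arrays, or O(N log N) with a kd-tree that must
be rebuilt as cells move.  `dorasim` implements a grid-based overlap
resolver that removes pairwise comparisons altogether, alongside the
kd-tree relaxation shover it is compared against, and a minimal IbM
(Monod growth, substrate diffusion) that reproduces colony and biofilm
growth across nutrient regimes.  It is aimed at researchers building or
benchmarking spatial microbial simulators.

## The algorithm

Cells (radius *r*, center *(x_c, y_c)*) are rasterized onto a lattice of
units about 1 um wide as their bounding squares, accumulating an occupancy
matrix Ω whose entries above one mark overlap.  The surplus
E = max(0, Ω − 1) is then redistributed by a diffusion-like iteration over
the von Neumann neighborhood,

    Ω′ = Ω − α (E − ¼ Σ_N E),    0 < α ≤ 1,

which conserves total occupancy on periodic grids and acts only where
cells crowd.  A four-layer motion tensor *M* records the directional
outflow α/4 · max(0, E_ij − E_kl) per unit and direction (down, right, up,
left).  Finally each unit's movement vector
v = (M_right − M_left, M_up − M_down) is summed over the units a cell
covers (units shared by several cells split their magnitudes by the
M-ratio rule) and cells are displaced accordingly.  The whole pass is
O(N) in the population plus grid-local work.

The accuracy metric is the **overlap ratio**: residual pairwise
circle–circle intersection area over total cell area, Σ lens / Σ πr².

## A worked example

Two unit-radius cells overlapping by half a radius, resolved on a 20 × 20
grid:

```r
library(dorasim)

g  <- grid_spec(20, 20)                       # 1 um units, periodic
cl <- make_cells(x = c(10, 10.5), y = c(10, 10), r = 1)
overlap_ratio(cl, g)
#> [1] 0.3425188

r1 <- cl
for (k in 1:3) {
  r1 <- dora_resolve_overlaps(r1, g)
  cat(k, sqrt(diff(r1$x)^2), overlap_ratio(r1, g), "\n")
}
#> 1 0.5 0.3425188
#> 2 1.642569 0.04411114
#> 3 2.25438 0
r1[, c("x", "y")]
#>          x  y
#> 1  9.24781 10
#> 2 11.50219 10
```

Resolvers in IbMs are called every movement step, and that is how this
one works too: the first call's grid-aligned geometry only shifts the
pair, the second drives the centers from 0.5 um to 1.64 um apart, and the
third clears the remaining overlap — slightly beyond contact (nothing
pulls cells back together), with the overlap ratio falling from 34% to
zero.

A growth simulation at quarter scale, with the grid-based resolver called
every 0.01 min movement step:

```r
sc <- build_scenario("colony", nutrient = 100,
                     overrides = list(domain_scale = 0.25,
                                      stop_population = 300, seed = 1))
st <- run_simulation(sc)
tail(st$metrics[, c("time", "population", "overlap_ratio")], 3)
#>       time population overlap_ratio
#> 3450 345.0        299  1.650774e-05
#> 3451 345.1        299  1.745932e-05
#> 3452 345.2        299  2.685113e-06
```

The population grows exponentially (35-minute doublings at 100 mg/L)
while the sampled overlap ratio stays orders of magnitude below the 1%
level, apart from brief transients around division events.  `run_experiment()` adds replicate handling,
snapshot/metrics CSVs and a JSON manifest; `inst/cli/dora.R` exposes
`run`, `resolve`, `fixture` and `compare` subcommands for shell use.

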