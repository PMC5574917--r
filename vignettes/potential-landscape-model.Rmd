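---
title: "The potential-landscape migration model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The potential-landscape migration model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywaysim)
```

## The model in brief

flywaysim treats a migrating bird as a particle rolling across an
environmental potential surface defined on a global latitude–longitude
lattice. Two environmental layers build the surface. Resource
concentration (chlorophyll-a as a proxy for marine food) attracts at a
distance: each cell's concentration acts like a point charge producing a
−1/r potential, so the resource potential at a cell is the sum
`φ = −Σ C/r` over every other resource-bearing ocean cell, with `r` the
great-circle distance between cell centres. Wind cannot be folded into a
global potential (it is a rotational field), so it instead tilts the
landscape locally around the bird: a candidate move with unit displacement
`d̂x` costs `χ = −|w|(w·d̂x)`, the sign convention making downwind moves
downhill. The tilt is quadratic in wind speed because aerodynamic drag is;
it captures tailwind support only, not dynamic soaring in crosswinds.

The two layers combine as `Ψ = φ + a·χ`, and the bird's next cell is drawn
from Maxwell–Boltzmann probabilities over its 8 lattice neighbours,
`P ∝ exp(−Ψ/kT)`, with land neighbours assigned exactly zero probability
and staying put excluded. Time advances by each step's great-circle length
divided by the ground speed, and the monthly resource and wind fields roll
over as the clock crosses calendar month boundaries.

The model's core assumptions, inherited by everything downstream: birds
have full knowledge of the long-run average resource field (memory or
inherited preference, not local sensing); movement decisions during the
non-breeding season are driven purely by the environment, with no colony
attachment, no competition, no thermal-niche term; and a month is a fine
enough environmental timestep.

## Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `a` | weight of wind tilt relative to resource attraction | dimensionless (see unit convention) | swept 0.001–0.008 |
| `kT` | movement randomness (β = 1/kT) | potential units | swept 0.05–0.2 |
| `airspeed` | typical airspeed | km/h | 60 |
| `speed_floor_frac` | minimum ground speed, as fraction of airspeed | — | 0.1 |

The exploration grid — `a` as multiples of 0.001 up to 0.008 crossed with
`kT` as multiples of 0.05 up to 0.2, 16 birds per pair, 32 pairs — is the
default of `sweep_parameters()`, and `a = 0.005, kT = 0.1` is referred to
throughout as the reference parameterisation.

**Unit convention.** The numerical value of `a` only has meaning relative
to the scales of `φ` and `χ`. This package fixes: distances in km on a
sphere of radius 6371 km, concentrations in mg m⁻³, winds in m s⁻¹. So
`φ` is mg m⁻³ km⁻¹ and `χ` is m² s⁻². The convention is recorded in every
metadata sidecar. With different data magnitudes (notably the synthetic
worlds below), the interesting range of `a` shifts; treat published ranges
as indicative and re-balance per dataset by comparing typical neighbour
differences of `φ` against `a·|χ|`.

## Grid and geometry conventions

Row 1 is the northernmost row and column 1 the westernmost, with cell
centres at `lat0 − (i−1)·cell_deg`, `lon0 + (j−1)·cell_deg` — the common
satellite-product layout; `grid_spec` carries the origin explicitly so any
other layout can be declared. Columns wrap across the antimeridian;
latitude does not wrap, and a neighbour beyond the first or last row is
simply not permitted. The displacement vector of a move is built in the
spherical surface geometry — zonal component ∝ Δlon·cos(latitude),
meridional ∝ Δlat, then normalised — because at high latitude a "diagonal"
lattice move is mostly meridional; diagonals use the mean latitude of the
two cells, and sub-cell accuracy beyond that is ignored. The −1/r sum
skips exactly the self-term, as distinct cell centres never coincide; no
softening epsilon is used.

Wind is sampled at the departure cell only (no interpolation to the
midpoint), both for the potential tilt and for the ground speed.

## Time accounting and ground speed

Months are calendar months at 24 h/day (April = 720 h), anchored at the
simulation start; runs default to April–July, and the final step that
crosses the total duration is executed in full rather than truncated. The
ground speed of a step is `airspeed + 3.6·(w·d̂x)` km/h — the same
tailwind dot product that defines `χ`, converted from m/s — floored at
`speed_floor_frac × airspeed` so a step into an extreme headwind still
terminates in finite time. The combination rule is a modelling choice
(tailwind adds, crosswind contributes nothing) and the floor is a
configuration knob, not a fitted constant.

## Numerical choices

- **Boltzmann stabilisation.** Move probabilities are computed after
  subtracting the minimum `Ψ` among permitted neighbours — a shift the
  distribution is exactly invariant under — so weights never overflow even
  at `|Ψ| ~ 10⁶` and `kT = 0.05`. The independent check
  (`oracle_boltzmann()`) instead uses the pairwise-ratio form
  `P(i) = 1/Σ_k exp((Ψ_i − Ψ_k)/kT)`, algebraically identical and
  overflow-safe in a different way (an infinite denominator yields an
  exact 0), so the two routes share no code path.
- **Potential memoisation.** `φ` depends only on the month's resource
  field, so it is computed on demand and cached per (cell, month). The
  cache is shared across all birds of an ensemble and all (a, kT) pairs of
  a sweep; cache transparency (identical values with and without it) is
  under test. A full-grid precompute would be O(N²) in cells and is never
  needed, since a trajectory visits a small fraction of the grid.
- **Distance evaluation.** The hot loop needs distances from one cell to
  all cells; the haversine separates into one term per row plus one per
  column, which is how `resource_potential()` evaluates it. The validation
  oracle uses the plain pairwise double loop instead.
- **kT = 0 is rejected**, not special-cased; the greedy limit is exercised
  with tiny positive temperatures (1e−9), where the argmin neighbour
  receives all sampled moves.
- **Degenerate inputs.** An all-zero resource field gives `φ = 0`
  everywhere (pure wind/random walk). Missing resource cells (`NA` after
  climatology) contribute nothing to the sum. A bird whose 8 neighbours
  are all land raises a dead-end error — unreachable from a legal start,
  since the predecessor cell is ocean. Ties in `snap_to_ocean()` break to
  the smallest row, then column.
- **Seeding.** Every bird runs on its own seeded stream (`base_seed +
  bird`), ensembles are therefore order-independent, and sweep pair `p`
  seeds at `base_seed + p·10⁶`, so extending a parameter grid never
  perturbs existing runs. All generators and simulators restore the
  caller's RNG state.

## The synthetic environments

`synth_environment()` generates worlds with the structure of the real
monthly inputs — non-negative patchy scalar fields masked to ocean, smooth
winds with dominant zonal flow, one slice per month — at whatever lattice
size is convenient:

- `point_source`: the world's entire attraction concentrated in one cell.
  The default amplitude (2000 mg m⁻³ in one cell) is chosen to be of the
  order of the *total* resource mass a real basin spreads over thousands
  of cells, so potential gradients at 1000–3000 km are comparable to
  `kT = 0.1`: the greedy pull per step, roughly `amplitude·Δr/r²`, then
  exceeds the temperature within a few thousand km of the source.
- `two_patch`: two equal Gaussian patches placed symmetrically east and
  west of a reference cell; mirror-symmetric by construction (patches are
  built in lattice-index metric), which makes east/west symmetry tests
  exact at the environment level.
- `uniform_wind`: uniform resource and uniform wind, isolating the wind
  term.
- `zonal_jet` and `ring_world`: a Gaussian-in-latitude westerly jet
  (peak 10 m s⁻¹) over patchy lognormal chlorophyll (median ~1 mg m⁻³,
  the order of real ocean values, smoothed with a 3×3 box filter);
  `ring_world` restricts ocean to a latitude band, exercising land
  exclusion. These are cartoons of the Southern Ocean.

What these worlds do *not* emulate: coastline geometry, the seasonal
progression of real chlorophyll, spatially structured wind direction
changes, and data gaps. Tests passing on them establish the mechanics —
potential arithmetic, probability normalisation, land legality, drift and
downwind transport, reproducibility — not that the model reproduces any
real population's flyways; that requires the real NASA/NOAA climatologies,
which the IO layer can ingest but this repository does not ship.

## File formats

Gridded IO uses a deliberately minimal plain-text CSV-grid dialect (header
`#grid n_rows n_cols cell_deg lat0 lon0 month`, then one comma-separated
line per row, `NA` for missing), written with 17 significant digits so
round trips are bit-exact; masks use the same dialect with 0/1 values.
Preparing real satellite products therefore means one export step from
whatever toolchain produced them, and the rasterised ocean mask is
consumed pre-made (the rasterisation rule — cell-centre versus any-overlap
— stays with the producer). Climatologies average one calendar month over
several years cell-wise, ignoring missing values; a resource cell missing
in every year stays missing, while a wind cell missing in every year is
filled from the nearest non-missing cell with a warning, because the
simulator requires a complete vector field.

## Test problem sizes

The validation and acceptance suites run on 16×32 to 64×128 lattices with
16-bird ensembles (400 for symmetry statistics, where a binomial 5σ bound
at n = 400 is ±0.125 around ½), one to four simulated months. These sizes
give every statistical check comfortable power while keeping the full
suite and the acceptance script to a few minutes each; the model code
itself is size-agnostic and has been exercised at 0.25° (720×1440)
geometry in the unit tests of the grid layer. One measurement subtlety: at
coarse cells a strongly wind-driven bird can circle the globe within a
month, so "net eastward displacement" is measured by accumulating signed
per-step zonal moves rather than by comparing endpoint longitudes, which
are only defined modulo 360°.

## Known limitations

Beyond the single-species assumptions listed above: no return migration or
breeding-site fidelity (runs are restricted to the non-breeding window for
exactly this reason); no flight energetics, stopovers or day/night
structure; no competition between colonies sharing a destination; no
thermal-niche (sea-surface temperature) term; and the wind contribution to
ground speed is a stated convention, not an aerodynamic derivation. The
parameter `a` is only comparable between runs that share the unit
convention and data scales.
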