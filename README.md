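# flywaysim

A mechanistic, physics-inspired simulator of population-level bird
migration, built for movement ecologists who want to *predict* non-breeding
pathways and destinations from a starting colony rather than infer them
statistically from tracking data. The motivating system is the non-breeding
migration of Southern Ocean seabirds (black-browed albatross colonies are
built in), but the machinery is generic: any highly mobile species moving
over a gridded resource and wind field.

## The model

A bird is a particle on a global latitude–longitude lattice, moving inside
an **environmental potential landscape** built from two monthly data
layers:

- **Resource attraction.** Each cell's chlorophyll-a concentration
  `C_kl` (mg m⁻³, a proxy for food) acts like a unit of charge or mass,
  contributing an attractive −1/r potential. At cell (i, j):

  ```
  φ_ij = − Σ_{(k,l) ≠ (i,j)}  C_kl / r_ij,kl
  ```

  with `r` the great-circle distance between cell centres (km, sphere of
  radius 6371 km). Inland water is excluded by a binary ocean mask.

- **Wind tilt.** Wind is rotational, so it has no global potential;
  instead the wind vector `w` at the current cell tilts the landscape
  locally. Since drag scales with the square of the airspeed, a move with
  unit spherical displacement `d̂x` (zonal component scaled by cos
  latitude) costs

  ```
  χ_ij = − |w| (w · d̂x)
  ```

  — downwind moves are downhill, upwind moves uphill, crosswind moves
  free.

The combined potential over the 8 neighbouring cells is
`Ψ_ij = φ_ij + a·χ_ij`, and the next cell is drawn from Maxwell–Boltzmann
probabilities

```
P(i,j) = exp(−Ψ_ij / kT) / Σ exp(−Ψ_kl / kT)
```

with land cells forced to probability zero and staying put excluded. The
two free parameters are `a` (importance of wind relative to resources) and
`kT` (movement randomness; 1/kT is the inverse temperature β). The clock
advances by each step's great-circle length divided by ground speed
(typical airspeed 60 km/h plus the tailwind component), the monthly
environment rolls over at calendar boundaries, and a run covers the
April–July non-breeding window by default.

## Worked example

Simulate a 16-bird ensemble from South Georgia in a synthetic Southern
Ocean (patchy lognormal chlorophyll under a Gaussian westerly jet):

```r
library(flywaysim)

g    <- grid_spec(32, 64, 5.625)                      # coarse global lattice
envs <- synth_environment("zonal_jet", g, seed = 1)   # April–July slices
sg   <- albatross_colonies()[5, ]                     # South Georgia (−54.2, −36.5)
pars <- model_params(a = 0.005, kT = 0.1)             # reference parameterisation

ens <- simulate_ensemble(sg, pars, envs, n_birds = 16, base_seed = 1)
glance(ens)
#> # A tibble: 1 × 8
#>   colony          a    kT n_birds total_steps mean_displacement_km fraction_east
#>   <chr>       <dbl> <dbl>   <int>       <int>                <dbl>         <dbl>
#> 1 South Geor… 0.005   0.1      16       25752                4356.         0.312
```

The 16 birds took 25 752 steps over the four months and ended on average
4356 km from the colony, 31% of them east of the start meridian —
`directional_split(ens)` gives the same east/west breakdown directly, and
`tidy(ens)` returns the full step table (one row per bird per step, with
cell indices, coordinates, clock hours and month) for dplyr/ggplot2 work.
`autoplot(ens)` draws the occupancy density with endpoint markers;
`sweep_parameters()` runs the default 8 × 4 grid of (a, kT) pairs;
`write_ensemble()` exports trajectories (CSV/GeoJSON), density grids and a
metadata sidecar. A command-line front end with the same capabilities
ships in `inst/cli/flywaysim.R`.

Real satellite fields can be used in place of the generator: save each
month as the package's plain-text CSV-grid dialect and load with
`load_scalar_field()`, `load_wind_field()` and `build_climatology()` (the
latter averages years cell-wise, filling cloud gaps).

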