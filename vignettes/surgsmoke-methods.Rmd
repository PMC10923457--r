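---
title: "Modelling surgical-smoke dispersion in a laminar-flow theatre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling surgical-smoke dispersion in a laminar-flow theatre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(surgsmoke)
```

## The problem

Electro-surgical cutting pyrolyses tissue at the knife tip and releases
surgical smoke: a hot mixture of waste gases (CO, CO2, CH4, NH3), condensed
tar droplets and non-viable particles of about 2 um. In a laminar-flow
operating theatre this smoke rises from the incision against a slow,
uniform, downward air curtain, stalls at some height, and is carried toward
the low wall exhausts — putting the bowed surgeon's breathing zone and the
patient's open wound in the most contaminated region of the room.
`surgsmoke` models that chain quantitatively: how the knife power sets the
tip temperature and the smoke source strength, how the buoyant plume
develops in the ventilated room, where the dispersed phases travel, and
which occupational thresholds are exceeded.

## Source calibration

The smoke source is characterised by four responses of an in vitro power
sweep (porcine muscle cut at 20--80 W in a sealed crucible), summarised as
polynomials in the knife power $P$ (W):

$$T_{tip} = 270 - 4.59\,P + 0.095\,P^2 \quad (^\circ\mathrm{C})$$
$$G_{wastegas} = 9.30\times10^{-6} - 4.49\times10^{-8}P + 7.16\times10^{-9}P^2 \quad (\mathrm{m^3/s})$$

and cubics for the particle and tar formation rates (g/s). These are the
package defaults (`default_calibration()`); `fit_calibration()` refits all
four from any power-sweep table by ordinary least squares (unweighted —
no error structure is available to justify weights).

Two deliberate wrinkles:

* **The canonical temperature lookup.** The four simulated operating points
  are described by their tip temperatures 200/300/400/500 degC and the
  corresponding powers 20/60/70/80 W. The quadratic actually evaluates to
  216/337/414/511 degC at those powers — and can reach no temperature below
  its vertex value of about 214.6 degC at 24.2 W, so "200 degC" has no
  exact preimage at all. `power_for_temperature()` therefore uses the
  published correspondence verbatim for the four canonical temperatures
  (lookup mode, the default) and the exact larger quadratic root otherwise,
  returning the vertex power with an `unreachable` flag for temperatures
  below the vertex.
* **Clamping.** The particle-rate cubic has a negative constant term, so its
  raw value is negative below ~6.5 W. Physical uses clamp it at zero;
  refitting sees the raw polynomial (`clamp = FALSE`), since clamping would
  bias the least squares.

## The synthetic in vitro generator

`generate_sweep()` emulates the power sweep: responses are the truth
polynomials times $(1 + \mathcal N(0, c_v))$, clamped at zero.
Multiplicative noise is the natural model here because the responses span
four orders of magnitude (tar rates of $10^{-3}$ g/s against temperatures
of hundreds of degC); the study reports no replicate counts or measurement
uncertainties, so the default $c_v = 0.02$ is a declared assumption of
instrument-grade relative error. Each response draws from its own seeded
substream, so adding a response to the design never perturbs the noise of
the others. What the generator does *not* emulate: instrument-specific
error models (chromatograph drift, flowmeter quantisation), power-level
miscalibration, or between-animal tissue variability. Passing recovery
tests therefore show that the fitting pipeline is correct and unbiased
under well-behaved relative noise — not that the published coefficients
carry any particular real-world uncertainty.

## Theatre scene and mesh

The theatre is an 8 x 6 x 3 m room with a 2.4 x 2.6 m ceiling inlet,
two 4 x 0.3 m outlets whose lower edges sit 0.1 m above the floor on
opposite walls, a 1.8 x 0.8 x 0.8 m table centred on the floor, and the
incision 0.1 m above the table centre. The source description leaves three
placements open, fixed here as: coordinate origin at a floor corner with
x along the 8 m side and z up; outlets on the two 8 m walls; inlet centred
on the ceiling. All are configurable in the scene constructor.

`build_mesh()` discretises the room on a uniform Cartesian grid. Table
cells are marked solid by the cell-centre-in-box rule under the same
half-open `[lo, hi)` convention used by `locate_cell()` — at the reference
0.2 m spacing this yields exactly a 9 x 4 x 4 solid block. Boundary faces
are labelled inlet/outlet when the patch covers at least half the face, so
labelled areas converge to the geometric ones under refinement; a patch
that receives no faces is an error naming the patch. Because the labelled
inlet area is grid-quantised, the solver rescales the inlet face velocity
to conserve the physical volumetric inflow ($0.096 \times 6.24$ m$^3$/s)
on whatever patch the grid resolved — otherwise coarse grids would
over-ventilate the room by up to ~8%.

The smoke source enters as volumetric sources in the single cell containing
the incision point: a mass source $\rho(T_{src})\,G_{wastegas}$ with
ideal-gas density of the hot source gas, the matching sensible-heat and
species sources, a vertical momentum source $\dot m\, G/A_{inc}$ with an
effective incision opening of $A_{inc} = 1$ cm$^2$ (a few-cm cut a few mm
wide; configurable), and the tar/particle injections. A resolved inlet
patch is impossible: the physical wound is centimetres across, far below
any whole-room grid.

## Flow model

The carrier flow solves the steady incompressible RANS equations with the
standard k-epsilon closure, an energy equation and passive species
transport. The model constants are $C_1 = 1.43$, $C_2 = 1.93$,
$C_\mu = 0.09$, $\sigma_k = 1.0$, $\sigma_\varepsilon = 1.43$ and
$\sigma_T = 1.00$, $\sigma_{t,T} = 0.9$ for the energy diffusivity
$\mu/\sigma_T + \mu_t/\sigma_{t,T}$. These differ slightly from the
canonical Launder--Spalding set (1.44/1.92/1.3), which is selectable via
`turbulence_constants(canonical = TRUE)`.

Boundary conditions: inlet velocity 0.096 m/s downward at 27 degC with
turbulence intensity 3.7% and length scale $0.07 \times 2.4$ m (the inlet
"width" is ambiguous between 2.4 and 2.6 m; 2.4 m chosen, configurable),
giving $k_{inlet} = 1.5 (V_{in} T_i)^2$ and
$\varepsilon_{inlet} = C_\mu^{3/4} k^{3/2}/l$; fixed-pressure outlets;
no-slip walls via the standard wall function (log law above
$y^+ = 11.63$, viscous below); a Robin heat condition on the four side
walls (1.5 W/m^2/K to a 30 degC exterior — the warm walls drive the upward
natural-convection zone); adiabatic ceiling, floor and table.

Buoyancy: with a source ~470 K above ambient the Boussinesq linearisation
is invalid, so density varies only in the gravity term as an ideal gas at
constant pressure, $\rho(T) = \rho_{ref} T_{ref}/T$, and the flow is
otherwise incompressible. Momentum uses the standard signed pressure
gradient and omits the $\tfrac23 \rho k$ isotropic term (absorbed into
pressure), regardless of how the governing equations are typeset elsewhere.

### Numerics

Finite volumes on a collocated uniform grid: first-order upwind convection
with central diffusion (chosen for boundedness — mass fractions remain in
$[0,1]$ and temperature within its boundary/source bounds by construction),
Rhie--Chow face-flux interpolation to suppress pressure checkerboarding,
and SIMPLEC pressure-velocity coupling. Momentum and scalars get implicit
under-relaxation (0.7 momentum, 0.3 pressure, 0.5 scalars) and a few damped
Jacobi sweeps per outer iteration; the pressure-correction equation is
solved exactly by sparse Cholesky. The correction operator is rebuilt every
25 outer iterations; because the flux correction uses the same frozen
conductances as the matrix, the corrected fluxes satisfy discrete
continuity exactly at every iteration regardless of staleness (which is
also why the species balances close to machine precision). Outlet face
fluxes are advanced only by the pressure correction — recomputing them from
the wall-cell velocity each iteration is subtly inconsistent with the
cell-gradient velocity correction and leaves a standing continuity
imbalance. Each equation's residual is normalised by its largest value over
the first five iterations, with an absolute floor that recognises an
equation sitting at rounding noise (an isothermal room's energy equation)
as converged; the default tolerance is $10^{-4}$, relaxed to $10^{-3}$ for
the desk-scale reference runs. Temperatures are carried in kelvin
internally; all interfaces take degC.

Gas properties are dry air at the reference state ($\rho_{ref} = 1.177$
kg/m^3, $\mu = 1.85\times10^{-5}$ Pa s, $c_p = 1006$ J/kg/K); species are
passive and affect density only through temperature. The measured property
table of the original study was not published, so these and the
dispersed-phase densities are documented configuration defaults, not
measured values.

## Dispersed phases

Tar droplets and non-viable particles (2 um, densities 1000 and 1200
kg/m^3 as placeholders) are modelled two ways, mirroring the dual
description the study invokes:

* **Eulerian (quantitative).** At 2 um the Stokes number is far below one
  — the relaxation time is $\tau = \rho_p d_p^2/18\mu \approx 1.2\times
  10^{-5}$ s against flow time scales of seconds — so the dispersed mixture
  follows the gas and its transport reduces to a passive concentration
  field (g/m^3) with the calibrated injection rate as source. All
  concentration claims (profiles, wound-zone levels) come from this field.
* **Lagrangian (qualitative).** `track_parcels()` integrates the drag-law
  trajectory equation with the Schiller--Naumann correction,
  $\dot u_p = \frac{18\mu}{\rho_p d_p^2}(1 + 0.15 Re_p^{0.687})(u - u_p)$,
  using the exact exponential update of the linearised step, which is
  unconditionally stable and lands exactly on the gas velocity for steps
  much longer than $\tau$. The trajectory equation contains no gravity
  term — settling at 2 um is ~0.1 mm/s, negligible against the room flow —
  and the default tracker follows that; `gravity = TRUE` adds it (and
  reproduces the Stokes terminal velocity, which is how the integrator is
  audited). The time step is half the local cell-crossing time: with an
  exact drag update there is no stability reason to resolve $\tau$, which
  would cost $10^7$ steps per parcel.

## Exposure analysis

* **Ascent height.** `compute_H_smoke()` finds the lowest
  positive-to-negative zero crossing of vertical velocity on the cell-centre
  line above the incision, linearly interpolated — the "smoke top" where the
  plume meets the descending curtain. The first crossing (not the highest)
  is deliberate: a single plume has one top, and higher sign structure is
  wall-convection circulation. When the velocity is never positive above
  the incision the rise is below grid resolution; the smoke top is then the
  incision height itself (0.9 m), reported with a `no_upwelling` flag.
* **Zones.** `classify_zones()` reproduces the qualitative seven-zone
  decomposition by sign/magnitude rules (upwelling column, laminar curtain,
  horizontal outflow, peripheral downflow, flow toward blank walls, wall
  natural convection, other). One zone of the original enumeration is never
  defined; `"other"` absorbs the gap. Labels are assigned by precedence and
  are exclusive and exhaustive over fluid cells.
* **Profiles and ppm.** Nose-height profiles are trilinear line samples at
  Z = 1.1 m (lying patient, table centre line) and Z = 1.5 m (standing
  surgeon, table border). CO ppm is $Y_{CO} (M_{mix}/M_{CO}) \times 10^6$
  with $M_{mix}$ fixed at dry air (dilute-smoke approximation).
* **Thresholds.** The report flags strict exceedances of 9/50/200 ppm CO
  (zone means over the surgeon box: within 0.5 m horizontally of the
  incision, 1.1--1.45 m high) and 20 g/m^3 tar / 12 g/m^3 particles (wound
  zone: incision cell plus face neighbours). The published quadratic for
  ascent height vs tip temperature is evaluated as
  $H = 1.14 - 6.37\times10^{-4} T + 2.45\times10^{-6} T^2$: the printed
  coefficients lost their exponents in typesetting (as printed they give
  $\sim 10^5$ m), and this restoration reproduces both printed endpoint
  heights (1.11 m at 200 degC, 1.43 m at 500 degC) to ~1%.

## What the desk-scale runs can and cannot show

The reference configuration is a uniform 40 x 30 x 15 grid (0.2 m cells,
18 000 cells), solved to $10^{-3}$ in a few minutes on one core; tests and
the acceptance script use it, with the smaller 16 x 12 x 10 room for
property checks. Two consequences of that scale are worth stating plainly:

* **The plume is resolution-limited.** First-order upwind convection adds a
  numerical diffusivity of order $u\,\Delta x/2 \approx 10^{-2}$ m^2/s in
  the plume region — an order of magnitude above the turbulent eddy
  diffusivity there — so the rising column is one cell wide and its excess
  temperature is diluted over 0.2 m cells. The 500 degC case still rises
  robustly (measured smoke top ~1.1 m against the published 1.45 m, and
  rising toward it under grid refinement); the
  200 degC case's source power (~1.5 W of sensible heat) produces a rise
  that a simple plume-in-counterflow scale $B/U^3$ puts at a few
  centimetres, below any whole-room cell size, so the measured smoke top
  sits at the incision height. A body-fitted, locally refined mesh of the
  kind commercial solvers use near the incision would be required to
  resolve it; uniform-grid refinement within desk budgets does not reach
  that regime.
* **The wound-zone thresholds are ratio-constrained.** Tar and particle
  concentrations are passive-linear in their injection rates, whose ratio
  at 80 W is 0.45 (0.0797 vs 0.1767 g/s); any linear-transport model
  therefore predicts wound tar at 0.45 times wound particles, and the two
  published exceedance levels (20 and 12 g/m^3, ratio 1.67) cannot both be
  tight simultaneously. At the reference grid the wound-zone mean at 500
  degC exceeds the particle level while the tar level is exceeded only in
  the source cell itself, not the 7-cell wound-zone mean.

Other known limitations: no radiation, humidity, transient/LES turbulence,
two-way coupling, droplet evaporation or coalescence; no patient/surgeon
bodies or lamps in the scene; absolute CO ppm values scale directly with
the assumed source composition (the measured composition was published only
graphically — the defaults satisfy the stated CO+CO2 dominance and are
flagged as assumptions).

## Reference runs

```{r, eval = FALSE}
# one case end to end
res <- simulate_case(default_config(tip_temp = 500))
res$report

# the four canonical cases and the ascent-height fit
sw <- run_sweep(default_config(), temperatures = c(200, 300, 400, 500))
sw$H_table
autoplot(sw$H_fit)
```
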