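---
title: "Data-driven rigid-body pair potentials and Langevin self-assembly: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven rigid-body pair potentials and Langevin self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The abstraction

`mdem` works at the molecular discrete element level: each
macromolecule is a single anisotropic rigid body with a position and an
orientation. Everything the solvent and the internal degrees of freedom
do is folded into two data-driven models:

* an **intermolecular interaction model** — a six-dimensional potential
  `U(x, y, z, alpha, beta, gamma)` over the relative configuration of
  molecule B in molecule A's body frame, learned from a sampling oracle
  by Universal Kriging and tabulated on a grid from which forces and
  torques are obtained by central differences; and
* an **anisotropic diffusion model** — per-body-axis translational and
  rotational diffusion coefficients that set friction and thermal noise
  in a Langevin integrator through the Einstein relation
  `zeta_i = kB T / D_i`.

The production parameterization this mimics runs hundreds of thousands
of pair MD simulations. Here the oracle is synthetic and analytic, so
every stage of the method is testable on a desk.

## Body frames and descriptors

A molecule's body frame is its mass-weighted principal-axes frame:
after `canonicalize_frame()` the center of mass is at the origin and the
coordinate covariance is diagonal with descending eigenvalues. Two sign
conventions make the frame reproducible: on the first two axes the
coordinate of largest magnitude is positive, and the third axis is the
cross product of the first two. The per-axis gyration radius is defined
*about* the axis (RMS of the two perpendicular coordinates), so the
smallest radius belongs to the longest principal axis, which matches the
reference dimer's ordering 1.31 < 1.85 < 1.97 nm with x the first
principal axis.

Two scalar descriptors organize the 6D space:

* `delta_m` — the minimum distance between backbone beads of the two
  placed molecules. It is the 1D coordinate of the systematic trend,
  because molecular interaction decays with separation, not with any
  particular Euler angle.
* `delta_r` — the RMSD of molecule B's backbone beads between two
  placements. It is the metric for kriging neighborhoods, variograms,
  resampling spacing and binding proximity. Internally a placement is
  flattened into a `3k`-vector, so `delta_r` is a Euclidean distance
  divided by `sqrt(k)`; this makes it a true metric (triangle
  inequality) and makes neighbor searches a plain nearest-neighbor
  problem. Note `delta_r` is *not* invariant under exchanging the two
  molecules; wherever exchange symmetry matters (the toy oracle, contact
  classification) both orderings are used explicitly.

Euler angles are stored only at the interface; all internal rotation
algebra is quaternionic. The convention is a parameter (scipy-style
strings, upper case intrinsic, lower case extrinsic) because the
reference binding table does not state one — see "the capsid fixture"
below for how it is resolved empirically.

# The estimation model

Each potential component `p` (direct A-B interaction, solvent term, …)
is treated separately and the total is the superposition of the
per-component estimates. A component is decomposed as
`U = mu(delta_m) + R`, with:

* **Trend** `mu(delta_m) = b0 + b1 g(delta_m; theta)`, `g` one of a
  small family of physically decaying basic functions — Gaussian
  `exp(-d^2 / 2 r^2)`, exponential `exp(-d / r)`, and shifted powers
  `1/(d + c)^k`, `k` in {1, 6, 12} — fitted by weighted least squares
  with the scale parameter profiled by 1D optimization. Weights are
  inverse Gaussian-kernel densities in `delta_r` (kernel width 2 nm), so
  heavily resampled regions do not dominate. The family with the best
  weighted R² wins; the constant basis is always included. The exact
  basis set used in production is not public, so this set is a
  documented superset of plausible decay shapes.
* **Sectional variograms.** The residual is not globally stationary (it
  collapses to zero at large `delta_m`), so the interaction range is
  split into five equal-width `delta_m` regions and a variogram
  `gamma(h) = nugget + psill * f(h / range)` is fitted in each region
  from the binned empirical semivariances of the residuals, using data
  from the region and its adjacent regions. Candidate families are the
  standard geostatistics set (nugget, spherical, exponential,
  Gaussian); the bin uncertainty is `sd / sqrt(n)` with a floor of 5% of
  the maximum semivariance so sparse or accidentally tight bins cannot
  dominate the fit.

## The kriging system and two stabilizations that matter

At a query, the `N` nearest points by `delta_r` form the neighborhood;
the `(N + M + 1)` Universal Kriging system (variogram block,
unbiasedness row, one basis row per non-constant basic function) is
solved by SVD with singular values below `max/1e6` discarded, which is
what keeps zero-slope Gaussian variograms solvable in double precision.
Variogram entries are normalized by the sill and basis entries by their
neighborhood maximum so all blocks are order one; the Lagrange
multipliers are de-normalized afterwards so the estimation variance
`sigma_K^2 = sum w_i gamma_i + sum lambda_j f_j` can be evaluated with
the raw functions (this bookkeeping is pinned by a closed-form
ordinary-kriging oracle in the tests).

Two choices were forced by failure modes observed on the 2D benchmark,
and both are deliberate parts of the model rather than tuning:

1. **No basis extrapolation.** The basis value at the query is clamped
   to the range of basis values over the neighborhood. A trend fitted on
   `delta_m` in [0.45, 2] nm and evaluated at `delta_m -> 0` can be tens
   of times larger than any data value; the universality constraint then
   forces explosive weights. With the clamp, queries below the sampled
   support fall back to local-mean behavior instead of exploding.
2. **Sectional neighborhoods.** The neighborhood is restricted to data
   whose `delta_m` lies in the query's region or its adjacent regions —
   exactly the domain on which the region's variogram was fitted.
   Without this, a query in the noise-free outer region can draw its
   neighbors from the noisy short-range region; under the outer region's
   near-zero-sill model those neighbors all look "perfectly correlated"
   and the estimate collapses to their mean.

Components whose residual shows no usable spatial correlation
(structured-sill fraction below 5% in every region) fall back to
trend-only estimates, mirroring the production observation that only the
direct A-B component is worth kriging.

# Synthetic worlds

## The 2D benchmark

`truth_field_2d()` reproduces the published validation world: a
sequential Gaussian simulation (random path, simple-kriging conditional
with a capped neighborhood of 24, Gaussian covariance) with range 0.7,
nugget 3000 and sill 10,000 on a 100×100 grid over [-2, 2]², multiplied
by a taper that is 1 up to `delta_m = 0.4`, falls linearly to 0 at 1.2
and stays 0 beyond ("scaled to zero between 0.4 and 1.2" is read as a
linear ramp; the profile is pluggable), plus a Gaussian trend of
amplitude −400 at zero minimum distance and range 1.0, interpreted as
`exp(-d^2 / (2 * 1.0^2))` — the same profile the trend-fit module uses,
so recovery is a consistent round trip. The oracle evaluates the stored
field bilinearly and adds no extra noise. The domain [-2, 2]² is a
choice (the published figures do not state axes limits); it contains the
full interaction range.

What a green benchmark test does and does not establish: the SGS nugget
is spatially uncorrelated at the grid scale, so roughly
`taper^2 * 3000` of squared error per node is irreducible no matter how
densely the field is sampled. Learning shows up as the *decrease* of
truth-RMS with refinement and in the recovery of the generator's sill,
range and trend amplitude — not as convergence of RMS to zero.

## The toy patchy oracle

`toy_patchy_oracle()` is the desk-scale stand-in for pair-MD sampling
in full 6D. Its A-B component is a sum of Gaussian binding wells in
`delta_r` around two opposite patches (at ±3 nm on the x axis, mutually
inverse so the component is exchange-symmetric; the surface is evaluated
as the average over a configuration and its pose inverse to make that
exact), a soft quadratic overlap repulsion vanishing beyond
`delta_m = 0.5` nm, a smooth correlated "roughness" surface (40
Gaussian bumps, sd 8 kJ/mol, `delta_r` width 0.8 nm) and Gaussian
evaluation noise of 1 kJ/mol; a small positive exponentially decaying
solvent component rides along. The roughness term exists because real
interaction data have spatial correlation; without it the component
would be nugget-only and kriging would — correctly — refuse to
interpolate anything, including inserted binding wells. Configurations
with any bead pair closer than 0.4 nm are rejected, as the collision
rule demands.

## The capsid fixture

The four reference binding configurations are printed rounded to two
decimals and are averaged over quasi-equivalent contact classes, and
that matters: under *no* Euler convention do the four rigid transforms
generate a finite orbit by direct breadth-first closure (the set is not
even approximately closed under inversion, and the implied rotation
axes miss the exact icosahedral arrangement by 13–24°). What does
survive rounding are the individual symmetry cycles: under the
extrinsic x-y-z convention, transform #2 is a 5-fold step
(`T2^5 ≈ identity` within 0.20 nm `delta_r`) and transform #3 a strict
3-fold step (0.17 nm), while #1 and #4 close only loosely (quasi-local
6-fold and 3-fold contacts, 1.1–1.3 nm). The generator therefore:

1. selects the convention by total cycle-closure error,
2. projects the two strict transforms onto *exact* icosahedral 72°/120°
   rotations about a jointly fitted capsid center (deterministic
   multi-start simplex over center, axis direction and azimuth,
   minimizing the worst `delta_r` displacement of the two contacts;
   residual ≈ 0.77 nm), and
3. runs breadth-first closure with the projected generators, which
   terminates exactly in a 60-pose shell deduplicated at
   `delta_r < 0.5` nm.

Every pose in that shell has exactly four partners within 1 nm
`delta_r` of a reference binding configuration, so the average
structured-contact count is exactly 4 — the quantity the contact
classifier is validated against. A 120-pose shell would require the
quasi-equivalent AB/CD doubling, which is explicitly out of scope; the
second class cannot be placed consistently from this table alone.

# Dynamics

The integrator advances each molecule per body axis with the exact
constant-force Ornstein–Uhlenbeck propagator: velocity
`v' = a v + (1 - a) F / zeta + xi_v` and displacement
`dx = tau (1 - a) v + (dt - tau (1 - a)) F / zeta + xi_x` with
`a = exp(-dt / tau)`, `tau = m / zeta`, and the exact joint Gaussian
law for `(xi_x, xi_v)` at the current temperature. This is a stochastic
Verlet/leap-frog family scheme whose free-particle configurational
statistics are exact at *any* ratio of `tau` to `dt` — the property the
module's contract (diffusion recovery, fluctuation–dissipation,
Boltzmann statistics) actually pins down. Orientation updates compose a
body-frame rotation-vector quaternion onto the pose; gyroscopic
coupling between angular momenta is neglected, which is exact in the
overdamped regime the stated world lives in.

On that stated world: the synthetic stand-in structures carry a total
mass of 30 amu. At this abstraction level inertia is not a physical
claim — momentum relaxation of a real dimer (~1 ps) is invisible on
every timescale the method addresses — and making `tau ≈ 1 fs ≪ dt`
puts the integrator in the regime where per-step displacement
increments divided by `2 dt` estimate the diffusion coefficient
directly, which is how the diffusion-recovery targets are specified.
The residual bias of that estimator is `tau/dt ≈ 1%`, inside the 5%
band.

Protocols: SP1 is a zero-temperature quench (noise exactly zero,
friction retained — the system relaxes to the local field minimum
without diffusive interference); SP2 a thermal run from a given state;
SP3 self-assembly from random placement with the molecule count
`round(c NA V / 2)` — the protein concentration counts monomers, the
particles are dimers, and a flag flips that interpretation. Neighbor
bookkeeping is a Verlet pair list with a skin, rebuilt when the maximum
displacement since the last build exceeds half the skin; a per-step
displacement guard aborts with advice when `dt` is too large for the
field resolution. Temperature and effective viscosity can be changed
without re-learning the field; viscosity scaling multiplies all
diffusion coefficients by its inverse (Stokes–Einstein), and the
production trick of emulating hydrodynamic shielding by a 10% effective
viscosity is exposed the same way. The hydrodynamic justification is
the Rotne–Prager–Yamakawa worked example (`rpy_drag_ratios()`): a
sphere surrounded by four neighbors at 2.2 radii in a plus pattern
feels 5.8% of its isolated drag in-plane and 12.9% out-of-plane.

# Field grids, collisions and empirical binding

Potential and estimation-variance grids are homogeneous 6D grids
(periodic angle axes covering (-pi, pi]; singleton axes freeze a
dimension, which is how the 2D benchmark reuses all 6D machinery).
Nodes beyond the interaction range are zero and masked gradient-free.
Lookup is multilinear over the 64-corner cell; forces are central
differences over x, y, z and torques central differences with respect
to quaternion-composed rotations of B about A's body axes of magnitude
equal to the angular step — *not* raw Euler-rate derivatives, which
degenerate at the gimbal singularity. The reaction force is the exact
negative; the reaction torque balances the total torque about the pair
midpoint. A function-backed field (`fun_field()`) exposes the same
interface for analytic potentials, used for verification and for wells
narrower than a grid cell.

Colliding configurations are unsampled by construction, so the grid is
augmented with `dU = k_coll * n_coll * ramp(delta_r_nearest / d_flex)`:
proportional to the number of overlapping bead pairs, ramped down to
zero at configurations directly backed by data (flexibility fully
trusted where the oracle has spoken). The functional form is a
documented reconstruction — the production appendix is not public — and
all parameters are exposed.

Empirical binding insertion writes two virtual point sets per binding
configuration: a constant-`U_center` set at the center and ±0.1 nm
axis-aligned offsets (rotational equivalents via
`dangle = dx / R_char`, `R_char` the largest gyration radius), and a
Gaussian-well set `U_outer + (U_center - U_outer) exp(-dr^2 / 2 (r_bind/2)^2)`
at ±0.2 and ±0.4 nm offsets per axis. Offsets beyond `r_bind` or adding
more than 10 backbone collisions are dropped; a colliding binding
configuration is first moved to the nearest overlap-free configuration
by a ±5-step search of 0.2 nm / 10° per axis. Inserted values are
targets for the *total* potential: the kriged component receives the
target minus the other components' trends, so zero-nugget exactness
reproduces the target; and models are always refitted on oracle points
only, so insertion cannot distort trends or variograms. The offsets are
axis-aligned (24 + center per site), not the full 5^6 tensor grid,
which would dominate every neighborhood and contradict the requirement
that virtual points only influence the nearby potential.

# Analysis definitions

Structured contacts lie within `delta_r <= 1` nm of a binding
configuration (both orderings checked); unstructured contacts touch
(`delta_m <= 0.3` nm) away from binding geometry. Structures are
connected components over both contact kinds; sizes map to classes
(1–5 individually, then decades `c` covering `c-4 … c+5`, everything
from 206 up in class 206). Transitions are counted per molecule per
saving step, normalized by the molecule count; both the symmetric sum
("net, sum of both directions") and the signed difference are exported
because the prose is ambiguous. Structure identity across frames uses
symmetric member overlap above 50% — a splinter does not inherit its
parent's identity, the majority part does, and under a merge the larger
parent continues — with lifetimes censored at the end of the run.
Assembly kinetics fit `N(t) = s + (N0 - s) exp(-t / r)` with `N0`
pinned to the first observation; that is the unique two-parameter
asymptotic-exponential family matching "asymptotic value" and "time
constant" semantics, the exact production formula being unpublished.
The capsid stability objective is a declared *surrogate* (fraction of
reference structured contacts retained, bounded [0, 1]); the production
objective's formula is not public and its published value is not a
target.

# Known limitations

* The kriging engine is dense and in-R; neighborhoods of a few hundred
  points are the practical ceiling (production used N = 500 on HPC).
* Single-level grids only by default; the optional two-level multi-grid
  trades memory for short-range resolution but sub-cell wells still
  rely on empirical insertion or function-backed fields.
* The capsid fixture is a single-class (60-pose) shell; quasi-equivalent
  doubling to 120 is out of scope and not possible from the printed
  table alone.
* `delta_r`-based machinery assumes one species; hetero pairs run
  through the same code but symmetrization and the toy oracle are
  written for identical species.
* The diffusion model is parameterized for dilute systems; crowding
  enters only through the interaction field and the global effective
  viscosity.
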