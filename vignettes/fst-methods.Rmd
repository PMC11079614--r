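---
title: "Filter-space energy flux and tensor geometry: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-space energy flux and tensor geometry: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstflux)
```

## The model

The filter-space technique measures the cross-scale kinetic-energy flux of
a time-resolved 2-D velocity field *a posteriori*. Low-pass filtering `u`
at a cutoff length `L` splits the flow into resolved (`u^L`) and
sub-filter content; the evolution equation for the resolved kinetic energy
contains the transfer term

$$Q(L) = -\tau_{ij}(L)\, S_{ij}(L), \qquad
\tau_{ij} = (u_i u_j)^L - u_i^L u_j^L,$$

with $S$ the rate of strain of the filtered field. Negative $Q$ moves
energy to scales larger than $L$ (inverse flux), positive $Q$ to smaller
scales. In two dimensions, writing both deviatoric tensors in their
eigenframes collapses the contraction to

$$Q(L) = -2\,\lambda_\tau \lambda_S \cos 2\theta,$$

where $\theta \in [0, \pi/2]$ is the folded angle between the extensional
eigenvectors. This identity is exact for symmetric deviatoric $2\times 2$
tensors and is verified in the test suite against direct contraction on
random tensor pairs; the implementation evaluates $\cos 2\theta$ via
`cospi()` so the $\theta = \pi/4$ zero crossing is exact in floating
point.

A uniform shear $v(x)$ has its extensional eigenvector at $\pi/4$ to the
$x$ axis everywhere, and a swimmer's thrust wake carries a stress whose
extensional axis follows the swimming direction. The folded angle
$\theta_s$ between swimming direction and shear eigenvector therefore sets
the sign and efficiency of the biogenic energy flux, which is the claim
the synthetic scenarios and the solver experiment probe.

### Stress decompositions

The turbulent stress splits into Leonard, cross and subgrid Reynolds
parts; `fstflux` computes both the classical split and the
generalised-central-moment (Germano) form, in which every component is
Galilean invariant. Both satisfy $\tau = L + C + \tau_S$ to machine
precision by linearity of the filter. Reported fluxes default to
$Q_s = -\tau_{S,ij} S_{ij}$: the subgrid Reynolds stress carries the
dominant share of the net transfer, and unlike the Leonard and cross
terms it is insensitive to the edge-padding contamination a finite
interrogation window produces. $Q$ from the full stress is available for
comparison (`stress = "full"`).

## Filtering: kernels, padding, margins

* **Kernel-to-L mapping.** The sharp-spectral kernel cuts at
  $k_c = \pi/L$; the gaussian kernel uses $\sigma^2 = L^2/12$, matching
  the second moment of a top-hat of width $L$; the top-hat is an exact
  discrete box average of width $L$ with fractional end-cell weights (so
  it is compact, symmetric, and preserves linear fields in the interior
  exactly). The default is gaussian: an everywhere-positive kernel makes
  $\tau_S$ positive-semidefinite nodewise, a property the tests assert.
* **Padding.** Mirror reflection by default for measurement-like
  (non-periodic) fields; periodic for solver output; zero padding
  available. Any padding contaminates filtered values near the boundary,
  so all spatial averages exclude an interior margin, `L/2` per side by
  default. Tests of closed-form interior values (e.g. $\tau_{yy} =
  \gamma^2\sigma^2$ for a linear shear) use a $2L$ margin, because the
  gaussian tail reaches ~$5\sigma \approx 1.5L$ before dropping below
  `1e-8` relative amplitude.
* **Masks.** Invalid nodes (e.g. a premasked swimmer body) are handled by
  normalised convolution — filter the masked field and the mask, divide —
  and output nodes with mask coverage below 0.5 are themselves masked.

## Synthetic data: what it emulates and what it does not

The generator reproduces the statistical and geometric structure the
analysis assumes, at the laboratory's stated conditions: a streamwise
uniform shear rising linearly from −1.2 to +1.2 cm/s over 7 cm
(γ ≈ 0.343 s⁻¹); localised jets with momentum-conserving gaussian-plume
(or sech², for shape sensitivity) envelopes; intermittent on/off schedules
(exponential jitter, mean 14 s, matching swimmer-like intermittency; a
bounded uniform jitter, 0.6–1.4× the mean, is available for pump-like
regularity); and PTV sampling at 9,000 particles per frame and 60 fps
with cubic re-gridding at Δx = 0.07 cm. The default swimmer wake is
0.5 cm wide with a 3 cm/s core and 1.5 cm development length — body-scale
for a centimetre swimmer. The needle-jet default (`jet_spec()`) uses the
0.96 mm nozzle at 6 mL/min through a 0.5 cm layer.

What the synthetic fields deliberately lack: near-body boundary layers
(real data premask the body), jet entrainment and return flow in a thin
fluid layer, free-surface effects, and genuine turbulence — the kinematic
fields are smooth superpositions. Consequently, passing tests show that
the *analysis chain* is correct and that the tensor-geometry mechanism
behaves as predicted on fields with the assumed structure; they do not
validate the hydrodynamic realism of any particular swimmer.

The superposition of shear and jet is exactly linear, so filtering before
or after summation is identical — a property test. The jet is not
divergence-free by construction; `divergence_clean()` applies a spectral
Helmholtz projection (annihilating the unpaired Nyquist modes of an
even-length grid, which cannot carry a real solenoidal representation)
when exactness matters.

### PTV emulation and reconstruction

Tracers are seeded uniformly, advected with classical RK4 at a quarter of
the frame interval, sampled at the frame rate with isotropic gaussian
position noise (default 0.2 Δx; zero in the round-trip accuracy tests),
and differenced centrally to velocities — the same operations a tracking
pipeline performs. Particles leaving the domain are truncated and
reseeded under fresh ids.

Reconstruction to the Eulerian grid uses moving weighted least squares:
a bivariate cubic fit under gaussian distance weights within an adaptive
radius (initial 2.5 Δx, doubled up to 8× where support is thin), the node
value being the local fit's value at the node. No pre-installed scattered
2-D cubic interpolator exists in this R stack, and MWLS is standard PTV
practice; it reproduces polynomial fields exactly at any sampling and
recovers the smooth shear + wake field to well under 1% RMSE of the rms
speed at the laboratory density of 9,000 particles per frame, degrading
monotonically at 3,000 and 300 — both checked. Frames with fewer than 50
samples are masked entirely.

## The quasi-2D solver and the geometry experiment

The solver integrates the 2-D vorticity equation, doubly periodic,
pseudo-spectral with 2/3-rule dealiasing, with viscosity and Rayleigh
(linear) friction handled by an exact integrating factor and the
nonlinear term plus forcing by classical RK4. Friction is the energy sink
of quasi-2D laboratory layers: its dissipation rate is proportional to
the kinetic energy. The linear physics is testable in closed form (exact
single-mode decay; inviscid energy drift below 1e-6 over 500 RK4 steps;
steady single-mode amplitude $F_0/(\nu k^2 + \alpha)$ within 1%), and
velocities derive from the streamfunction, hence are divergence-free to
spectral precision.

`run_geometry_experiment()` is the in-silico analogue of the angled-jet
laboratory runs. Design choices, made once and reported here:

* **Kolmogorov-type band.** A steady zero-mean body force
  $F_0 \sin(k_f x)\,\hat y$ with one cross-stream mode replaces the
  wall-bounded electromagnetic forcing; analysis is restricted to the
  band centre (±1.5 cm of a 12 cm domain), where the profile is nearly
  linear and the strain eigenvector sits at π/4 — mirroring the
  laboratory interrogation window.
* **Defaults** (`solver_config()`): 64² modes, 12 cm box,
  ν = 0.05 cm²/s, α = 0.3 s⁻¹, dt = 0.015 s; band force
  F₀ = 0.7 cm/s² giving a laminar no-jet band of ≈2.2 cm/s peak — the
  no-jet flow must stay laminar, and these values are reported, not
  fitted to any laboratory number. The jet force is a compact gaussian
  blob (width 0.8 cm, amplitude 4 cm/s²) at the band centre, angled
  $\theta_s$ from the extensional eigenvector, ramped over 0.1 s.
* **Alternating polarity.** The jet flips direction each on-cycle. The
  injected stress $\propto e\otimes e$ is an axial quantity and is
  unchanged, while the DC momentum the jet would otherwise deposit in
  the band cancels over the schedule, so `P~` isolates the
  tensor-geometry mechanism.
* **Burst scheduling and frame selection.** The band strain tumbles
  injected vorticity out of alignment on a timescale ~1/S ≈ 0.5 s, so
  the geometric signal lives in the early development of each burst.
  The schedule uses a 2 s mean interval with bounded uniform jitter
  (exponential jitter's unit coefficient of variation makes the
  measured `P~` variance swamp the effect), and `P` is averaged over
  frames recorded during on-periods plus 0.5 s of decay — the analogue
  of analysing video sections from jet start to full development. The
  no-jet reference is a paired run from identical initial conditions.
* **Problem size.** 60 s of sampled experiment (plus 6 s spin-up) at 64²
  per run; three seeds with a shared reference keep the three-angle
  experiment within a few CPU-minutes. The jet width spans ~4 grid cells
  and the dealiased dynamics remain smooth. The 64² defaults *are* the
  stated study conditions: at finer resolution the sharper-resolved jet
  vortices shift the quantitative deviations (the ordering persisted in a
  128² spot check) and the effect margins differ.

Under these conditions the experiment reproduces the mechanism's
signature ordering — `P~(0) > 1 > P~(pi/2)` with `P~(pi/4)` closest to
unity — for every seed tried during development; the acceptance checks
assert it for three seeds. The effect sizes (a few percent) are
deliberately scaled-down: the laboratory values arise from a different
(electromagnetically forced, wall-bounded) flow and are not targets here.

## Flux-sign scenarios and the noise floor

The kinematic scenarios (`run_scenario()`) superpose the laboratory shear
with a body-scale wake at $\theta_s \in \{0, \pi/4, \pi/2\}$, plus the
jet-without-shear and pure-shear controls. Because these fields are
deterministic, replicate seeds enter through node-level gaussian velocity
noise (default in the acceptance checks: 0.05 cm/s, ≈5% of the rms speed,
emulating residual PTV measurement error). The noise floor is defined as
three standard errors of the frame-mean flux of the noisy pure-shear run
plus its absolute mean.

The analysis band is L ∈ {3, 3.5, 4, 4.5} cm: above the wake's agitation
scale (below ~3 cm every swimmer case shows the inherent 2-D inverse
flux, because the wake deforms the local strain field and the imposed
eigenframe no longer holds) and below the 7 cm shear width. In that band
the aligned case is robustly negative, the anti-aligned case positive,
and the neutral case sits at the jet-alone level: slightly stronger, as
expected when a finite wake disturbs the local shear, but within the
floor of that level and an order of magnitude closer to it than the
aligned/anti-aligned spread.

## Numerical choices and degenerate inputs

* Derivatives: 2nd-order centred differences (one-sided at edges), exact
  for linear fields, so one code path serves non-periodic measurement
  fields and solver output; spectral derivatives behind
  `method = "spectral"` for periodic fields.
* Eigenframes: angle $= \tfrac12\,\mathrm{atan2}(2b, a_{xx}-a_{yy})$ on
  $[0,\pi)$; nodes whose deviatoric magnitude is below $10^{-12}$ of the
  frame-rms tensor norm are flagged degenerate and excluded from
  alignment statistics rather than given an arbitrary angle.
* Angle folding: orientations are axial; differences are folded to
  $[0, \pi/2]$.
* `theta_s` classification uses a neutral band of ±5° around π/4 by
  default (configurable); no numeric band is dictated by the physics.
* The effective-viscosity diagnostic $\nu_e = Q/(2 S_{ij}S_{ij})$ masks
  nodes with $S_{ij}S_{ij}$ below $10^{-14}$ of its mean.
* Grid validation: readers reject non-uniform spacing beyond $10^{-6}$
  relative and name missing nodes; arithmetic between fields requires
  identical grids — nothing broadcasts silently.

## Known limitations

* Strictly 2-D: no three-dimensionalisation, no vertical structure
  beyond the single friction coefficient.
* The kinematic scenarios have no feedback of the flux onto the mean
  flow; only the solver experiment closes that loop.
* The solver's laboratory realism stops at "laminar shear band plus
  compact momentum source"; boundary layers, electromagnetic forcing
  geometry and free surfaces are out of scope.
* MWLS reconstruction is exact only for locally polynomial fields; under
  severe under-resolution (features narrower than the fit radius) it
  smooths, which is the same trade a laboratory cubic re-gridding makes.
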