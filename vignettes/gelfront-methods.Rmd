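---
title: "Methods: simulating and tracking the barium-alginate gelation front"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and tracking the barium-alginate gelation front}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

When a body of ultra-high-viscosity (UHV) alginate sol meets a BaCl~2~ bath,
Ba^2+^ ions diffuse inward and bridge guluronate blocks of neighbouring
chains ("egg-box" coordination), converting free polymer into a stationary
cross-linked network. The visible signature is a thin reaction front that
travels from the rim to the core. `gelfront` models this with a
mixture-theory continuum description carrying four fields on a radially
symmetric domain:

* $\rho_{poly}$ — free-polymer partial density,
* $\rho_{ba}$ — free-barium partial density,
* $\rho_{cross}$ — cross-linked-polymer partial density (stationary),
* $\kappa \in [0,1]$ — binding occupancy, the fraction of cation-binding
  positions of the network already occupied.

The coupled system is

$$\partial_t \rho_{poly} = \nabla\!\cdot\!\big(D^0_{poly}
  e^{-K_{poly}\rho_{cross}} \nabla \rho_{poly}\big)
  - C_{poly}\,\rho_{poly}\rho_{ba},$$
$$\partial_t \rho_{ba} = \nabla\!\cdot\!\big(D^0_{ba}
  e^{-K_{ba}\rho_{cross}} \nabla \rho_{ba}\big)
  - C_{ba}\,\rho_{poly}\rho_{ba}
  - C_{\kappa ba}\,\rho_{ba}(1-\kappa)\rho_{cross},$$
$$\partial_t \rho_{cross} = (C_{poly}+C_{ba})\,\rho_{poly}\rho_{ba}
  + C_{\kappa ba}\,\rho_{ba}(1-\kappa)\rho_{cross},$$
$$\partial_t \kappa = C_{\kappa}\,\rho_{ba}(1-\kappa)\rho_{cross}.$$

The cross-link source is minus the sum of the two free-phase sources, so
reaction mass is conserved identically; the network neither diffuses nor
advects (no swelling/syneresis — a known limitation, see below). Diffusion
is Fickian with an exponential hindrance in the local cross-link density:
as the mesh tightens, both the polymer and (much faster) the ion slow down.

A typographical note on the source equations: one earlier statement of the
barium balance reuses the primary-attachment coefficient and an unnamed
"cross" coefficient for the two sink terms; the implemented system above,
with distinct $C_{ba}$ and $C_{\kappa ba}$, is the one that matches the
published parameter table, and is what this package implements. Likewise
the flux term is implemented as div(D grad), the only reading consistent
with Fick's law.

## Units and the published parameters

The published parameter table gives diffusivities in m^2^/s but no units
for the four rate constants and two hindrance exponents. `gelfront`
therefore adopts an explicit nondimensional convention
(see `unit_system()`):

| quantity | reference | model value |
|---|---|---|
| length | mm | — |
| time | s | — |
| free barium | 10 mM bath | baths 10/20/40 mM → 1, 2, 4 |
| free polymer | the 0.65 % w/v mixed sol | initial body → 1 |
| cross-linked polymer | polymer reference units | starts at 0 |

Defaults (`model_parameters()`): $D^0_{poly} = 6.78\times10^{-12}$,
$D^0_{ba} = 6.78\times10^{-9}$ m^2^/s, $K_{poly}=2.5$, $K_{ba}=2.3$,
$C_{poly}=0.16$, $C_{ba}=0.08$, $C_{\kappa ba}=C_{\kappa}=0.025$, the
published best-fit set. $C_{\kappa ba}$ and $C_{\kappa}$ are kept as
independent parameters even though their published values coincide.

Two consequences of this convention are worth stating plainly:

* $\rho_{cross}$ accumulates **total** exchanged mass — polymer plus
  absorbed barium. Starting from $\rho_{poly}=1$ it saturates near 2.5
  model units (1 from polymer, 0.5 from primary-attachment barium since
  $C_{ba}/C_{poly}=\tfrac12$, and up to 1 from secondary absorption, which
  is capped because $C_{\kappa ba}=C_{\kappa}$ makes total secondary uptake
  equal $\kappa_\infty \le 1$).
* Absolute time scales are the convention's, not the experiment's. With
  $K_{ba}\rho_{cross}\approx 5.7$ behind the front, barium diffusion is
  hindered ~300-fold and a 2.5 mm disc gels in ~$5\times10^4$ s (40 mM)
  rather than the tens of minutes seen on the microscope. Every property
  the package asserts — concentration orderings, two-phase kinetics,
  geometry effects — is invariant under this rescaling; absolute agreement
  with wall-clock experimental times would require re-fitting the rate
  constants under a different density normalisation, which the published
  table does not determine.

## Discretisation and time integration

Space: conservative finite volumes on $[0, R]$ with metric $r^m$
($m = 0, 1, 2$ for slab, disc, sphere), nodes graded 2× finer in the outer
20 % of the radius where the front is born (`radial_grid()`). Face
diffusivities are harmonic means of the node values — the right average
when $D$ drops by orders of magnitude across one cell, as it does at the
front. The scheme is exact for quadratic fields with constant $D$ (so the
`spatial_operator()` test against $2D(m+1)$ on $r^2$ checks to round-off)
and second-order accurate otherwise; convergence order is demonstrated on
a quartic field, where the truncation error is nonzero.

Time: the reaction timescale at bath densities ($C\rho\rho \sim 1$/s) is
three orders of magnitude faster than hindered diffusion, so the
semi-discrete system is stiff. The integrator is TR-BDF2 (trapezoid to
$t+\gamma h$, then BDF2, $\gamma = 2-\sqrt2$): one-step, L-stable, second
order, with an embedded third-order error estimate filtered through the
iteration matrix. Newton systems use an analytic Jacobian in banded form
(node-major ordering, half-bandwidth 4) factored by LAPACK `dgbtrf`. The
environment provides no stiff ODE package for R, so this is implemented in
the package's compiled code; a variable-order BDF would add machinery
without changing any tested property. Defaults: rtol $10^{-6}$, atol
$10^{-9}$; boundary conditions are Dirichlet barium at the rim (the bath is
treated as an unlimited reservoir — it holds roughly five disc volumes),
zero-flux polymer everywhere, no transport at all for $\rho_{cross}$ and
$\kappa$. Values in $[-10^{-8}, 0)$ are clamped to zero on output; anything
below that aborts the run.

## Front extraction

The experimental observable is the bright ring where gelation is ongoing,
so the front is defined as the radius of maximum instantaneous
$\rho_{cross}$ production (not a threshold on cured gel). Ties break
outward. The peak is refined to sub-cell precision by a parabola through
the peak node and its neighbours; without this the radius is quantised to
the grid and the calibration objective becomes a staircase.

Completion ("total gelation time") is declared when the front radius falls
within 2 % of the initial radius, or when detection fails persistently.
Two details deviate deliberately from the simplest rule and are worth
recording:

* **Dissipation reference.** A front is "dissipated" when its production
  peak drops below 1 % of the recent historical maximum — the maximum over
  the trailing 20 detected states, *excluding* the initial state. At
  $t=0^+$ full polymer meets full bath concentration at the rim and
  production spikes to ~$10^2$–$10^3$ times the quasi-steady front value;
  referenced to that global spike, the rule would declare the front dead
  seconds into a multi-hour run while it is still travelling. Against the
  trailing window the peak decays slowly during propagation but collapses
  by orders of magnitude within a few output frames once the front
  converges at the core, so the rule fires exactly once, and in practice
  after the 2 %-radius rule.
* **Isolated dropouts.** One missing detection surrounded by detections is
  treated as tracker noise (relevant for the image-based tracker under
  heavy noise); completion requires two consecutive misses or a miss on
  the final state.

Velocities follow the experimental analysis: a continuous single-breakpoint
piecewise-linear least-squares fit of radius against time, scanning every
interior observed time as the candidate breakpoint (deterministic
exhaustive search). Both slopes are negative (the ungelled core shrinks);
the early slope is steeper. A single line fitting as well as two flags the
breakpoint as unidentifiable; a constant trajectory yields zero slopes with
a warning.

## Synthetic imaging

`render_frame()` projects the radially symmetric production profile onto a
pixel grid (default 10 µm/px — the study does not print its camera's pixel
size, so this is an arbitrary but realistic choice), adds quadratic
vignetting, a background pedestal and i.i.d. Gaussian noise under a fixed
seed. Frames in a series are normalised per frame by default, emulating an
autoscaled acquisition (the experimental preprocessing also autoscales):
the ring keeps its contrast while the reaction lives and drops into the
noise floor only when production truly flattens. The tracker mirrors the
experimental pipeline: a difference-of-Gaussians bandpass
($\sigma = 3/2$ and $50/2$ px, the ImageJ "filter large structures down to
50 px / small up to 3 px" setting; the directional-tolerance and saturation
options are cosmetic and omitted), azimuthally averaged radial profile in
1 px bins, peak with MAD-based prominence gating, parabolic sub-pixel
refinement, and an inward-motion consistency filter (outward jumps > 5 px
are dropped).

What a green round-trip test establishes: that the image-analysis pipeline
recovers the field-level gelation time within 10 % and late velocity within
15 % under additive noise, vignetting and pixel quantisation. What it does
not establish: robustness to real phase-contrast optics (halos,
shade-off), drift, uneven illumination beyond smooth vignetting, or debris
— the generator does not emulate those.

Stacks are stored as plain-text ASCII PGM frames plus a CSV sidecar
(timestamps, pixel size, quantisation range); the environment provides no
TIFF/PNG codec for R, and a 16-bit text PGM round-trips to within
1/65535 of the intensity range.

## Calibration

`trajectory_objective()` is the sum of squared differences between
simulated and observed front radii, with simulated radii linearly
interpolated to the observed times, summed over all observations (all
three bath concentrations jointly — the study does not say whether its fit
was joint or per-concentration; joint is the stronger constraint). A
simulation whose front has already vanished contributes the full observed
radius as residual, so disappearing early is penalised.

`fit_parameters()` optimises in log~10~ space *centred on the starting
values* (all parameters are positive scale parameters; centring makes a
0.1 step mean "×1.26" for every parameter alike). The default method is
damped Gauss-Newton (Levenberg-Marquardt) on the residual vector with a
forward-difference Jacobian. A derivative-free simplex was tried first
and kept as `method = "nelder-mead"`, but on the interesting
$(C_{poly}, D^0_{ba})$ pair the misfit forms a narrow curved compensation
valley, and the simplex reproducibly stalls far from the minimum within
any reasonable evaluation budget; the least-squares structure of the
objective is real information and LM uses it, converging in ~10 iterations.

The valley holds a second lesson about identifiability: besides the true
minimum there is a shallower *impostor* basin (roughly $C_{poly}$ halved
and $D^0_{ba}$ tripled reproduces the front trajectories to ~10 µm RMS),
separated from the truth by a low ridge. A purely local descent started
two-fold off can settle there. For two or more free parameters the fit
therefore first evaluates a deterministic coarse grid (5 points per
parameter, ±0.6 decades — the half-decade scale of realistic prior
uncertainty on rate constants) and starts the local LM from the best grid
node. This is initialisation seeding, not global optimisation: no
guarantee is claimed beyond the screened box, and the whole procedure
stays deterministic. Coarse solver settings (hundreds of nodes, rtol
$10^{-5}$) are used during optimisation. Only small parameter subsets are
identifiable from front radii alone; the package asserts recovery for
$(C_{poly}, D^0_{ba})$ jointly and single parameters, never for all
eight — and the impostor basin shows why that caution is warranted.

## Numerical choices, degenerate inputs, tie-breaks

* Dirichlet rows in the Newton matrix are identity rows; the pinned bath
  node keeps its value exactly.
* Newton uses a chord approximation (diffusivities frozen in the Jacobian);
  non-convergence rejects the step and shrinks it threefold.
* "Reaction off" in verification runs means rate constants of $10^{-30}$:
  the parameter contract demands strict positivity, and $10^{-30}$ is
  dynamically indistinguishable from zero over any tested horizon.
* Degenerate trajectories (constant radius) yield zero velocities plus a
  warning; fewer than 8 detected points refuse the two-phase fit.
* Equal production peaks: outermost radius wins (the advancing interface).
* The grid must start at exactly $r = 0$; the symmetry face carries zero
  flux by construction.

## Known limitations

No shrinkage/syneresis (the gelled disc keeps its diameter); no osmotic or
co-ion (NaCl, Cl^-^) effects; radial symmetry is assumed, so azimuthal
instabilities and the experimentally observed micro-layering are out of
reach; the bath is an infinite reservoir; the 200 µm disc thickness is
collapsed (thin-film assumption); absolute times depend on the density
normalisation as discussed above. The end-of-run acceleration of the
simulated front — also reported for the original finite-element
implementation — is reproduced here and is a genuine feature of the
cylindrical/spherical focusing plus the dissipation of the front, not a
target of any test.
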