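---
title: "Morphodynamics of surface-attached active nematic drops: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphodynamics of surface-attached active nematic drops: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The physical model

`activedrop` simulates a two-dimensional drop of active nematic fluid —
a suspension of elongated, force-dipole-exerting units with orientational
order — attached to a rigid, impermeable substrate. The drop is pinned at
the two triple contact points $(0,0)$ and $(2,0)$ (lengths in units of the
initial drop radius $R$), starts as a semicircle at rest, and evolves under
the flow its own activity generates.

**Flow.** Inertia is negligible (Stokes flow), and the fluid is
incompressible and Newtonian:

$$\nabla\cdot\boldsymbol u = 0, \qquad \boldsymbol 0 = \nabla\cdot\boldsymbol\sigma,
\qquad
\boldsymbol\sigma = -\Pi\,\boldsymbol I
  + \left[\nabla\boldsymbol u + (\nabla\boldsymbol u)^{\mathsf T}\right]
  - \mathrm{Ca}\;\boldsymbol p\boldsymbol p .$$

All quantities are dimensionless: length in $R$, time in viscocapillary
units $\mu R/\gamma$, velocity in $\gamma/\mu$, pressure in $\gamma/R$. The
single flow parameter is the active Capillary number
$\mathrm{Ca} = \alpha/(\gamma/R)$, the ratio of the active stress scale
$\alpha$ to the capillary pressure; $\mathrm{Ca}>0$ is extensile,
$\mathrm{Ca}<0$ contractile.

**Nematic order.** In the strong elastic limit the orientation field relaxes
instantaneously to the minimiser of the one-constant Frank energy, so each
Cartesian component of the director $\boldsymbol p$ is harmonic,
$\nabla^2 \boldsymbol p = \boldsymbol 0$, with Dirichlet anchoring data: on
the substrate $\boldsymbol p = R(w_s\pi/2)\,\hat{\boldsymbol e}_x$ and on
the interface $\boldsymbol p = R(w_i\pi/2)\,\hat{\boldsymbol t}$, where the
integer winding numbers $w_s, w_i$ count counterclockwise quarter turns
relative to the boundary tangent. We take the harmonic model literally:
$|\boldsymbol p|$ is **not** renormalised in the bulk, so it dips towards
zero at orientational defects, which naturally regularises the active
stress there (a `normalize_director` flag exists for sensitivity studies).
A full nematic description through the Landau–de Gennes tensor
$\boldsymbol Q = S(\boldsymbol p\boldsymbol p - \boldsymbol I/2)$ solving
$0 = [a - b\,\mathrm{tr}(\boldsymbol Q^2)]\boldsymbol Q + K_Q\nabla^2\boldsymbol Q$
is available via `nematic_model = "qtensor"`; its active stress is
$-\mathrm{Ca}\,\boldsymbol Q$ (the isotropic offset between
$\boldsymbol p\boldsymbol p$ and $\boldsymbol Q$ is absorbed by the
pressure).

**Free surface.** The interface moves with the fluid's normal velocity
(kinematic condition) and carries the capillary traction
$\boldsymbol\sigma\cdot\hat{\boldsymbol n} = -C\,\hat{\boldsymbol n}$, with
$C$ twice the mean curvature, $C=+1$ on the unit semicircle, and
$\hat{\boldsymbol n}$ the outward normal. The substrate is no-slip
($\boldsymbol u = \boldsymbol 0$), including the contact vertices.

Because the nematic field and the flow are instantaneous functionals of the
geometry, the interface polyline is the **only** dynamical state: every step
re-solves both fields quasi-statically on the current shape.

# Discretisation

**Interface.** An ordered polyline from the left contact over the apex to
the right contact, with nodes kept equispaced in arclength by resampling
after each step (tangential motion is a pure reparameterisation). Tangents
are central differences; curvature is the signed circumscribed-circle
formula through each node and its neighbours, one-sided at the pinned ends
(exact on circles, second-order on smooth curves under near-uniform
sampling). Endpoint curvature is used only in diagnostics-adjacent
interpolation; the contact vertices themselves carry the no-slip condition.

**Mesh.** All curve nodes become vertices of an unstructured triangulation
(so the mesh boundary polygon equals the curve polygon exactly); boundary
edges are graded down to $0.25\,h$ within $0.2$ of the contact points to
resolve the corner stress singularity and the anchoring-mismatch defects
there, and the size field additionally follows the local interface height so
thinning regions stay resolved. Interior vertices come from a hexagonal
lattice with a tiny deterministic jitter (seeded from the configuration, so
runs are bit-reproducible), triangulated by Bowyer–Watson insertion, then
improved by Lawson flips and smoothing until the minimum angle is at least
15°. Between full rebuilds the mesh follows the interface by harmonic
extension of the boundary displacement (cached factorisation); a rebuild is
triggered when the interface has moved more than `remesh_disp_factor * h`
(default 2) since the last build or the minimum angle drops below 15°. We
deliberately relaxed the displacement trigger relative to a
rebuild-every-step strategy: the deformation map is smooth and quality-
checked, and fields are never interpolated across meshes — they are
recomputed from the geometry, which is the only state.

**Flow solve.** Mixed Taylor–Hood elements (quadratic velocity, linear
pressure) — inf-sup stable without stabilisation. The active stress enters
the weak form as $\int \mathrm{Ca}\,(\boldsymbol{pp}):\nabla\boldsymbol v$
on the right-hand side; the capillary traction is assembled edgewise from
the nodal curvature with Simpson quadrature on the quadratic trace
(a Laplace–Beltrami variant, `traction = "laplace_beltrami"`, integrates the
tangent form by parts instead). The traction condition fixes the pressure
level, so the saddle system has no nullspace and is solved by sparse LU.
On the exact semicircle at $\mathrm{Ca}=0$ the discrete curvature is exactly
1 and the solver reproduces the static equilibrium
($\boldsymbol u \approx 10^{-14}$, $\Pi = 1$); a manufactured solution with
quartic velocity converges at order $\gtrsim 3$ in the velocity.

**Director/Q solves.** Linear (P1) elements. The harmonic director is two
Dirichlet–Laplace solves; the stationary Landau–de Gennes equation is solved
by damped Newton (lumped-mass bulk term, exact sparse Jacobian) initialised
from the harmonic extension after a short semi-implicit pre-relaxation;
on stagnation it falls back to the semi-implicit gradient flow (implicit
diffusion, explicit bulk term, single cached factorisation).

**Time stepping.** Explicit first-order updates of the interface:
each node moves by $\Delta t\,(\boldsymbol u\cdot\hat{\boldsymbol n})\hat{\boldsymbol n}$.
The nodal normal speeds are obtained by projecting the quadratic interface
flux onto the curve-node hat functions and dividing by the discrete area
gradient (half the neighbour chord); the flux share of the pinned endpoints
is handed to their neighbours. With this construction the implied polygon
area rate telescopes to the discrete flux through the interface, which
vanishes by incompressibility — the scheme conserves area up to geometric
truncation error, and a uniform normal projection (`area_projection`,
default on) removes even that, keeping the area drift at machine precision
over full runs. The step is
$\Delta t = \min(\Delta t_{\max},\ c\,\Delta s/|\boldsymbol u|_{\max})$
with $c$ the CFL factor (default 0.5) and
$\Delta t_{\max} = 0.5\,h$ by default, which respects the explicit
capillary stability limit (the stiffest capillary mode relaxes at a rate
proportional to the interface node spacing).

**Pinned-contact exclusion wedge and contact condition.** The contact line
is pinned: the drop can neither spread nor dewet. The free interface may
legitimately overhang *above* the substrate (mushroom-type caps), but at
strong extensile activity the discrete interface tends to push nodes onto
the wall beyond the pins and crawl outwards — which is spreading. Nodes are
therefore kept out of an exclusion wedge hinged at each pin (opening
`pin_guard_deg`, default 60°, measured from the wall) by perpendicular
projection onto the wedge edge; small folds thrown up at the wedge are
excised (standard front-tracking loop removal). Where the interface rests
on the wedge, the Stokes solve switches those edges from free capillary
traction to a no-penetration (free-slip) obstacle condition, imposed by a
penalty on $\boldsymbol u\cdot\hat{\boldsymbol n}$; contacts whose reaction
turns adhesive are released and the solve repeated once. Without this
feedback the flow would press against the constraint indefinitely and no
steady state would exist; with it, strongly spreading drops settle into
constrained equilibria with a stationary pile at each pin. The wedge angle
is a numerical regularisation of the pinning constraint — the continuum
model is silent on how close to the wall an overhang may approach — and
morphologies at large $|\mathrm{Ca}|$ depend on it; see *Limitations*.

**Steady-state detection.** The drop is declared steady at the first sample
time $t^*$ such that over the whole window $[t^*, t^*+1]$ the relative drift
of $|\boldsymbol u|_{\max}$ stays below `steady_tol` (default $10^{-3}$) per
unit time and the maximum interface normal speed stays below `steady_tol`.
Records are sampled every `cadence` (default 0.25) time units. This is an
operational criterion, deliberately strict: the approach to steady state is
a clean exponential, and the detector fires roughly when the slowest mode
has decayed to $10^{-3}$ relative amplitude, which is later than the point
where a plotted $|\boldsymbol u|_{\max}(t)$ looks flat by eye.

# Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `ca` | active Capillary number (sign = extensile/contractile) | 0 | — |
| `w_s`, `w_i` | substrate / interface winding numbers | 0, 0 | quarter turns |
| `h_mesh` | target mesh edge length | 0.05 | $R$ |
| `n_interface` | interface nodes | $\lceil\pi/h\rceil+1$ | — |
| `dt_max` | time-step cap | $0.5\,h$ | $\mu R/\gamma$ |
| `cfl_factor` | advective step fraction | 0.5 | — |
| `steady_tol` | steady-state tolerance | $10^{-3}$ | per unit time |
| `landau$a`, `landau$b` | Landau coefficients ($S_{\max}=\sqrt{2a/b}$) | 1, 2 | — |
| `landau$K_Q` | Q elastic constant (coherence length $\sqrt{K_Q/a}$) | $2.5\times10^{-3}$ | $R^2$ |
| `pin_guard_deg` | pinning exclusion wedge | 60 | degrees |

The Landau defaults make $S_{\max}=1$ with a defect-core coherence length of
$0.05$, resolvable at the default mesh; the main-text model gives no values,
so results with the Q pipeline should be read as parameter-dependent. For
the Q-tensor symmetry checks in the test suite the core is widened
($K_Q = 0.02$) so that it stays resolved at the coarse test resolution —
an under-resolved core rattles between remeshes and masquerades as
symmetry breaking.

# Diagnostics

* **Vortex census**: the streamfunction solves
  $-\nabla^2\psi = -\omega$ with $\psi = 0$ on the boundary (exact at steady
  states, where the boundary is a streamline); vortices are interior extrema
  of $\psi$ with $|\psi| \ge 0.05 \max|\psi|$, merged within $2h$; the sign
  gives the rotation sense.
* **Defect census**: local minima of $|\boldsymbol p|$ below a threshold
  (default 0.75), merged within $2h$. The default counts the quarter-turn
  anchoring-mismatch defects at the contact corners: a $\pi/2$ jump in the
  boundary data makes the harmonic $|\boldsymbol p|$ dip to exactly
  $1/\sqrt2 \approx 0.707$ (wedge harmonic extension), while $\pi$
  mismatches and bulk defects drive $|\boldsymbol p|$ towards 0. A threshold
  of 0.3, sometimes natural for deep bulk defects, can never fire at a
  $\pi/2$ corner in the unnormalised model.
* **Entropy production**: $\dot s_v = \int (\nabla\boldsymbol u +
  \nabla\boldsymbol u^{\mathsf T}) : \nabla\boldsymbol u\,\mathrm dA \ge 0$
  and $\dot s_a = -\mathrm{Ca}\int (\boldsymbol{pp}):\nabla\boldsymbol u\,
  \mathrm dA$, with exact quadrature for the discrete polynomial degrees,
  reported in $\rho T$-scaled dimensionless form. At an exact steady state
  the divergence theorem forces $\dot s_v + \dot s_a = 0$; we report both
  terms and their sum separately and treat only the robust statements
  ($\dot s_v \ge 0$, quadratic small-Ca scaling, $\dot s_a < 0$) as claims.
* **Morphology classifier** (thresholds config-exposed): film-two-lobes if
  the central interface height falls below 0.25 of the maximum and the
  height profile has two maxima; broken-symmetry if the mirror asymmetry
  (area of the symmetric difference with the $x\to2-x$ reflection over the
  drop area, computed by exact interval arithmetic on symmetric scanlines)
  exceeds 0.01; mushroom if the width above half the apex height exceeds
  the contact width by 5%; else simple-symmetric. The mushroom rule also
  fires for strongly flattened extensile drops with corner bulges; the film
  and symmetry rules, which carry the scientific claims, are unaffected.

# Symmetries used as tests

Three exact discrete identities anchor the test suite: (i) *linearity* — for
fixed geometry and nematic field the flow is exactly linear in
$\mathrm{Ca}$; (ii) *duality* — rotating all boundary directors by a quarter
turn and flipping the sign of $\mathrm{Ca}$ adds only the isotropic stress
$\mathrm{Ca}\,|\boldsymbol p|^2 \boldsymbol I$, absorbed by the pressure, so
$(w_s, w_i, \mathrm{Ca})$ and $(w_s{+}1, w_i{+}1, -\mathrm{Ca})$ give
identical velocities to solver precision; (iii) *mirror equivariance* — the
$w_i = 3$ director field is the negated mirror of the $w_i = 1$ field
(negated because the polarized boundary data is head–tail sensitive even
though the bulk active stress is not), so shapes and flows mirror exactly.

# Problem sizes

The package defaults ($h = 0.05$, about 700 vertices and 6–7k velocity
unknowns) are used for the timing, vortex-census and defect criteria in the
acceptance suite. The scaling fits, the morphology sweep and the protocol
property checks run at $h = 0.1$ (about 2k unknowns), where the fitted
exponents and shape classes are unchanged; these sizes keep a full test run
in tens of minutes on one core. The acceptance script reports, for each
quantity, the number of unknowns or runs used.

# Design decisions on open points

* **Corner precedence**: the two contact vertices take the substrate
  anchoring value; the interface/substrate mismatch is absorbed by the
  graded mesh, mimicking the boundary defects at the triple points.
* **Rotation sense**: counterclockwise for positive winding; $(0,1)$ is the
  counterclockwise quarter turn and $(0,3)$ its clockwise mirror.
* **No bulk renormalisation of p** (see above); the flag exists.
* **Corner grading factor 0.25** within 0.2 of the pins: our choice; the
  continuum treatment of the contact-line singularity is not specified by
  the model.
* **Steady criterion and cadence**: chosen once (1e-3, 0.25) as the
  operational definition; both config-exposed.

# Limitations

* First-order explicit time integration with capillary-limited steps; runs
  at fine meshes are proportionally slower ($\Delta t \propto h$).
* The high-$|\mathrm{Ca}|$ extensile morphology depends on the
  pinned-contact regularisation. With the default wedge, strong extensile
  drops flatten into a pancake with corner piles; a central film connecting
  two lobes does not appear in the sweeps the acceptance suite runs, and a
  film-shaped initial condition refills towards the pancake on the
  viscocapillary timescale at those resolutions. The quasi-static model as
  implemented here therefore does not reproduce a film-two-lobes attractor;
  resolving whether this is a resolution effect, a consequence of the
  one-sided free-surface treatment (the ambient air exerts no lubrication
  resistance), or a genuine branch difference would require the original
  study's unreported numerical scheme.
* The steady-state detector is stricter than a visual plateau read; reported
  equilibration times are correspondingly later.
* No inertia, no outer-fluid viscosity, no proliferation, no nematic
  advection (the strong elastic limit removes the rotational viscosity and
  vorticity coupling); pinch-off is detected and reported, not simulated
  through.

# A minimal session

```{r, eval = FALSE}
library(activedrop)
cfg <- sim_config(ca = -2.5, anchoring = anchoring_spec(0, 0),
                  h_mesh = 0.1, t_end = 15)
run <- simulate_drop(cfg)
summary(run)
plot(run, "shape")
psi <- streamfunction(run$flow, run$mesh)
vortex_census(psi, run$mesh)
```
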