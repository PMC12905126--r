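# activedrop

Simulation of the morphodynamics of a 2D drop of **active nematic fluid**
pinned to a rigid substrate — the continuum setting behind bacterial
colonies, tissues, and microtubule suspensions sitting on surfaces. The
drop contains elongated, self-driven units with orientational order; the
stresses they exert generate internal Stokes flow that deforms the drop's
free interface, which in turn reorganises the units. `activedrop` solves
the full moving-boundary problem (no thin-film approximation) and tracks
the drop to its steady shapes and flows.

## Model

Dimensionless incompressible Stokes flow with an active stress,

$$\nabla\cdot\boldsymbol u = 0,\qquad
\boldsymbol 0 = \nabla\cdot\boldsymbol\sigma,\qquad
\boldsymbol\sigma = -\Pi \boldsymbol I
 + \nabla\boldsymbol u + (\nabla\boldsymbol u)^{\mathsf T}
 - \mathrm{Ca}\,\boldsymbol{pp},$$

on a drop pinned at $(0,0)$ and $(2,0)$ (lengths in the initial radius
$R$, time in viscocapillary units $\mu R/\gamma$). The director field
$\boldsymbol p$ is quasi-static — componentwise harmonic,
$\nabla^2\boldsymbol p = 0$ (strong elastic limit) — with winding-number
anchoring: $\boldsymbol p = R(w_s \pi/2)\hat{\boldsymbol e}_x$ on the
substrate and $\boldsymbol p = R(w_i \pi/2)\hat{\boldsymbol t}$ on the
interface. The interface moves with the fluid under the capillary traction
$\boldsymbol\sigma\cdot\hat{\boldsymbol n} = -C\hat{\boldsymbol n}$. The
three control parameters are the active Capillary number
$\mathrm{Ca} = \alpha R/\gamma$ (extensile $>0$, contractile $<0$) and the
winding numbers $(w_s, w_i)$. A Landau–de Gennes Q-tensor variant
(`nematic_model = "qtensor"`) replaces the polarized director with a true
nematic.

Numerics: unstructured Taylor–Hood (P2/P1) finite elements on a
triangulation that tracks the interface polyline; explicit, area-conserving
interface updates; deterministic meshing. See the methods vignette
(`vignettes/active-drop-model.Rmd`) for the discretisation, parameter
defaults, and design decisions.

## Worked example

A contractile drop with tangential anchoring on both boundaries
($w_s = w_i = 0$, $\mathrm{Ca} = -2.5$), run at coarse resolution:

```r
library(activedrop)
cfg <- sim_config(ca = -2.5, anchoring = anchoring_spec(0, 0),
                  h_mesh = 0.1, t_end = 15)
run <- simulate_drop(cfg)
summary(run)
#> Drop run: Ca = -2.5, model = director, h = 0.1
#>   final time 5.300 (steady); |u|_max = 0.0563; area drift 9.08e-07%
#>   morphology: simple-symmetric; asymmetry 0.0004; vortices 2; defects 0

psi <- streamfunction(run$flow, run$mesh)
vortex_census(psi, run$mesh)$vortices
#>           x         y          psi
#> 1 0.5590781 0.5255294 -0.010116219
#> 2 1.4692327 0.5337523  0.009994296
```

The run reaches a steady state a few viscocapillary times in (detector
fires at $t = 4.25$), the drop area is conserved to machine precision, the
shape stays mirror-symmetric, and the internal flow settles into two
counter-rotating vortices (opposite signs of the streamfunction extrema)
placed symmetrically about the midplane — the signature steady state of
contractile parallel anchoring. Switching to $w_i = 1$ breaks the mirror
symmetry; `run_protocol()` drives time-dependent anchoring schedules, and
`sweep_state_diagram()` maps morphologies over a $(\mathrm{Ca}, w)$ grid.

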