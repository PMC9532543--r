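---
title: "Modelling projectile-driven compression-shear loading of cultured cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling projectile-driven compression-shear loading of cultured cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellhammer)
```

## The loading method

Cells cultured on the bottom wall of a liquid-filled rectangular
microchannel can be loaded dynamically by striking the liquid column with a
projectile. The impact launches a weak compression front that traverses the
channel at roughly the acoustic speed; as it sweeps over each cell it
applies a MPa-scale compressive stress directly, and — because the fluid is
viscous — a synchronous kPa-scale shear stress through the boundary layer
the moving core flow drags up at the wall. Both components are controllable:
the impact velocity sets the amplitude, the projectile length sets the pulse
duration.

`cellhammer` is a desk-scale model of that rig. It predicts, for a given
fluid, projectile and channel, the inlet pressure pulse, the propagating
pressure and velocity fields, and the compression and axial-shear time
histories a cell at any station experiences, along with the design criteria
that tell you whether the continuum, rigid-wall and explicit-stability
assumptions hold for your geometry. It deliberately stays one-dimensional:
the reference 3D finite-volume treatment of this class of problem (meshed
CFD with a k-epsilon closure) is out of scope, and the package documents
where that matters.

## Liquid thermodynamics

The working liquid follows the Tait equation of state on the datum p = 0 at
the reference density,

$$p = B\left[(\rho/\rho_0)^\gamma - 1\right],$$

with the water preset using the empirical constants B = 3.35e8 Pa,
gamma = 7.15, rho0 = 999.8 kg/m^3, c0 = 1439 m/s, p0 = 101325 Pa,
mu = 1.0e-3 Pa s.

One numerical choice deserves emphasis. The empirical Tait constants and
the measured sound speed are not mutually consistent:
sqrt(gamma B / rho0) = 1548 m/s, about 8% above the measured c0 = 1439 m/s.
The package therefore treats (rho0, c0, gamma, B) as four independent
givens and splits their roles:

* the pressure–density relation (`tait_pressure()`, `tait_density()`) uses
  the printed B verbatim;
* every wave-speed quantity — `local_sound_speed()`, the shock-jump
  relations, the conduit celerity, the solver — is anchored at (rho0, c0)
  through the bulk modulus K = rho0 c0^2, using the Tait exponent for the
  curvature. Concretely, the shock-jump density input is taken on the
  acoustic isentrope rho0 (1 + gamma p / K)^(1/gamma), which has exactly the
  slope 1/K at the reference state.

Without this split the acoustic limits degenerate (the jump relations would
return front speeds near 1548 m/s for vanishing amplitude). With it, all
wave speeds reduce exactly to c0 and the pressure evaluations reproduce the
empirical Tait curve. The first-order density correction
`linearized_density()` (rho0 + p/c0^2) is the tangent of the anchored
isentrope; against the printed-B curve it agrees to first order only
(within 0.3% over the 0–30 MPa range), which is the direct numerical
footprint of the constants' inconsistency.

All EOS-layer pressures are gauge on the Tait datum; the solver and all
exported fields carry the explicit ambient offset p0 and are labelled
total. This avoids silently double-counting the ambient pressure when the
inlet pulse (gauge) meets the outlet boundary condition (absolute).

## Weak-shock jump relations

For the weak fronts of interest (a few MPa against a bulk modulus of
2 GPa), the Rankine–Hugoniot jump is treated isentropically:

$$c_s = \sqrt{\frac{\rho_1}{\rho_0}\frac{p_1 - p_0}{\rho_1 - \rho_0}},
\qquad u_1 = c_s\,\frac{\rho_1 - \rho_0}{\rho_1}.$$

`jump_residuals()` provides the conservation oracle: for states built this
way the mass and momentum balances in the front-fixed frame close to
machine precision (the isentropic front speed happens to conserve both
exactly), and the energy (Bernoulli) residual measures the neglected
entropy production, growing smoothly from ~5e-8 at 1 MPa. Rarefaction
fronts are rejected rather than mishandled. The polytropic-gas Hugoniot
ratio (`density_ratio()`) is included for completeness but sits outside the
solver path, which stays on the liquid isentrope throughout.

At the representative 3 MPa amplitude the front speed exceeds c0 by about
4 m/s (0.3%). The solver propagates at the constant linear celerity and
reports the correction rather than feeding it back: 0.3% is below the
discretization error at the packaged problem sizes.

## The impact source

Pressure–velocity matching at the projectile/fluid interface gives the
pulse amplitude

$$\Delta p = \frac{Z_f Z_p}{Z_f + Z_p}\,u_p,$$

with Z the rho c impedances; the rigid-projectile limit is the Joukowsky
value Z_f u_p, always an upper bound. The buffer plate between projectile
and fluid is taken impedance-matched to the projectile and hence dropped
from the model (the projectile effectively strikes the fluid column
directly).

The projectile then decelerates against the pressure it generates. With the
isentropic slope linearized at normal conditions,
$(\partial p/\partial c)_s = \frac{2\gamma}{\gamma-1}\frac{p_0 + B}{c_0}
\approx 5.41\times 10^5$ Pa s/m, Newton's second law becomes a linear ODE
and the inlet pulse is exponential:

$$p(t) = p(0)\,e^{-\lambda t},\qquad
\lambda = \frac{\gamma - 1}{2}\,\frac{A_p}{m_p}\,
\left(\frac{\partial p}{\partial c}\right)_s.$$

`integrate_projectile_ode()` integrates the deceleration explicitly (RK4)
and is the independent oracle the tests compare the closed form against
(agreement to <0.1% over five decay times; impulse–momentum bookkeeping to
0.5%). The two control knobs behave as the method intends: amplitude scales
linearly with impact velocity at fixed length (lambda unchanged), and
lambda scales as 1/length at fixed velocity (amplitude unchanged). For the
packaged 0.01 m PMMA projectile lambda = 1.41e5 s^-1, a 7.1 microsecond
decay time.

The projectile impedance uses the material's longitudinal bulk wave speed
by default; the 1D matching argument does not by itself decide between bulk
and bar speed, the difference is a few percent for the packaged materials,
and the choice is explicit in the material presets (PMMA 1180 kg/m^3,
2757 m/s; steel 7850, 5900; borosilicate glass 2230, 5640 — standard
handbook values, all overridable).

## Conduit acoustics and design criteria

Wall compliance slows the surge below the free-fluid sound speed. The
celerity follows the general conduit form

$$c_f = 1\Big/\sqrt{\rho\left(\frac1K +
  \frac1A\frac{\delta A}{\delta p}\right)}$$

with the rectangular-duct area compliance assembled per wall: each wall is
a uniformly loaded fixed-fixed plate strip of span a or b and thickness e,
contributing plate bending (modulus E/(1-nu^2), nu inferred from E and G)
plus Timoshenko shear (modulus G, shear factor 5/6):

$$\frac{\delta A}{\delta p} = \frac{a^5 + b^5}{30\,E'\,e^3}
  + \frac{a^3 + b^3}{5\,G\,e}.$$

This factor is validated by its limits rather than against any single
printed coefficient: it is symmetric in a and b, monotone in E and e, and
vanishes in the rigid limit so that c_f -> c0. For the packaged glass-walled
3 x 3 mm channel with 3 mm walls, c_f = 1415 m/s — within 2% of c0, which
is what justifies the rigid-wall solver in the first place. The corrected
bulk modulus K_mod = rho0 c_f^2 is reported so a rigid-wall model can mimic
the compliant-wall celerity exactly.

Three criteria gate a run, each reported with its raw value so the decision
is auditable:

* **fluid loading** beta = (c_f^2/c_s^2)(rho_f/rho_s)(2R/e) with R the
  hydraulic-radius equivalent a b/(a+b) (the classical definition is for a
  round duct; the convention is recorded in the report). The rigid-wall
  treatment requires beta small; the flag threshold is 0.1, a quantification
  of "much less than one" chosen here since no canonical number exists.
  The packaged channel gives beta = 0.028.
* **continuum**: Knudsen number below 0.001. The liquid mean free path is a
  config input with default 3e-10 m (molecular scale of liquid water),
  giving Kn = 1e-7 for a 3 mm channel — seven decades of margin.
* **Courant**: C = c_f dt/dz <= 1 for the explicit characteristics scheme.
  The packaged grids specify dz and derive dt = dz/c_f (C = 1 exactly),
  which also makes the propagation interpolation-free.

## The transient solver

The solver is a fixed-grid method of characteristics for the linear
rigid-wall water-hammer equations — the standard scheme for 1D surge
problems, chosen over a finite-volume compressible solver because the
channel is acoustically one-dimensional (rigid walls, uniform section) and
MOC propagates the wave exactly at C = 1. Friction closures:

* `none` — the solver then reproduces the analytic travelling wave
  p(z,t) = p0 + p(0) e^{-lambda (t - z/c_f)} H(t - z/c_f) to machine
  precision on C = 1 grids (the discrete front is carried half-open:
  ambient exactly on the characteristic, the jump one step behind);
* `quasi_steady` (default) — laminar Poiseuille-equivalent wall friction
  for the rectangular section, f Re from the Shah–London aspect-ratio
  polynomial (56.9 for a square duct);
* `unsteady` — adds Trikha's three-exponential approximation of Zielke's
  laminar frequency-dependent kernel, applied on the hydraulic radius. The
  kernel is exact for a circular pipe only; for the rectangular section it
  is an approximation and is flagged as such.

Boundaries: the inlet pressure is prescribed as the impact pulse; the
outlet is either constant-pressure (reflection coefficient -1, velocity
doubling) or closed (coefficient +1, pressure doubling), both verified
from simulated reflections. Courant numbers above 1 are refused outright
rather than warned about.

Degenerate-input behaviour worth knowing: at C slightly below 1 the
space-line interpolation introduces numerical diffusion that smears the
front over a few cells (bounded, no overshoot); the leading-edge amplitude
carried by the discrete front is the pulse one time step after onset, so
peak readings sit lambda dt (about 1%) below the nominal amplitude at the
packaged resolution.

## Wall shear on the culture wall

The reference treatment resolves a turbulent boundary layer with wall
functions; at desk scale this package uses the laminar impulsively-started
boundary layer, which is also the theoretical basis originally invoked for
shock-induced boundary layers. Once the front passes a station the wall
shear is the Stokes first-problem gradient driven by the local core
velocity:

$$\tau_z(t) = \frac{\mu\,u_e(t)}{\sqrt{\pi\nu\,(t - t_a + t_{reg})}},$$

with boundary-layer thickness delta = sqrt(pi nu (t - t_a + t_reg)). The
t = t_a singularity is regularized by t_reg, defaulting to one solver time
step; the peak shear depends on this choice — which is exactly why t_reg is
exposed, reported with every trace, and why the package reports full
tau_z(t) histories rather than a single headline peak. For the
representative case the laminar estimate brackets the turbulence-model
value: 0.2 kPa at 30 microseconds elapsed, 4.4 kPa at one solver step,
against roughly 2 kPa from the 3D k-epsilon treatment. The tests assert
the bracket [0.1, 10] kPa, not the k-epsilon number: exact reproduction of
a turbulence closure is not claimed, and the transverse shear is
identically zero in this planar model (consistent with it being negligible
away from the side-wall edges in 3D).

The viscous normal-stress correction 2 mu du/dz is evaluated on the solved
field behind the front and confirmed below 1 Pa — six orders under the
compressive component — so the wall-normal stress is the total pressure for
practical purposes. The evaluation excludes the jump cell itself, where the
discrete gradient measures grid resolution rather than flow.

## The packaged cases and problem sizes

**Representative culture channel** (`preset_config("representative")`):
water-filled 3 x 3 x 60 mm channel, glass walls 3 mm thick, 0.01 m PMMA
projectile at 3 m/s. The velocity is an explicit input chosen so the
matched amplitude is ~3 MPa, the working point of the design study. Grid:
dz = 0.1 mm (600 cells), dt = dz/c_f ≈ 0.7e-7 s at C = 1, total time
4.2e-5 s (one full traversal, ~600 steps). The solve takes well under a
second; all tests run on this or smaller grids.

**Validation shot** (`preset_config("shot62")`): the classical projectile
water-hammer experiment — 0.67 kg steel projectile at 18.5 m/s into a
water-filled specimen tube of 38.1 mm bore and 12.74 mm wall, closed far
end. Two parameters are absent from the published record and are packaged
as explicit assumptions: the tube material (taken near-rigid, celerity
correction off — the 12.74 mm wall on a 38 mm bore makes this mild) and the
tube length (0.2 m, used only to exhibit the closed-end reflected wave).
The predicted peak, 25.8 MPa, is a pure source-model quantity independent
of both assumptions; it sits +3.1% from the recorded numerical peak
(25.03 MPa) and -5.1% from the experimental one (27.20 MPa).

```{r validation}
print(run_validation_shot62())
```

## What the model does and does not show

The 1D model conserves the inlet peak: interior peak pressures can only
fall (by friction) below the inlet amplitude, whereas the reference 3D
computation reports interior peaks a few percent *above* its nominal
3 MPa inlet. A rigid 1D linear model cannot produce that excess; we report
peaks as computed and do not tune toward it. Similarly, the laminar
attenuation per 15 mm of travel is far below the 1%-per-15 mm bound the
design study quotes (the bound is respected, not saturated); a turbulent
closure dissipates more. Cavitation, column separation, repeated impacts,
elastic waves inside the projectile, per-cell stress resolution and the
roughness effect of a confluent cell lawn are all outside the model — the
last deliberately, since the design study itself concludes the smooth wall
suffices within ~2%.

```{r example}
sim <- run_simulation(preset_config("representative"))
summary(sim$field)
vapply(sim$traces, function(tr) max(tr$tau_z), numeric(1))  # peak tau_z (Pa)
```
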