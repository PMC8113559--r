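---
title: "A particle model of RBC aggregation under sinusoidal pulsatile flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A particle model of RBC aggregation under sinusoidal pulsatile flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcflow)
```

## The model

`rbcflow` simulates red blood cells (RBCs) as 2D elastic disks of radius
$R = 4\,\mu m$ and mass $m = 2.94\times10^{-13}\,$kg moving through a rigid
micro-tube (diameter $h = 0.12$ mm, length $L = 0.5$ mm) under an *analytic*
sinusoidal pulsatile velocity field

$$u(t,x,y) = \left\{A_f \sin(\omega t - k_f x) + B_f\right\}
             \left(1 - \frac{4y^2}{h^2}\right),$$

a Poiseuille profile across the bore modulated by a traveling sine along the
axis. $A_f$ is the velocity amplitude, $B_f$ the mean flow velocity,
$\omega = 2\pi f$ with $f = 1$ Hz (60 BPM), and $k_f$ the wavenumber. The
field is prescribed, not solved for: it is compressible
($\partial u/\partial x \neq 0$), which is exactly what makes it interesting —
the axial velocity gradient alternately compresses and stretches the particle
suspension as the wave passes, and that axial shear is the driver of the
local "parabolic rouleaux" aggregation patterns the package quantifies.
Fluid feedback from the particles, Navier–Stokes coupling, deformable cells
and elastic walls are out of scope.

Each particle obeys Newton's second law with three forces:

* **Elastic contact** (Hertz-type): $f^e = k\,(2R - d)^{3/2}\,\hat n$ for
  center distance $d < 2R$, with $k = 3\times10^{-6}$ (overlap in meters).
* **Depletion aggregation** from a Morse potential
  $\Phi(\delta) = DA\,(e^{2B(\delta_0-\delta)} - 2e^{B(\delta_0-\delta)})$
  with surface distance $\delta = d - 2R$, giving
  $f^a = 2\,DA\,B\,(e^{2B(\delta_0-\delta)} - e^{B(\delta_0-\delta)})\,\hat n$;
  $DA = 10^{-25}$ J, $B = 10^{7}\,m^{-1}$, $\delta_0 = 11$ nm. The force is
  repulsive below $\delta_0$, attractive out to the cutoff
  $r_\mathrm{cut} = 1\,\mu m = 10/B$, where it is truncated (the truncated
  tail is below $e^{-10}$ of the force scale $2\,DA\,B$).
* **Stokes drag** $f^h = 6\pi\mu R\,(u - v)$ toward the local flow velocity,
  with $\mu = 1.2\times10^{-3}$ Pa·s.

### Shear decomposition

The velocity gradient splits into a radial and an axial shear rate,

$$\dot\gamma_y = \frac{\partial u}{\partial y}, \qquad
  \dot\gamma_x = \frac{\partial u}{\partial x},$$

with magnitude $\dot\gamma = \sqrt{\dot\gamma_x^2 + \dot\gamma_y^2}$ and
direction $\varphi = \mathrm{atan2}(\dot\gamma_y, \dot\gamma_x)$ (the
two-argument form resolves the quadrant ambiguity of
$\tan^{-1}(\dot\gamma_y/\dot\gamma_x)$). Under steady Poiseuille flow
($A_f = 0$) the axial component vanishes identically; under pulsatile flow
it is largest on the centerline — precisely where the radial shear is
smallest — which is why the aggregation analyses are organized around the
axial component and the axial-to-radial ratio in a 16 µm center band.

## Parameters, defaults, and how they were fixed

| parameter | default | why |
|---|---|---|
| $A_f$, $B_f$ | 1, 4 mm/s | reference pulsatile condition |
| $f$ | 1 Hz | one cardiac-like cycle per second |
| $k_f$ | $4\pi/L \approx 25.1\,mm^{-1}$ | see below |
| $h \times L$ | 0.12 × 0.5 mm | micro-channel geometry |
| $N$ | 533 | reference particle count (nominal 40% hematocrit) |
| $R$, $m$ | 4 µm, 2.94e-13 kg | RBC-scale disk |
| $k$ | 3e-6 N·m$^{-3/2}$ | contact stiffness (overlap in m) |
| $DA$, $B$, $\delta_0$ | 1e-25 J, 1e7 /m, 11 nm | depletion interaction |
| $\mu$ | 1.2e-3 Pa·s | plasma-like viscosity |
| $dt$ | 1e-5 s | see *Numerical choices* |

Three of these deserve comment, because the literature the model follows
does not pin them down and the package had to choose:

**Wavenumber $k_f$.** We take $k_f = 4\pi/L$: exactly two wavelengths per
tube length. This makes the analytic field consistent with the periodic
axial boundary of the particle engine (a particle leaving the outlet
re-enters the inlet *in the same phase of the wave*), and it reproduces the
documented axial-shear spans: $|\dot\gamma_x| \le A_f k_f \approx 25\,s^{-1}$
at $A_f = 1$ mm/s and $\approx 32\,s^{-1}$ at 1.3 mm/s. It is configurable
(`k_f` in `flow_params()`, `k_f_per_m` in the config file).

**Viscosity $\mu$.** Never stated in the sources the model draws on. We use
a plasma-like 1.2 mPa·s; it enters only through the drag relaxation time
$\tau = m/6\pi\mu R \approx 3.3\,\mu s$, which is so much shorter than any
flow time scale that particles are effectively advected by the field; the
dynamics are insensitive to moderate changes in $\mu$.

**Contact stiffness units.** The elastic law raises a length to the 3/2
power, so the printed prefactor (nominally N/m) cannot be dimensionally
exact. The only self-consistent reading — adopted here — is as a prefactor
on the overlap *in meters*, with effective units N·m$^{-3/2}$.

**Depletion calibration.** With the printed `DA = 1e-25` J the aggregation
force scale $2\,DA\,B = 2\times10^{-18}$ N is ~8 orders of magnitude below
the drag scale, so cohesion is dynamically irrelevant and "aggregation" is
flow-driven crowding only. `mech_params()` documents a physically admissible
range `DA` $\in [10^{-25}, 2\times10^{-16}]$ J (depletion energy density of
order 10 µJ/m² over an apposition area of order $R^2$). The package's
quantitative-reproduction runs use a calibrated `DA = 5\times10^{-17}` J —
large enough that bonded pairs survive axial stretching at the reference
pulsatile condition, beyond which results are insensitive — and record the
value in the run manifest. The default stays at the printed value.

**Hematocrit vs. count.** $N = 533$ disks of radius 4 µm occupy 44.6% of the
0.12 × 0.5 mm² tube, not 40%. The explicit count takes precedence; the
nominal hematocrit is stored as a label only (`hematocrit_label`).

## Numerical choices

**Integrator.** The drag term is stiff: $\tau \approx 3.3\,\mu s$ against a
1 s pulse period. A fully explicit scheme would need $dt < \tau$; instead the
engine uses an operator splitting in which the pairwise elastic + depletion
forces, the wall contact and the local flow velocity are frozen over the
step, and the remaining *linear* ODE
$m\dot v = F_\mathrm{pair} + 6\pi\mu R(u - v)$ is solved exactly:

$$v \leftarrow v_\infty + (v - v_\infty)e^{-dt/\tau}, \qquad
  v_\infty = u + \frac{F_\mathrm{pair}}{6\pi\mu R},$$

with positions advanced by the exact time integral of that velocity. This is
unconditionally stable in the drag term and first-order accurate in the
frozen quantities; the test suite verifies both the machine-precision
relaxation in steady flow and the $O(dt)$ convergence under pulsatile flow.
The default $dt = 10^{-5}$ s resolves the wave (a particle advances
$\sim 0.05\,\mu m$ per step, against a 250 µm wavelength) and commits an
$O(e^{-3})$ per-step relaxation error only in the frozen forces.

**Displacement limiter.** With calibrated depletion constants (next section)
the repulsive Morse core is stiff on the scale of the step: a deeply
overlapping pair can be assigned a force whose drag-balanced drift velocity
$F/6\pi\mu R$ would move it through many interaction ranges in one step,
after which the (frozen-force) scheme overshoots and the pair ping-pongs.
The engine therefore caps the pair-force drift velocity at
$v_\mathrm{cap} = 1/(2B\,dt)$ — at most half a Morse range $1/B$ of
force-driven displacement per step. Flow advection is never limited, and
forces at physical separations are far below the cap
($v_\mathrm{cap} = 5$ mm/s at $dt = 10^{-5}$ s versus sub-mm/s cohesive
drift), so the cap only removes the unphysical overshoot branch.

**Walls.** "Rigid tube" fixes no particular contact law. Walls act through a
Hertzian contact against a mirror particle reflected across the wall
(re-using the particle-particle elastic law), plus a hard clamp of centers to
$|y| \le h/2 - R$ as a safety net. Axially, positions wrap modulo $L$ with
velocity and force carried over unchanged.

**Initialization.** Centers are placed by seeded rejection sampling, uniform
over the tube with pairwise distance $\ge 2R$ (periodic metric) — so the run
starts with zero aggregation by construction. Initial velocities are set to
the local flow velocity to suppress the (3 µs) startup drag transient; a
from-rest start is available (`zero_velocity = TRUE`).

**Overflow guard.** The Morse repulsion grows like $e^{2B|\delta|}$ for deep
overlap; below $\delta = -0.5\,\mu m$ its magnitude is frozen at the value
there. In that regime the elastic contact dominates the physics anyway, and
the guard only prevents floating-point overflow.

## Aggregation quantification

A pair is **aggregated** when the center distance is strictly below
$2R = 8\,\mu m$ (periodic metric). Note this threshold coincides with the
elastic contact onset, so "aggregated" pairs are exactly the contacting
pairs. Aggregates are connected components of the pair graph; the **mean
aggregation size** (MAS) is the mean size of components with at least two
members, defined as 0 when there are none (the convention for the empty
case is ours).

**Equal-area shear deciles.** At a given time the chosen shear field
(axial, radial, or magnitude) is ranked over the 100 × 100 grid cells and
split into 10 rank-deciles of exactly 1000 cells each, ties broken by cell
index. A particle belongs to the section containing its center.

**Normalized aggregated count.** Aggregated particles per section divided by
the expected uniform count $N \times$ (section area / tube area) — $N/10$
for deciles. The realized initial count in a section is seed-noisy and
ill-defined for sections that move with the field; the expected count agrees
with it in expectation and makes runs comparable, so the package uses it
throughout (including the rectangular ROI, where the baseline for the
default 0.1 × 0.1 mm² center box is $533/6 \approx 88.8$). Values above 1
mean locally elevated hematocrit, mainly due to rouleaux formation.

**Cycle statistics.** Decile profiles are read out at phase $t/T = 0.9$ of
each cycle and averaged over all simulated cycles (default five, no warm-up
discarded). Hysteresis curves fold per-snapshot (mean shear, normalized
count) pairs onto a phase grid, average within phase bins across cycles, and
report the signed shoelace area of the mean loop (positive =
counterclockwise).

## What the simulation does and does not show

The particle dynamics here are dominated by advection through a compressible
traveling wave: where $\partial u/\partial x < 0$ the suspension is locally
compressed, particles come into contact, and dense bands form that trail the
wave's compression zones — the same mechanism that produces the arc-shaped
("parabolic") rouleaux patterns near the tube center, where radial shear is
too weak to strip them. With the depletion constants as printed, the
attractive force ($\sim 2\,DA\,B = 2\times10^{-18}$ N) is many orders below
the drag scale ($\sim 10^{-10}$ N), so cohesion contributes little and
aggregation here is primarily flow-driven crowding. The constants are
exposed in `mech_params()` / the config file for sensitivity studies.

With a calibrated `DA` (see above) cohesion is real: clusters bind in the
low-shear compression zones and survive part of the stretching phase, and
mean aggregation size grows steeply with the velocity amplitude. Two hard
ceilings still apply to any stable integration of this model. Excluded
volume caps the local area fraction near hexagonal packing at the Morse
equilibrium gap (~0.90, i.e. a normalized count of ~2.0 against the 44.6%
mean), so normalized counts well above 2 require deep many-body overlap,
which the calibrated repulsion forbids. And passive advection through the
compressible wave produces only a bounded, oscillatory densification (the
wave-frame velocity ratio, ~1.5 at the reference condition), not
cycle-over-cycle accumulation. Reference implementations that integrate the
stiff drag term explicitly at too coarse a step can instead pile particles
into overlapping clumps and report much larger values; this package's
unstable early builds did exactly that until the displacement limiter was
added.

Consequences to keep in mind:

* Aggregate *counts* and their dependence on $A_f$ and $B_f$ (more
  aggregation at higher amplitude and lower mean flow, monotone decay with
  radial shear under steady flow, hysteresis over the cycle) are robust
  model outputs.
* Absolute MAS values depend on the unreported time step, integrator and
  contact details of any reference implementation; quantitative comparisons
  are tolerance-based.
* Real blood adds cell deformability, biconcave shape, hydrodynamic
  inter-cell coupling and 3D packing — none of which are modeled. Passing
  tests show the model's internal consistency and the reproduction of its
  documented flow-driven trends, not physiological fidelity.

## Problem sizes used in the shipped analyses

The package's own test-and-reproduction workload is desk-scale by design:
single runs use the full $N = 533$, five cycles at $dt = 10^{-5}$ s;
sweeps reproduce a 300-amplitude study on a reduced grid of about 10
amplitudes, fewer cycles ($dt = 2\times10^{-5}$ s), which the sweep
machinery (`run_sweep()`) scales back up if desired. Stochastic trend checks
use three seeds.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(flow = flow_params(A_f = 1.3e-3, B_f = 4e-3))
traj <- run_simulation(cfg)

# cycle-averaged decile profile at phase 0.9 against axial shear
phase_profile(traj, "gx")

# center-ROI hysteresis: counterclockwise loop of normalized count vs shear
roi_hysteresis(traj)
```
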