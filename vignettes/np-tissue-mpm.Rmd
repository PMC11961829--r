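---
title: "Modeling clampable soft tissue with an affine material point method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clampable soft tissue with an affine material point method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(npsim)
```

## The problem

The nucleus pulposus (NP) — the gel-like core of the intervertebral disc —
is gripped, stretched, torn and removed during endoscopic discectomy. A
training simulator for that procedure needs a tissue model that (i) survives
extreme deformation and topology change (the tissue is torn apart), (ii)
shows the viscoelastic signatures of real soft tissue (creep under constant
load, stress relaxation at constant strain), (iii) accumulates permanent
(plastic) deformation, and (iv) reports a physically meaningful grip force
to a haptic device at every frame.

`npsim` implements this as a moving-least-squares material point method
(MLS-MPM): particles carry mass, velocity, an affine velocity matrix and a
deformation gradient; a transient background grid solves momentum each
frame. Mesh-free transfer makes tearing free — when particles separate by
more than the kernel support they simply stop interacting.

## The constitutive model

Each particle carries a deformation gradient $F$ with volume ratio
$J = \det F$, split multiplicatively into an elastic and a plastic part,
$F = F_E F_P$. The strain energy is compressible Neo-Hookean in the elastic
part:

$$\psi = \frac{\mu(J_P)}{2}\left(\mathrm{tr}(F_E^T F_E) - d\right)
  - \mu(J_P)\,\log J_E + \frac{\lambda(J_P)}{2}\,\log^2 J_E,$$

with first Piola–Kirchhoff stress

$$P = \mu(J_P)\,(F_E - F_E^{-T}) + \lambda(J_P)\,\log(J_E)\, F_E^{-T}.$$

Two mechanisms make this viscoelastic–plastic:

1. **Volume-ratio limits.** The elastic volume ratio is confined to
   $[1-\theta_C,\, 1+\theta_S]$ by a per-frame limit map: inside the range it
   is untouched; outside, the excess is pulled a fraction $k_c$ (below) or
   $k_s$ (above) of the way back toward the nearest limit. Applied once per
   frame to the elastic candidate $J/J_P$, with the plastic volume ratio
   $J_P$ ratcheting so that $J_E J_P = J$ always, the excess decays
   geometrically with per-frame ratio $1-k_s$. This is the entire
   viscoelastic engine: at held strain the stress decays to a plateau
   (relaxation); under sustained load the plastic ratio keeps ratcheting
   (creep / flow).
2. **Hardening.** The Lamé coefficients are functions of the plastic state,
   $\mu(J_P) = \mu_0\, e^{\xi(1-J_P)}$ (and likewise $\lambda$): compaction
   stiffens, dilatational plastic flow softens. The softening branch is what
   makes tension localize into a neck and tear.

### Statefulness

Applying the limit map to the *total* volume ratio each frame (a stateless
reading) yields a fixed stress at fixed strain — no relaxation. The package
therefore defaults to `plasticity_mode = "stateful"`: a per-particle $J_P$
persists across frames, the elastic candidate is $J/J_P$, and each
application of the limit map both relaxes the elastic excess and advances
$J_P$. The stateless mode is retained (`material_params(plasticity_mode =
"stateless")`) as a comparison baseline; the test suite checks that it
produces no decay during a relaxation hold, which documents why stateful is
the default.

Because $k_c, k_s$ act once per frame, they are per-$\Delta t$ quantities:
halving the time step doubles the number of relaxation steps per unit time.
$\Delta t$ is a configuration constant and runs use a fixed frame interval,
so the decay rate per unit time is well defined for a given configuration.

### Elastic rescaling

The elastic gradient is defined from the limited volume ratio by rescaling
the total gradient. A literal linear rescaling $F_E = (J_E/J) F$ does not
satisfy $\det F_E = J_E$ in more than one dimension; the package uses
$F_E = (J_E/J)^{1/d} F$, the unique isotropic rescaling for which the
determinant identity holds — and therefore the only reading under which the
volume limits act on the elastic volume change that the energy is written
in. The literal variant is available behind
`sim_config(paper_literal_scaling = TRUE)` for comparison.

## The solver loop

One frame executes four steps (`advance_frame()` chains them):

1. **Particle to grid** (`p2g()`): an affine-velocity increment is gathered
   from the previous frame's grid velocity-increment field; the deformation
   gradient updates as $F \leftarrow (I + \Delta t\,(C + \Delta C))\,F$;
   stress is evaluated through the split; mass and momentum scatter to the
   grid with quadratic B-spline weights, the momentum carrying the fused
   APIC + stress term
   $\omega_{ip}\left[m_p v_p + \left(m_p C_p - \tfrac{4\Delta t}{\Delta x^2}
   V_p^0 P F^T\right)(x_i - x_p)\right]$.
2. **Grid update** (`grid_update()`): $v_i = (mv)_i/m_i$ on active nodes,
   optional gravity and damping, then boundary conditions — within
   `bc_margin` cells of a face the inward velocity component is zeroed
   (slip; a sticky variant zeroes everything).
3. **Grid to particle** (`g2p()`): velocities and a fresh affine matrix
   $C = \tfrac{4}{\Delta x^2}\sum_i \omega_{ip}\, v_i (x_i-x_p)^T$ are
   interpolated back; fixed particles receive their prescribed velocity
   instead (particle-level Dirichlet constraints).
4. **Collide and finalize** (`collide()`, `finalize_frame()`): the clamp
   resolves particle positions; velocities follow from positions,
   $v_p = (x_p^{n+1}-x_p^n)/\Delta t$; the per-particle velocity increment
   $\Delta v_p = v_p - \tilde v_p$ is scattered back to the grid
   ($\Delta v_i = \tfrac{1}{m_i}\sum_p \omega_{ip} m_p \Delta v_p$) for the
   next frame's step 1, and the haptic output force is
   $\sum_p -m_p \Delta v_p / \Delta t$.

The $4/\Delta x^2$ factors are the inverse inertia tensor of the quadratic
B-spline kernel and are fixed, not configurable. The affine term in the
momentum scatter uses the pre-increment $C^n$, matching the combined
momentum-update form; only the gradient update uses $C + \Delta C$.

Numerical guards: volume candidates are clamped to $\ge 10^{-6}$ before
logarithms; a deformation update that would produce $\det F \le 0$ aborts
the frame with the particle index; a CFL warning fires once per run if
$\Delta t\,\max|v| > \Delta x/2$.

### The clamp

The tool is two cubic collision boxes at $\pm$`opening` along the jaw axis
of a rigid clamp frame. Capture and release rules are not dictated by the
physics and were designed to match surgical clamping semantics: particles
inside a box while the jaws are closed (`opening <= closed_threshold`) are
captured, storing their clamp-frame coordinates; while captured they are
carried rigidly (position = pose applied to stored coordinates, exact to
machine precision); opening the jaws releases them at their proposed
position. Open jaws push penetrating particles to the nearest box face so
the tool can probe without gripping. Captured particles keep scattering
mass, momentum and stress to the grid — the gripped tissue stays coupled to
its neighborhood, which is what makes drag forces and tearing-by-pulling
work.

## The synthetic specimen and the experiments

`make_slab()` samples a rectangular thin slab on a particle lattice
(optionally jittered) with per-particle mass chosen so total mass equals
`density × volume` exactly. Default scales: a 100 mm × 10 mm slab on a 2 mm
grid with 16 particles per cell (4,000 particles), density 1040 kg/m³,
E = 10 kPa, ν = 0.4 — soft-tissue orders of magnitude; no quantitative match
to any real NP measurement is claimed. The wave speed is
$c = \sqrt{(\lambda_0 + 2\mu_0)/\rho} \approx 4.5$ m/s, which sets
$\Delta t = 10^{-4}$ s (CFL number ≈ 0.23 on the 2 mm grid).

Observables: engineering strain is the elongation of the particle bounding
extent along the pull axis relative to its initial value; engineering
stress is the rest-volume-weighted mean of the axial first Piola–Kirchhoff
component over the whole specimen. The whole-specimen mean was chosen after
observing that plastic zones localize at the grip edges: a narrow central
gauge band can miss all plastic activity and then shows no relaxation
signal at all.

### Quasi-static protocol choices

An explicit, undamped integrator rings: a suddenly applied load or a
velocity jump excites elastic waves of relative amplitude
$\rho c u / \sigma$ that never decay, which would bury the smooth
characterization curves. Three standard experimental-protocol devices keep
the runs quasi-static, all documented and configurable:

* **Grid damping** (dynamic relaxation): grid velocities are multiplied by
  $1-$`damping` each frame (tear/relaxation ramps 0.005, creep 0.02). This
  adds an effective drag; at the default pull rates the resulting stress
  bias is a roughly constant offset over the run, visible as a nonzero
  intercept of the stress–strain fit but not as curvature.
* **Soft start**: prescribed velocities and applied loads ramp linearly over
  0.02 s instead of jumping.
* **Static hold** (relaxation only, `hold_mode = "static"`): once the ramp
  reaches the target strain the deformation field is frozen and only the
  constitutive recursion advances. This realizes "the strain is then
  maintained" exactly and isolates the viscoelastic decay from inertial
  ringing; a `"dynamic"` hold (ends pinned, full stepping) is available for
  comparison.

### What the experiments show — and what they cannot

The model is a *threshold* material: plastic flow begins only where the
elastic volume candidate exceeds $1+\theta_S$, and the hardening exponent
then softens the flowing region, so flow localizes and runs away rather
than settling into steady secondary creep. Consequently:

* **Tear** (`run_tear()`, 0.2 m/s): the full four-stage curve — linear
  elastic rise, nonlinear plateau with onset of flow, tearing with stress
  oscillation, and collapse to ~0 after separation. The stage detector
  (`segment_stages()`) turns the qualitative stage descriptions into
  operational thresholds: departure from the initial linear fit by >5%
  relative residual (with a 1%-of-peak absolute floor), last point within
  99.5% of the peak, first point below 10% of the peak. The first ~0.01 of
  strain is a stress-transmission foot (the gauge-mean stress lags the end
  displacement in an overdamped run) and is excluded from the linearity
  window, which is taken as strain in $[0.1, 0.5]\times\theta_S$.
* **Creep** (`run_creep()`, 500 Pa ≈ 55% of the tear strength, 0.3 s): the
  strain rises quickly and decelerates toward the elastic equilibrium, with
  slow plastic flow at the grip-edge stress concentrations. Holding the
  load near or beyond the tear strength instead produces tertiary,
  accelerating creep ending in necking failure — real behavior of the
  model, but outside a creep characterization window, which is why the
  default load is well below threshold.
* **Relaxation** (`run_relaxation()`, hold at strain 0.105): the held
  configuration must contain material beyond the volume limit for any decay
  to occur. Under plane strain at ν = 0.4 the volume ratio grows only as
  $J \approx 1 + \varepsilon/3$, so a homogeneous specimen would need ~30%
  strain to cross $1+\theta_S$ — beyond its tearing point. In practice the
  grip-edge concentrations cross the limit at 9–11% extent strain, giving a
  window (found by a ramp sweep, documented here, fixed once) where the
  hold decays without tearing. The single-element recursion is the exact
  oracle: excess decays by precisely $(1-k_s)$ per frame.

A green test therefore establishes the qualitative shapes and the exact
constitutive recursion — not quantitative agreement with any measured NP
data, which the package does not attempt.

## Numerical and design notes

* Transfers scatter through `rowsum` over precomputed stencil indices:
  accumulation order is fixed, so runs are bit-reproducible on one thread
  (the determinism test compares full trajectories and output CSV bytes).
* Grid mass equals particle mass after `p2g` up to floating-point rounding
  of the partition of unity (relative ~1e-16; tested at 1e-12).
* Inactive nodes are those with mass below $10^{-12}\times$ the mean
  particle mass; they take no part in the velocity update.
* Gravity is off by default — the clamping scenario is dominated by tool
  and elastic forces, and body forces would only add a constant sag.
* Frame 0 uses a zero grid velocity-increment field (there is no previous
  frame).
* The configuration is TOML; the reader supports the subset the
  configuration needs (tables, scalars, flat arrays) and warns on unknown
  keys. Curves export as CSV, particle clouds as legacy ASCII VTK, run
  manifests as JSON recording config, seed and outputs — enough to replay
  any run exactly.

## Limitations

Isotropic constitutive response only (no fibers, no anisotropy, no
temperature); plasticity is purely volumetric by construction of the split;
`k_c`/`k_s` are frame-rate-bound; explicit integration limits the stable
time step; the 2-D default is plane strain, and 3-D runs, while supported,
are an order of magnitude slower at equal resolution; the haptic force is
reported raw per frame with no device-side filtering.
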