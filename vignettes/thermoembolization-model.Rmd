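---
title: "Methods: 1D network modeling of transarterial thermoembolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1D network modeling of transarterial thermoembolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `vasctherm`, its
assumptions, the numerical choices behind the solvers, the design of the
synthetic fixtures, and the limits of what the test suite demonstrates.

## The physical model

Thermoembolization delivers dichloroacetyl chloride (DCACl) dissolved in
Lipiodol through a microcatheter into a hepatic artery branch. DCACl
hydrolyzes exothermically on contact with aqueous blood, so the bolus
simultaneously occludes vessels and injures the vessel wall and
surrounding tissue. The package models the intravascular part of this
process in one dimension along a segmented arterial tree.

Three simplifications define the model class:

1. **Static Hagen-Poiseuille flow.** Blood is Newtonian with viscosity
   μ = 8.9×10⁻⁴ Pa·s; each branch is a rigid cylinder; flow is steady and
   laminar. The flow field is solved once and is not updated as the bolus
   occludes vessels — embolization feedback on the flow is out of scope.
2. **Miscible single-velocity transport.** The bolus is treated as a
   homogeneous mixture advected passively at the blood velocity. In
   reality the oily bolus forms immiscible droplets; droplet dynamics,
   viscosity feedback and two-phase effects are not modeled.
3. **Lumped downstream beds.** Everything distal to a terminal node is a
   single hydraulic conductance γ_a/μ draining to central venous pressure.
   One scalar γ_a is shared by all terminals; per-terminal conductances
   would not be identifiable from a single perfusion number.

The node-balance system is symmetric positive definite once the Dirichlet
row (root pressure) is eliminated, so pressures obey a discrete maximum
principle: every nodal pressure lies between the venous sink pressure and
the arterial root pressure. The tests assert this on random graphs
alongside agreement with an independently assembled dense solve.

Although the input trees normally are trees, the solver only requires a
connected graph with one root: cycles that survive 26-connectivity
skeletonization are retained, and the linear system remains well posed.

## Parameters

| Symbol | Meaning | Default | Units |
|---|---|---|---|
| P_MAP | root (mean arterial) pressure | 100 | mmHg |
| P_CVP | sink (central venous) pressure | 5 | mmHg |
| μ | blood viscosity | 8.9×10⁻⁴ | Pa·s |
| γ_a | terminal conductance parameter | calibrated | m³ |
| ε | DCACl volume fraction of bolus | 0.1919 | — |
| ρ_DCACl, ρ_o | DCACl / bolus density | 1532, 1280 | kg/m³ |
| ρ_b, c_p,b | blood density / specific heat | 1045, 3600 | kg/m³, J/(kg·K) |
| h | hydrolysis enthalpy | 1.38×10⁵ | J/mol |
| W | DCACl molar mass | 0.147 | kg/mol |
| γ_t | hydrolysis time constant | calibrated | 1/s |
| δ | damage threshold for tagging | 0.01 | — |

The molar mass default is chosen for internal consistency: a 2 M bolus
gives ε = M·W/ρ_DCACl = 2000 × 0.147 / 1532 = 0.1919, exactly the tabulated
saturation. The effective first-order decay rate of saturation is
λ = γ_t ε ρ_DCACl/ρ_o ≈ 0.23 γ_t, so γ_t ≈ 13–14 1/s corresponds to a
hydrolysis timescale 1/λ of roughly a third of a second.

Units at every interface are clinical (mmHg, mm, mL/min, µL); all internal
physics is SI, with the conversions centralized (1 mmHg = 133.322 Pa).

## Calibration

**Terminal conductance.** Total perfusion is strictly increasing in γ_a
and saturates at a network-limited maximum, so the squared-error objective
|q_calc(γ_a) − q_ref|² has a unique minimizer whenever q_ref is below that
asymptote (targets above it raise an error that reports the asymptotic
perfusion). Optimization runs on log10(γ_a) — enforcing positivity and
giving scale-free steps — with Nelder-Mead at absolute tolerance 10⁻¹⁶,
preceded by a decade-coarse bracketing scan so the simplex starts in the
right order of magnitude. A monotone bisection implemented independently
in the test helpers serves as the cross-check oracle; with one unknown,
Nelder-Mead is retained as the primary method for methodological fidelity.

**Hydrolysis time constant.** The objective g(γ_t, δ) = β + (1 − α) mixes
a smooth term (the escaped fraction β) with a piecewise-constant term (the
balanced accuracy α jumps when a node's damage crosses δ). Plateaus and
local minima are real features of this landscape, which is why calibration
draws 10 random starts uniformly in (10, 20) 1/s from a single seeded
generator and keeps every start's trajectory for audit. Objective values
are memoized per γ_t within a calibration run; the simulation is
deterministic, so this changes nothing but runtime.

## Transport discretization

The advection–reaction equation is discretized with a backward Euler
upwind scheme on the graph. Each node owns half of every incident branch
cylinder (ΔV_x = Σ πR²L/2); edges are oriented by the sign of the solved
flow; each node receives flux-weighted upstream saturation at the new time
level, loses its advective outflux, and decays at rate λ. The update
matrix is constant in time, so it is LU-factorized once and each step is a
pair of triangular solves.

Numerical choices, and why:

- **Time step** Δt = 0.5 × min(L/|u|) over flowing edges. The implicit
  scheme is unconditionally stable; the Courant-like factor 0.5 limits
  numerical diffusion. Halving Δt changes total damage by under 1% on the
  pipe benchmark (first-order convergence, asserted in the tests).
- **Injection model.** The treatment record specifies only an injected
  volume, not a rate, so the inlet is saturated (s_o = 1) for T_inj = V_injected /
  q_root — the pure bolus briefly displaces blood at the catheterized
  inlet — then reverts to 0. The per-step inlet duty cycle is computed as
  the exact overlap of the step with [0, T_inj], so the injected volume is
  exact to machine precision.
- **Conservation.** The discrete update telescopes exactly:
  injected = reacted + escaped + residual at every step, and the suite
  asserts closure to 10⁻⁶ (observed: machine precision). The scheme is
  positivity-preserving and bounded by the inlet saturation, so
  0 ≤ s_o ≤ 1 throughout.
- **Stopping.** Time stepping ends when the bolus volume remaining in the
  network falls below 10⁻⁶ of the injected volume (after injection ends),
  with a 10⁶-step cap that warns and reports the residual. A stagnant
  flow field (no outflow to advect into) is an error, as is an all-zero
  centerline or a root that is not a degree-1 node.
- **Steady benchmark.** On a uniform pipe the discrete steady profile is
  Π(1 + λΔx/u)⁻¹, which converges to exp(−λx/u); the tests verify 1%
  agreement at the default resolution.

### The temperature equation

The energy balance mirrors the saturation equation with source
h ε γ_t ρ_DCACl / (W ρ_b c_p,b) · s_o, using blood density and specific
heat for the carrier continuum (the carrier phase is not specified at the
equation level; blood is the natural choice and is recorded as such).
Temperature is tracked as a rise above baseline with no conduction,
perfusion cooling, or tissue coupling.

Under the saturated-plug injection model this source is large: ≈ 950 K/s
per unit saturation at γ_t = 14. A plug parcel that stays saturated for
tens of milliseconds therefore heats by tens of kelvin, and the reported
peak ΔT on the desk-scale fixtures is of order 10²–10³ K. This is an
upper bound with every mitigating mechanism switched off — no dilution of
the bolus at the catheter tip, no heat conduction into tissue, no
perfusion cooling, and a network whose volume is commensurate with the
bolus. It should be read as "the reaction enthalpy is ample", not as a
prediction of intravascular temperature; in a perfused liver the
observable rise is expected to be orders of magnitude smaller. The tests
therefore assert the structural properties of the temperature solution
(non-negativity, exact linearity in h, zero without reaction) rather than
a magnitude.

## Synthetic fixtures

The generator rasterizes a planar H-fractal binary tree into a voxel grid:
trunk radius 1.5 mm, Murray's-law radii (r_parent^m = 2 r_child^m, m = 3),
per-generation length shrink 0.65, isotropic 0.5 mm voxels, depth 5 by
default (32 terminals, ~400–500 nodes). Two seeded asymmetries make the
fixture realistic and the reaction parameter identifiable:

- branch lengths are jittered by ±20%, and
- the Murray flow split is drawn from U(0.38, 0.62) rather than fixed at
  one half.

A perfectly symmetric tree gives every root-to-tip path the same transit
time, so the damage pattern barely changes over a wide range of γ_t and
the observed labels carry almost no information about it — a degenerate,
unrealistic special case. With asymmetry, path transit times vary, the
tagged boundary moves smoothly with γ_t, and forward-simulated labels pin
the generating value. The rasterizer verifies the rebuilt graph has
exactly 2^depth terminals and raises a collision error otherwise.

**Perfusion scaling.** A ~500-node tree stands for a small subtree of the
hepatic arterial bed, not a whole liver, so the synthetic subject carries
`perfusion_scale` (default 0.04) of the weight-derived whole-liver
reference flow. The default puts the bolus transit time through the tree
on the scale of seconds, commensurate with the hydrolysis timescale
1/λ ≈ 0.3 s — the operating regime of the therapy, in which most of the
bolus reacts inside the segmented network (escaped fraction near zero at
the optimum) and the damage boundary falls inside the tree. At whole-organ
flows the same small tree would flush the bolus in well under a
reaction time, which represents a mis-scaled geometry rather than the
treatment regime.

What passing tests on these fixtures do **not** show: performance on real
segmentations with gaps and missed branches (observed in vivo to produce
false negatives), immiscible-droplet behaviour, or accuracy of the
absolute temperature scale. They do show that every algorithmic component
— graph building, the flow solver against a dense oracle, conservation,
calibration against bisection, parameter recovery from forward-simulated
labels, and the grid/cross-validation machinery — behaves as designed.

## Experiment design choices

- **Confusion matrix node set**: all graph nodes except the root, which
  trivially reacts at the injection site. Ratios with a zero denominator
  (e.g. precision with no predicted positives) are reported as missing and
  excluded from averages rather than coerced to zero.
- **Uncertainty grid**: perfusion values evenly spaced over the subject's
  reference band, endpoints included; thresholds 1%…10% in steps of 1%.
  Each cell calibrates γ_a to its perfusion before calibrating γ_t; cell
  failures are recorded and the grid continues. Cells are pure functions
  of their inputs and a per-cell derived seed, so grids are reproducible.
- **Cross-validation aggregation**: the held-out subject's γ_t is the
  arithmetic mean of the remaining subjects' optima — the simplest rule
  consistent with the published per-subject values.
- **Component tie-breaks**: equal-size components select the one holding
  the smallest linear voxel index; builds are bit-reproducible.
- **Root choice**: by default the degree-1 node with the largest radius
  (anatomically, the feeding artery is the widest vessel end); a voxel
  coordinate can override this when the catheterized end is known.
- **Edge radius**: arithmetic mean of the endpoint node radii — symmetric,
  order-independent, and exact for linear tapers.

## Problem sizes

The shipped suite exercises: random graphs up to 50 nodes against dense
oracles (20+ instances), a 400-node pipe for the analytic profile, the
depth-5 (~400-node) fixture for calibration and recovery (10 starts × 5
seeds), a 3×3 uncertainty grid, and three-subject cross-validation. These
sizes were chosen so the full suite runs in minutes on one core while
still covering every code path at physically meaningful operating points;
all of them scale up by changing `tree_spec()` / grid arguments.

## Known limitations

- No embolization feedback: the flow field never reacts to the predicted
  occlusions, so late-time damage in heavily embolized trees is
  overestimated.
- Miscible transport: droplet-scale physics, delayed hydrolysis initiation
  at droplet surfaces, and bolus viscosity effects are absent.
- The temperature equation has no losses (see above).
- Observed-label mapping is nearest-voxel: no dilation or tolerance for
  small registration errors between centerline and post-treatment mask.
- Radius values are taken from the centerline voxel values and must be in
  millimetres; the package does not attempt to detect voxel-unit radii.
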