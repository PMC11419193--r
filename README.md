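# vasctherm

1D vascular-network modeling of transarterial **thermoembolization** — a
minimally invasive liver-cancer therapy in which a bolus of dichloroacetyl
chloride (DCACl) dissolved in ethiodized oil (Lipiodol) is injected into the
hepatic artery, where its exothermic hydrolysis simultaneously embolizes the
vessel and chemically ablates the surrounding tissue.

The package is aimed at researchers in computational interventional
radiology who want to predict *where* in a segmented arterial tree the
injected bolus will react, and therefore where embolization is likely to
occur, from routine CT-derived vessel centerlines.

## The model

**Geometry.** A vessel-centerline NIfTI volume (nonzero voxels on the
centerline, voxel value = local radius in mm) is converted into a graph:
every centerline voxel is a pressure node, 26-neighbourhood voxel pairs are
branch segments, and the largest connected component is kept. Degree-1
nodes are the pressurized **root** (the catheterized inlet) and the
**terminal** outflow nodes.

**Hemodynamics.** Steady laminar flow on each branch follows
Hagen-Poiseuille,

    q_ij = k_ij (P_i − P_j),    k_ij = π R_ij⁴ / (8 μ L_ij),

with mass balance Σ_j q_ij = 0 at interior nodes, P_root = P_MAP
(100 mmHg), and a lumped outflow condition at every terminal node,

    Σ_j k_ij (P_i − P_j) + (γ_a/μ)(P_CVP − P_i) = 0,

where γ_a/μ is the hydraulic conductance of the unsegmented downstream bed
draining to central venous pressure (5 mmHg). The single free parameter
γ_a is calibrated so that total simulated perfusion matches a
weight-derived reference: porcine liver weight is 2.04% ± 0.33% of body
weight and regional hepatic flow is 22.28 mL/min per 100 g liver.

**Transport and reaction.** The bolus saturation s_o is advected passively
on the solved flow field and consumed by first-order hydrolysis,

    ∂s_o/∂t + ∂(u s_o)/∂x = −γ_t ε (ρ_DCACl/ρ_o) s_o,

discretized with a backward Euler upwind scheme on the graph (ε = 0.1919 is
the DCACl volume fraction of a 2 M bolus). A matching energy equation
tracks the temperature rise of the exothermic reaction. The cumulative
reacted fraction at node x,

    D_x = (1/V_DCACl) γ_t ε (ρ_DCACl/ρ_o) Σ_t s_o(x,t) Δt ΔV_x,

is the damage score; nodes with D_x ≥ δ are tagged as predicted
embolization sites, and β is the fraction of bolus escaping the network
unreacted. The hydrolysis time constant γ_t (1/s) is calibrated by
multi-start Nelder-Mead minimization of

    g(γ_t, δ) = β(γ_t) + (1 − α(γ_t, δ)),

where α is the balanced accuracy of the tagged sites against observed
post-treatment Lipiodol labels. Uncertainty grids over (q_ref, δ), Pearson
correlation summaries and leave-one-out cross-validation across subjects
round out the analysis, and a synthetic bifurcating-tree generator
(Murray's-law radii, seeded asymmetry, forward-simulated observation
masks) makes the whole pipeline testable without animal data.

## Worked example

```r
library(vasctherm)

# synthetic depth-3 arterial tree, rasterized and rebuilt from voxels
tree <- make_tree(tree_spec(depth = 3, segment_length = 12))
g <- build_vessel_graph(tree$volume)
g
#> vessel_graph: 154 nodes, 167 edges
#>   roles: 1 root, 145 interior, 8 terminal

reference_perfusion(weight_kg = 54)
#> perfusion_reference: 54 kg -> q_ref 205.73 / 245.44 / 285.14 mL/min (min/mean/max)

# calibrate the terminal conductance to a 10 mL/min subtree target
cal <- calibrate_gamma_a(g, flow_params(), q_ref = 10)
cal
#> gamma_a_calibration: gamma_a = 1.46424e-15, q_calc = 10.0000 mL/min
#>   (target 10.0000, rel. residual 1.2e-09)

sol <- solve_pressures(g, flow_params(gamma_a = cal$gamma_a))
res <- simulate_transport(g, sol, bolus_params(gamma_t = 14, v_dcacl_ul = 200))
res
#> transport_result: 350 steps (dt = 0.0106 s, t_end = 3.71 s)
#>   reacted 0.9950, escaped (beta) 0.0050, residual 9.7e-07; max dT = 310 K

sum(tag_embolization(res, delta = 0.01)$tagged)
#> 27
```

Reading the numbers: 99.5% of the injected 200 µL bolus hydrolyzes inside
the segmented tree (β = 0.005 escapes), mass is conserved to the stopping
tolerance, and 27 of 154 vascular elements accumulate at least 1% of the
total reacted bolus — the predicted embolization sites. The temperature
rise is that of the undiluted saturated plug with no heat losses; see the
methods vignette for why this upper bound is far above what a perfused
liver would see.

A command-line front-end over the same functions ships with the package
(`system.file("cli", "vasctherm", package = "vasctherm")`) with
subcommands `synth`, `build-graph`, `flow`, `calibrate-flow`, `simulate`,
`calibrate-reaction` and `uncertainty`.

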