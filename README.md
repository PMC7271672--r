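# dceflow

Non-invasive estimation of tumor **interstitial fluid pressure (IFP)** and
**interstitial fluid velocity (IFV)** from dynamic contrast-enhanced
(DCE) MRI, with the group statistics used to relate those maps to
radiotherapy response. The package is aimed at quantitative-imaging
researchers who want a fully testable, self-contained implementation of
this modeling chain: every stage can be exercised on synthetic phantoms
with known ground truth, so no patient data are required to validate it.

## What it computes

**1. Pharmacokinetics.** Voxelwise contrast kinetics follow the
two-compartment extended Tofts model (ETM)

    C_t(t) = Ktrans ∫₀ᵗ exp(−k_ep (t−τ)) C_p(τ) dτ + v_p C_p(t),
    k_ep = Ktrans / v_e

with the volume transfer constant `Ktrans` (1/min), EES fraction `v_e`,
plasma fraction `v_p`, and arterial input function `C_p(t)`. Signal is
converted to concentration by exact inversion of the spoiled
gradient-echo steady-state equation, and parameters are fitted by bounded
nonlinear least squares (`Ktrans ∈ [0,5]`, `v_e, v_p ∈ [0,1]`).

**2. Fluid model.** The interstitium is a porous medium: Darcy's law
`u = −K_H ∇p_i` and the steady-state continuity equation

    −K_H ∇²p_i = (Ktrans/⟨Ktrans⟩) · L_p (S/V) (P_eff − p_i)

with lymphatic clearance fixed at zero (brain), tissue-specific
hydraulic conductivity `K_H`, vessel permeability `L_p`, exchange area
`S/V`, and lumped Starling effective pressure `P_eff` (400 Pa normal,
1550 Pa tumor by default). The equation is discretised with a 7-point
finite-volume stencil on a 1 mm isotropic grid (harmonic-mean face
conductivities) and solved with preconditioned conjugate gradients; the
solver is certified against a closed-form two-region radial solution.

**3. Features and statistics.** Per-lesion histogram features of the IFP
(kPa) and IFV (m/s) maps — mean, SD, skewness, Pearson kurtosis — at two
timepoints plus their change Δ, compared between objective-response (OR)
and non-OR lesions with Wilcoxon rank-sum tests and ROC/Youden cutoff
analysis.

A synthetic-data module generates DCE phantoms and paired pre/post
treatment cohorts (default 31 OR / 22 non-OR lesions) with a designed,
configurable response effect, so the whole chain runs end to end from
nothing but a seed.

## Worked example

```r
library(dceflow)
props <- tissue_properties()

# benchmark: 10 mm spherical tumor, 20 mm normal margin, 1 mm grid
dom <- spherical_domain(tumor_radius = 10, margin = 20, spacing = 1)
fld <- solve_ifp(assemble_system(dom, props))
fld
#> IFP field: 61x61x61, max 1499.1 Pa, residual 7.62e-11 (cg, 86 it)
ctr <- (dom$dims + 1) / 2
fld$p[ctr[1], ctr[2], ctr[3]]        # 1499.1 Pa at the center
radial_reference_ifp(0, 0.010, 0.030, props)  # analytic: 1497.4 Pa

# a small synthetic response cohort through the full pipeline
cfg <- pipeline_config(out_dir = "demo_run",
                       cohort = cohort_spec(n_or = 8, n_non_or = 6, seed = 2),
                       pk_mode = "truth", spacing = 2, margin = 10, seed = 2)
mf <- run_pipeline(cfg)
summarize_run(mf)
#> dceflow run (package 0.1.0, seed 2)
#> 14 lesions (non-OR=6, OR=8)
#> failed lesions: 0
#> total failed voxel fits: 0
#> max solver residual: 9.85e-11
#> significant feature rows (of 24): 12

g <- read.csv("demo_run/group_stats.csv")
g[g$significant & g$set == "delta" &
    g$feature %in% c("ifp_kurt", "ifv_mean_mps"),
  c("feature", "mean_non_or", "mean_or", "p")]
#>        feature mean_non_or   mean_or       p
#>       ifp_kurt   -6.90e-02 -6.75e-01 0.00368
#>   ifv_mean_mps   -1.27e-12  1.02e-08 0.00241
```

The two Δ rows show the designed response pattern: responders' IFP
kurtosis falls (histogram flattens as the vascular pattern smooths) while
their mean IFV rises (shrinking lesions have a larger high-velocity rim
fraction); non-responders barely change. The maximum pressure, 1499 Pa,
sits just below the tumor effective pressure (1550 Pa) because a 10 mm
lesion is not much larger than the ~6 mm pressure decay length.

The voxelwise fitting path (`pk_mode = "fit"`) runs the same cohort
through signal synthesis, SPGR inversion, and the ETM fit instead of the
ground-truth maps.

## Layout

- `R/` — protocol/AIF, SPGR signal model, ETM fitting, phantom and cohort
  generators, domain/solver, features, statistics, pipeline.
- `src/` — compiled preconditioned-CG kernel for the 7-point stencil.
- `vignettes/ifp-modeling.Rmd` — methods: model assumptions, parameter
  table, numerics, synthetic-data design, limitations.
- `inst/scripts/dceflow-pipeline.R` — command-line pipeline wrapper.
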