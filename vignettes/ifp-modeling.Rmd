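---
title: "Modeling tumor interstitial fluid pressure and velocity from DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor interstitial fluid pressure and velocity from DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dceflow estimates interstitial fluid pressure (IFP) and interstitial
fluid velocity (IFV) inside brain tumors from dynamic contrast-enhanced
(DCE) MRI, and tests whether histogram features of those maps separate
treatment-response groups. This vignette documents the science and the
numerical choices: the models and their assumptions, the parameters that
matter and their defaults, what the synthetic-data generator does and
does not emulate, and the known limitations.

## 1. Pharmacokinetic stage

### Extended Tofts model

Tissue contrast concentration is modeled with the two-compartment
extended Tofts model (ETM),

$$C_t(t) = K^{trans}\int_0^t e^{-k_{ep}(t-\tau)}\,C_p(\tau)\,d\tau
  + v_p\,C_p(t), \qquad k_{ep} = K^{trans}/v_e,$$

where $K^{trans}$ (1/min) is the volume transfer constant of contrast
agent from plasma into the extravascular extracellular space (EES),
$v_e$ and $v_p$ are the EES and plasma volume fractions, and $C_p(t)$ is
the arterial input function (AIF). The model assumes fast water
exchange, a well-mixed EES, and negligible bolus dispersion between the
AIF measurement site and the tissue.

The convolution is evaluated *exactly for the piecewise-linear
interpolant* of $C_p$ on the acquisition grid, via the per-interval
closed form of $\int e^{-ks}(a+bs)\,ds$ with a series branch for
$k\,\Delta t \to 0$. At a 5–6 s temporal resolution this is noticeably
more accurate near the bolus peak than plain trapezoidal quadrature of
the product, at identical cost, and it makes the forward model an exact
inverse of the fitter's model family. The test suite bounds the residual
error against trapezoidal quadrature on a 10× finer grid evaluated on
the continuous AIF (< 0.5 % relative L2).

### Signal model and inversion

The dynamic acquisition is a spoiled gradient-echo (SPGR) sequence;
its steady-state signal is
$S = M_0 \sin\alpha\,(1-E_1)/(1-\cos\alpha\,E_1)$ with
$E_1 = e^{-TR\,R_1}$ and $R_1(t) = 1/T_{10} + r_1 C(t)$.
`signal_to_concentration()` inverts this exactly: the baseline signal
(mean of the pre-injection phases) fixes the unknown scale
$M_0\sin\alpha$, after which $E_1$ has a closed form. Samples whose
inversion argument leaves $(0,1)$ — possible under strong noise — are
flagged `NA` and counted rather than failing the voxel. Exact inversion
(rather than the linearised small-$\Delta R_1$ approximation) was chosen
so that the synthetic module's forward signal model round-trips to
machine precision, which the tests rely on.

Without a measured T1 map, $T_{10}$ is a single assumed constant; 0.8 s
and 1.0 s are the two conventional choices depending on field strength.
Which value maps to which field strength is exposed as plain
configuration (`acquisition_protocol(T10_default=)`) with no fidelity
claim; the default is 1.0 s. The relaxivity default is
$r_1 = 4.5\,$L/(mmol·s), typical for gadopentetate.

### Fitting

`fit_etm_voxel()` minimises the sum of squared errors with bounded
Levenberg–Marquardt (minpack.lm), bounds $K^{trans}\in[0,5]$ 1/min,
$v_e, v_p \in [0,1]$ (with $v_e \ge 10^{-3}$ so $k_{ep}$ stays defined
during the search), single start at $(0.1, 0.2, 0.05)$ and an optional
three-point multistart flag. Non-convergent voxels are flagged, carry
`sse = Inf`, and are excluded from the downstream $K^{trans}$ field
(background value), with their count logged.

The acceptance suite verifies noiseless self-consistency — median
relative recovery error below 1 % per parameter over a $5^3$ grid
spanning $K^{trans}\in[0.01,1]$ /min, $v_e\in[0.05,0.6]$,
$v_p\in[0.01,0.1]$ — and graceful degradation at SNR 20. Note the
noiseless check certifies the optimizer and quadrature (the data come
from the same model family), not fidelity to any scanner's data.

### AIF

Clinically the AIF is read from a sagittal-sinus voxel;
`extract_aif()` implements that convention with the hematocrit plasma
correction $C_p = C_b/(1-\mathrm{Hct})$, default Hct = 0.45. For
synthetic work a parametric population bolus is used instead: a
difference of exponentials $A\,d\,(e^{-m_1\tau} - e^{-m_2\tau})$ with
defaults $m_1 = 0.008$/s, $m_2 = 0.08$/s, scaled to peak near 5 mM.
The ~30 s rise was chosen to be resolvable at the 5.5 s frame interval,
and the default arrival time coincides with the first post-injection
frame (injection synchronized with a phase start), so the sampled curve
represents the continuous bolus without an inter-sample kink.

## 2. Fluid-model stage

### Continuity equation

The interstitium is treated as a rigid, isotropic porous medium with
incompressible, low-Reynolds-number steady flow, so Darcy's law
$\mathbf u = -K_H \nabla p_i$ holds, and mass balance with a Starling
transvascular source gives

$$-K_H \nabla^2 p_i \;=\;
  \frac{K^{trans}}{\langle K^{trans}\rangle}\,
  L_p \frac{S}{V}\,\bigl(P_{e\!f\!f} - p_i\bigr),$$

where the dimensionless ratio $K^{trans}/\langle K^{trans}\rangle$
(tumor mean in the denominator) modulates the source for heterogeneous
vascular leakiness, and $P_{e\!f\!f}$ lumps the Starling terms
$p_V - \sigma_T(\pi_V - \pi_i)$ into one effective pressure per tissue
class. Lymphatic clearance is identically zero in both tissues (brain).
The equation is linear in $p_i$, of reaction–diffusion type, with
characteristic decay length $\lambda = \sqrt{K_H/(L_p S/V)}$ — about
6.2 mm in tumor and 2.7 mm in normal tissue at the default parameters.

Default physical parameters (per tissue class):

| parameter | units | normal | tumor |
|---|---|---|---|
| $K_H$ interstitial hydraulic conductivity | m²/(Pa·s) | 5.65×10⁻¹⁵ | 4.9×10⁻¹³ |
| $L_p$ vascular hydraulic conductivity | m/(Pa·s)·(scaled with S/V) | 8×10⁻¹⁴ | 6.4×10⁻¹³ |
| $S/V$ vessel exchange area | 1/m | 10 000 | 20 000 |
| $P_{e\!f\!f}$ effective pressure | Pa | 400 | 1 550 |

Individual Starling constants are deliberately not exposed — only the
lumped $P_{e\!f\!f}$, matching how the parameter set is specified.

Two modeling choices were genuinely open and are resolved as follows,
both as configuration with the stated defaults:

* the modulation ratio is defined only where a $K^{trans}$ map exists
  (the tumor VOI); normal tissue uses ratio 1;
* the normal-tissue compartment is *sourced* by default
  ($c = L_p S/V > 0$ with $P_{e\!f\!f} = 400$ Pa) since the parameter
  set provides normal-tissue values; `source_normal_tissue = FALSE`
  switches to a tumor-only source.

### Domain

`build_domain()` reslices the lesion mask to an isotropic grid
(default 1 mm, the working resolution of the whole fluid stage) by
nearest-neighbour sampling and pads it with normal tissue; the Dirichlet
condition $p = 0$ (normal far-field) sits on the outer voxel shell. The
default margin is 20 mm: the normal-tissue decay length is 2.7 mm, so
the boundary is ~7 decay lengths from the tumor, and the solver tests
include a margin-doubling check on the central pressure. A margin below
2 voxels is rejected.

### Discretisation and solver

The equation is discretised with a cell-centred 7-point finite-volume
stencil; face conductivities are harmonic means of the adjacent cell
$K_H$ values, the standard flux-continuous treatment of the
tumor/normal discontinuity. Rows are scaled per unit volume, so an
interior row in homogeneous tissue reads
$\sum_f K_H/h^2 (p_i - p_j) + c\,p_i = c\,P_{e\!f\!f}$. Dirichlet cells
are eliminated into the right-hand side, leaving a symmetric positive
definite system solved by Jacobi-preconditioned conjugate gradients
(compiled, matrix-free on the stencil) to a relative residual of
1e-10; a direct sparse path (`method = "direct"`) exists for
cross-checks and is verified against a dense solve on a 6³ domain to
1e-9.

For the *spherical benchmark domains* the exact geometry is known, and
`spherical_domain()` passes it to the assembler, which then applies
embedded-boundary corrections: face conductivities use the
distance-weighted harmonic mean at the exact sphere crossing, cells cut
by the tumor surface get volume-fraction-mixed reaction/source
coefficients (6³ subcell sampling), and links crossing the spherical
outer boundary are shortened to the exact boundary distance. Without
these corrections the staircase representation of the sphere limits
convergence to first order; with them the solver converges at second
order against the analytic reference, which is what the grid-convergence
acceptance test asserts (error ratio ≈ 4 per spacing halving, < 3 %
relative L2 at 1 mm). Patient-style masks have no sub-voxel truth — the
voxelized mask *is* the geometry — so the pipeline path uses the plain
staircase assembly.

The analytic reference itself (`radial_reference_ifp()`) is the
closed-form two-region radial solution
$p = P_{e\!f\!f} + (A \sinh(r/\lambda) + B\cosh(r/\lambda))/r$ with
regularity at the origin, pressure and flux continuity at the interface,
and the outer Dirichlet condition; the normal region uses a scaled
decaying-exponential basis for conditioning. It is validated in the test
suite against an independent ODE shooting solution (deSolve).

Invariants asserted by the tests: discrete maximum principle
($0 \le p \le \max P_{e\!f\!f}$), exact balance between the integrated
transvascular source and the boundary outflux (to 1e-8 relative, a
divergence-theorem identity of the scheme), linearity of $p$ in
$P_{e\!f\!f}$, and the large-tumor asymptote $p(0) \to P_{e\!f\!f}$
(verified at radius 50 mm ≫ λ, where the center value reaches 1550 Pa
within 1 %).

### Velocity

`compute_ifv()` applies Darcy's law with central differences (one-sided
at array faces) and the voxelwise $K_H$. On a linear pressure field the
result is exact; on the spherical phantom the flow is radial/outward
with its magnitude peaking in a shell at the tumor rim, both asserted in
the tests. IFP maps are stored in Pa and converted to kPa only in
feature tables; IFV is reported as the magnitude in m/s.

A consequence of the default parameters worth knowing: because normal
tissue conducts ~90× worse than tumor, the tumor interior is nearly
isobaric just below $P_{e\!f\!f}$, with the entire pressure drop
concentrated in a ~3 mm normal-tissue boundary layer. Intratumoral IFP
variation is therefore small in absolute terms (tens of Pa), and the
shape statistics below operate on that fine structure; the IFV map is
dominated by the high-velocity rim.

## 3. Features

`histogram_stats()` uses population (n-denominator) moments: mean,
$\sqrt{m_2}$, Fisher–Pearson skewness $g_1 = m_3/m_2^{3/2}$, and
**Pearson (non-excess) kurtosis** $m_4/m_2^2$ (normal → 3); an excess
flag is available. The non-excess convention was chosen because the
reported kurtosis values in this literature cluster near 3. Constant
samples have undefined shape statistics and return `NA`, which
propagates through Δ.

`lesion_features()` implements both readings of "an average value
computed across multiple slices": the default `per_slice_mean` computes
each statistic per axial slice (slices with ≥ `min_slice_voxels` = 8
tumor voxels) and averages the statistics across slices, following the
literal sentence; `whole_voi` pools voxels. They coincide on
single-slice lesions (asserted). If no slice qualifies the function
falls back to `whole_voi` with a warning. Δ features are exactly
post − pre.

## 4. Statistics

`wilcoxon_ranksum()` wraps the standard two-sided rank-sum test with an
explicit selection rule: exact enumeration when the pooled sample is
≤ 12 with no ties, otherwise the normal approximation with tie and
continuity corrections. (At the default cohort sizes, 31 vs 22, the
approximation branch is always taken; the exact branch is verified
against full enumeration in the tests.) No multiple-testing correction
is applied by default, matching univariate reporting conventions; a
Benjamini–Hochberg flag exists.

`roc_youden()` reports the directional Mann–Whitney AUC (probability
that a positive case scores higher, ties half-weighted) and scans all
midpoint cutoffs in both directions for the maximal Youden index
$J = \text{sens} + \text{spec} - 1$; ties in $J$ break toward higher
sensitivity, because the operating points of interest are
high-sensitivity detection of non-response. The positive class is
non-OR. `group_comparison()` produces the 24-row table (8 features × 3
timepoint sets) with group means, p-values, significance flags at
α = 0.05, and ROC columns for significant rows.

## 5. Synthetic data: what it emulates and what it does not

The generator reproduces the *structure* of the study data: SPGR DCE
series with 10 pre-injection + 30 dynamic phases at 5.5 s resolution and
5 mm-class slices; ellipsoidal lesions of realistic size (default 8 mm
radii) with spatially correlated $K^{trans}$ fields (Gaussian random
field: white noise smoothed at a 2 mm correlation length, standardised
to the requested tumor mean 0.25 /min and SD 0.12 /min, clipped to
[0, 5]); uniform $v_e$, $v_p$; additive Gaussian noise on the magnitude
signal (Rician optional); and paired pre/post cohorts of 31 OR + 22
non-OR lesions. A lesion's vascular pattern persists across timepoints
(shared field seed) with a configurable session-remodelling weight
(default 0.2), and lesion radii vary log-normally (SD 0.1) within the
cohort.

The designed response effect, all magnitudes configurable
(`or_response_spec()`):

* **smoothing** — post-OR $K^{trans}$ spatial SD × 0.15, modeling the
  loss of microvascular heterogeneity after necrosis. Through the fluid
  model, heterogeneity is what lifts IFP kurtosis above its geometric
  baseline (~2 for a near-isobaric ellipsoid with a rim tail), so
  smoothing lowers kurtosis — the responder pattern;
* **shrinkage** — radii × 0.75, since objective response is by
  definition size reduction. Smaller lesions have a larger rim fraction,
  which raises the tumor-mean IFV;
* **core** — a mild concentric low-$K^{trans}$ core (radius fraction
  0.5, factor 0.5), central devascularisation. Its effect on the
  pressure field is small at these parameters (the tumor plateau is
  propped by conduction) and it is kept mainly for realism.

Non-OR lesions reuse the pre-treatment template, so their Δ features
scatter around zero through session remodelling alone. These choices
were fixed from deterministic single-lesion mechanism studies (direction
and rough magnitude of each knob's effect through the solver) before the
cohort-level acceptance experiment, and the 20-seed end-to-end test then
verifies that the designed ΔIFV-mean increase and ΔIFP-kurtosis decrease
for responders are recovered as significant with the designed ordering.

Not emulated: motion, B1/flip-angle error, slice profile, partial
volume at the lesion rim, bolus dispersion or patient-specific AIFs,
T1-mapping, DICOM. Passing tests therefore certify the computational
chain under its own assumptions — not robustness to scanner physics the
generator does not model. In particular, real VOIs that include rim
voxels across the steep peritumoral pressure drop would show much larger
IFP spread than these phantoms.

## 6. Problem sizes and runtimes

The shipped tests run at deliberately modest sizes: radial certification
at 1 mm and 0.5 mm spacing (61³ and 121³ grids), the asymptote phantom
at 2 mm (101³), cohort experiments with 14×14×7-voxel phantoms resliced
at 2 mm with a 10 mm margin, and 20 cohort seeds in the effect-recovery
experiment, with ground-truth maps feeding the fluid stage there (the
fitting stage is certified separately; at ~12 k voxel fits per cohort it
is the one stage whose cost scales far faster than its incremental
evidence). The full voxelwise-fit path is exercised end to end on a
two-lesion cohort and checked to agree with the ground-truth path.

## 7. Known limitations

* The tissue parameter set is literature-derived and untuned; absolute
  IFP/IFV values inherit its uncertainty, and the velocity magnitude at
  the rim depends on which side's $K_H$ multiplies the smeared
  interface gradient (central differences straddle the discontinuity).
* Real lesion masks get the staircase discretisation; the second-order
  embedded corrections apply only to the analytic benchmark geometry.
* The steady-state model ignores poroelasticity, solid stress, and any
  time dependence; the zero-lymphatics assumption is brain-specific.
* Exact SPGR inversion assumes a clean baseline and the assumed
  $T_{10}$; voxels violating it are flagged rather than corrected.
* The ETM fit uses a single AIF for the whole volume and no
  bolus-arrival fitting or model selection.
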