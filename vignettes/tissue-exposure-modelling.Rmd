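---
title: "Modelling layered soft-tissue indentation and tissue exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling layered soft-tissue indentation and tissue exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueload)
```

`tissueload` answers a comparative question: when a small circular device
presses on skin with a clinically plausible pressure (2–10 kPa), how do
anatomy and tissue stiffness decide *which* tissue layer absorbs the
mechanical burden, and how much of its volume is pushed into the upper
tail of its stress or strain distribution? This vignette records the
model, the numerical method, and every place where the design was
genuinely open — together with what the shipped defaults do and do not
represent.

## 1. The mechanical model

### Geometry

The tissue is an axisymmetric layered cylinder: epidermis, dermis,
adipose, skeletal muscle, and bone, from the surface (z = 0, z increasing
downward) to a fully fixed base. The domain radius is 60 mm — the
half-width of the 120 mm × 120 mm footprint the stack idealizes — and the
load is a 10-mm-diameter circular patch on the axis. A region of interest
(ROI), a 30-mm-diameter cylinder through the soft layers, is where all
summary metrics are computed.

Two built-in parameterizations represent distinct adult anatomical
profiles:

| layer     | t (mm) m1 / m2 | E (kPa) m1 / m2 | ν    |
|-----------|----------------|-----------------|------|
| epidermis | 0.1 / 0.07     | 1500            | 0.48 |
| dermis    | 1.5 / 0.8      | 35              | 0.48 |
| adipose   | 4.4 / 3        | 2               | 0.48 |
| muscle    | 6.6            | 2 / 1           | 0.48 |
| bone      | 5              | 6480            | 0.33 |

These defaults come from a source table whose layout is ambiguous in
places (run-together columns); the shipped values are a documented
best-effort reading, and **every number is a configuration key** —
`write_config()` / `load_config()` round-trip a YAML file in which any
thickness or modulus can be overridden. One consequence of this ambiguity
is discussed in §6: the absolute deep-tissue stress level scales roughly
with the adipose/muscle shear moduli, so analyses that depend on absolute
(rather than percentile-normalized) deep-layer stresses should treat
those moduli as the dominant uncertainty.

### Constitutive law

All soft tissues are compressible Neo-Hookean,

$$W = \tfrac{\mu}{2}(I_1 - 3) - \mu \ln J + \tfrac{\lambda}{2}(\ln J)^2,$$

with $\lambda,\mu$ from each layer's $(E, \nu)$. $\nu = 0.48$ puts
$\lambda/\mu = 24$: near-incompressible, which drives both the element
technology (§2) and the characteristic pattern of results (deviatoric
strain concentrates in compliant layers while volumetric stiffness
transmits pressure).

Viscoelasticity is available as a normalized Prony relaxation
$g(t) = 1 - \sum_i \gamma_i (1 - e^{-t/\tau_i})$, monotone from $g(0)=1$
to $1-\sum\gamma_i$. Two open points were settled here: (i) the relaxing
normalized form is implemented — a relaxation modulus must decay from 1,
and the stated "short- and long-term relaxation time constants" only make
sense in this form; (ii) because no tissue-specific $(\gamma_i, \tau_i)$
values are available, the **default analysis is quasi-static**
($g \equiv 1$, instantaneous moduli): the static loading protocol makes
the elastic response the reproducible quantity. Prony terms remain
accepted as configuration inputs for users who have them.

Bone (and the loading electrode, which is not meshed) are flagged
`is_linear`; the solver applies the same Neo-Hookean kinematics to bone,
which is exact to within its negligible strains (peak bone effective
strain in the worked cases is ~2×10⁻⁴).

### Load delivery

The loading electrode is a stiff disc in frictionless contact with the
skin. Two idealizations are implemented:

* **`rigid_punch` (default)** — a flat rigid frictionless disc: all
  surface nodes under the patch share one vertical degree of freedom (a
  multipoint tie keeping the contact face flat), radial sliding is free,
  and the punch carries the total force $p\,\pi a^2$. This matches a
  rigid electrode pressed with the nominal pressure, and was chosen as
  default because the electrode's bulk stiffness (E = 1300 kPa, ~3 orders
  above the underlying fat/muscle) makes it effectively rigid at these
  loads.
* **`traction_patch`** — the nominal pressure applied directly as a
  uniform follower traction (normal to, and integrated over, the deformed
  surface). Without the flattening constraint the thin stiff epidermis
  dimples and stretches more, raising superficial stress by ~10 % in the
  10 kPa cases; deep-layer metrics are nearly identical between modes.

Neither mode models contact separation or re-contact. In the 10 kPa
cases the tied punch face carries compressive nodal forces over its
interior but develops localized tensile tie forces at the edge ring
(of order 15 % of the total force), where a unilateral contact model
would permit slight separation — a known deviation of the tied-face
idealization, concentrated at the singular punch edge. Tangential
friction is zero by protocol.

## 2. Numerical method

**Elements.** Structured, graded meshes of 4-node axisymmetric
quadrilaterals with 2×2 Gauss quadrature. Near-incompressibility makes
fully integrated low-order elements lock volumetrically, so the
volumetric part of the energy, $-\mu\ln J + \tfrac{\lambda}{2}(\ln J)^2$,
is evaluated at the element's volume-averaged $\bar J$ (mean dilatation,
Q1/P0-style), while the $\tfrac{\mu}{2}(I_1-3)$ part is integrated
pointwise. This keeps the discrete residual the exact gradient of a
discrete energy — so the patch test is exact and external work balances
stored energy — and restores the correct compliance at ν = 0.48. The
effective first Piola–Kirchhoff stress is
$P = \mu F + \bar p J F^{-T}$ with
$\bar p = (\lambda \ln\bar J - \mu)/\bar J$, reducing to the pointwise
Neo-Hookean stress for homogeneous deformation.

**Meshing.** Grid lines are placed exactly at the punch edge (r = 5 mm)
and the ROI boundary (r = 15 mm); spacing grows geometrically toward the
far field (axis-adjacent edges are at most half the far-field edge) and
every layer gets at least three elements through its thickness, including
the 0.07-mm epidermis. The resolutions used throughout are `coarse` (238
elements), `medium` (550, the default reporting resolution), and `fine`
(1400); ROI layer means change by ≤ 1.3 % from medium to fine in the
10 kPa reference case, which is the package's mesh-convergence evidence.
Reference element counts of the source 3-D models are carried as layer
metadata only — desk-scale meshes are resolution-controlled, with
convergence checks replacing fixed counts.

**Solution.** Total-Lagrangian Newton iterations inside adaptive load
increments: pseudo-time scales the load from 0 to 1 with initial
increment 0.05, bounds $[10^{-6}, 1]$, at most 1000 increments; an
increment is halved on non-convergence or element inversion and grown
1.5× after two consecutive fast increments. Convergence demands a
residual below $10^{-8}$ of the *gross* (cancellation-free) nodal force
norm, with an absolute floor a few orders above the floating-point noise
of the force sums so that vanishing loads converge cleanly. A
backtracking line search (up to six halvings) stabilizes the strongly
nonlinear punch cases. The consistent tangent is assembled by columnwise
finite differences of the vectorized element kernels — the residual is
exact, so tangent accuracy affects only the convergence rate — and the
reduced system (after Dirichlet elimination and the punch multipoint tie)
is solved by sparse direct factorization.

**Verification.** The test suite checks, among others: exactness of the
constant-strain patch test; global reaction balance to 10⁻⁶; agreement
with a scalar root-finding oracle for confined compression (the FEM
reproduces the closed-form $J$ to machine precision on a homogeneous
slab); the linear half-space settlement $w_0 = 2pa(1-\nu^2)/E$ within a
stated 10 % finite-domain tolerance on a deep homogeneous mesh; linearity
at vanishing load; and external-work/strain-energy consistency to 1 %.

## 3. Field metrics

Per-element deformation gradients are evaluated at element centroids;
principal logarithmic (Hencky) strains come from the eigenvalues of
$F^TF$, and Cauchy stress from $\sigma = (\mu/J)B + \bar p I$, consistent
with the solver's volumetric treatment. The scalar reductions are
von Mises stress $\sigma_{vm} = \sqrt{3/2\, s\!:\!s}$ and effective
strain $\varepsilon_{eff} = \sqrt{2/3\, e\!:\!e}$ of the deviatoric
logarithmic strain. The 2/3 normalization is a deliberate choice: it
makes an incompressible uniaxial stretch $\lambda$ read
$|\ln \lambda|$, so values pair directly with strain benchmarks quoted in
percent (therapeutic band 3–6 %, damage level > 9 %).

Layer summaries are volume-weighted ROI means by default. Depth profiles
are reported as ratios (stress normalized to adipose, strain to
epidermis). Whether such published ratios are means, medians or peaks is
not stated in the sources this package emulates; means are the default
because they are mesh-robust, and `layer_ratio_profile(statistic =
"max")` provides the peak-based alternative.

## 4. The exposure pipeline

**Thresholds.** For each tissue and quantity, the reference threshold is
the volume-weighted 75th percentile of the reference model's
baseline-stiffness field, restricted to the ROI. The percentile uses
cumulative-volume linear interpolation between order statistics
(left-continuous), a convention chosen for bit-reproducibility; it
reduces to the standard sample percentile for equal volumes.
ROI-restriction is the default because the thresholds' purpose is to
characterize the loaded region, not the far field.

**Exceedance and AUC.** $S(x)$, the fraction of selected tissue volume
with field value ≥ x, is stored as an exact step function on the
volume-weighted order statistics — no histogram binning — so
$\int_T^\infty S\,dx = E[(X-T)_+]$ is computed exactly, and
$\int_0^\infty S\,dx$ equals the volume-weighted mean (an identity the
tests assert to 10⁻¹⁰).

**Two exposure definitions.** The protocol this package implements
admits two inequivalent readings of "tissue exposure", and both are
always reported side by side:

* the AUC ratio $100 \cdot E[(X-T)_+]/E[X]$ — the share of the
  *integrated burden* above the threshold;
* the volume fraction $100 \cdot V(X > T)/V_{\text{layer}}$ — the share
  of *tissue volume* above the threshold.

The volume-fraction variant is the default comparison quantity. Its
denominator is, by default, the layer's **square-footprint volume**
($(2R)^2 \times$ thickness): the axisymmetric disc is the mechanically
active core of a square-footprint domain whose corner volume (beyond
r = 60 mm, far field) never approaches any threshold, so counting it in
the denominator — and not in the numerator — is the consistent way to
quote exposure as a percentage of the full modelled tissue.
`denominator = "disc"` switches to the solved disc volume (values scale
by $4/\pi$).

**Fixed vs. matched threshold pressure.** Thresholds exist per pressure
(2–10 kPa), but scoring each pressure against its *own* 75th percentile
is self-normalizing: the reference model's volume fraction above its own
threshold is ~25 % at every pressure, by construction. The pressure sweep
therefore defaults to the thresholds of the **highest pressure**
(`threshold_pressure = "max"`): against this fixed yardstick, exposure at
2 kPa is negligible and grows steeply toward 10 kPa, which is the
comparison the study design intends. `threshold_pressure = "matched"`
restores own-pressure scoring for redistribution analyses.

**Softening comparisons.** Thresholds always stay those of the reference
model at baseline stiffness; softened variants are scored against them.
(Otherwise a model's own exposure could never increase with softening —
its thresholds would soften too.) Per-case totals are the sums of the
four per-layer percentages, the stacked-bar convention.

## 5. The synthetic generator and what passing tests mean

`generate_field()` draws per-element stress/strain samples from
per-layer distributions (lognormal by default — positive and
right-skewed, like indentation stress fields; uniform and gamma
alternatives) with equal element volumes within a layer, under a fixed
seed (bit-reproducible, and the caller's RNG stream is restored).
`two_cohort_fixture()` adds a designed multiplicative shift on deep-layer
strain, giving the pipeline an end-to-end oracle: the exceedance of
cohort B above cohort-A thresholds has a closed lognormal form.

What the generator does *not* emulate: spatial correlation of FEM
fields, volume gradation (real meshes concentrate small elements near
the load), cross-correlation between stress and strain, or atoms/ties.
Pipeline tests passing on synthetic fields therefore validate the
*arithmetic* (percentiles, exceedance, AUC, equivariance, Monte-Carlo
calibration) — they do not validate the solver, which has its own
benchmark suite (§2), nor the discretization granularity effects of real
fields, which the mesh-convergence checks cover.

## 6. Known limitations

* **Axisymmetric idealization.** The square domain becomes a disc of
  equal half-width; lateral boundary conditions are rollers at r = 60 mm.
  Effects on ROI metrics are small (the ROI ends at r = 15 mm), but
  corner-region volume accounting is by convention (§4).
* **Material-table ambiguity.** With the shipped adipose/muscle moduli
  (E = 2 / 2–1 kPa), deep-layer von Mises stress is of order
  $\mu \varepsilon_{eff}$ ≈ 0.3–1 kPa in the 10 kPa cases. Published
  deep-tissue thresholds of several kPa at comparable strains imply
  roughly an order of magnitude stiffer deep layers; under such a
  reading, superficial-to-deep stress ratios would compress
  correspondingly. Because thresholds are percentile-based, the exposure
  *percentages* are far less sensitive to this ambiguity than the raw
  ratios — which is visible in the acceptance results, where
  percentile-normalized quantities land near their published values
  while the epidermis/adipose stress ratio does not. Users with better
  layer moduli should supply them via the config file.
* **No true contact mechanics.** The rigid punch is a tied-face
  idealization (no separation, no friction, no edge rounding); the punch
  edge induces a mild mesh-regularized stress concentration in the
  epidermis.
* **Quasi-static only.** Time is a load-scaling parameter; no inertial,
  thermal, perfusion, ischemia, or damage-accumulation physics is
  modelled, deliberately — outputs are exposure indicators, not injury
  predictions.
* **Softening trends.** Under force control, uniformly softening all
  layers leaves the stress field nearly scale-invariant; the residual
  effect on stress exposure is a second-order geometric one and its sign
  depends on the idealization. Strain exposure, by contrast, grows
  robustly with softening in all configurations tested.

## 7. Reproduction surface

`scripts/acceptance.R` re-runs the 10 kPa sweep (both models, three
stiffness levels, medium mesh, rigid punch), derives the model-1
thresholds, and writes the layer ratios and exposure percentages to
JSON. The test suite (`tests/testthat/`) contains the full property
suite — constitutive identities, solver benchmarks, exposure arithmetic,
ordinal trends — and the scaled-down quantitative comparisons at their
stated tolerances.
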