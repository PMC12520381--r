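---
title: "Methods: synthetic TAA maps and neural-operator inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic TAA maps and neural-operator inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A thoracic aortic aneurysm (TAA) is a localized dilatation of the aorta
driven by microstructural damage. Two mechanobiological contributors are of
particular interest: loss of elastic fiber integrity (the elastin-dominated
matrix loses load-bearing capability) and dysfunctional cellular
mechanosensing (the cells underestimate intramural stress and therefore
stop remodeling before homeostasis is restored). Different mixtures of the
two produce aneurysms of similar size but different mechanical
vulnerability, and neither can be measured in vivo. What *can* be obtained
from a cardiac-gated image are two full-field scalars on the vessel
surface: dilatation `d(θ,z)` (local inner radius over the mean end radius)
and distensibility `𝒟(θ,z) = (r_S − r_D)/r_D` between systole and diastole.

This package builds the complete synthetic study around that inverse
problem: it generates vessels whose lesions arise from known mixed insult
fields, renders the `d`/`𝒟` maps a clinician could obtain, and trains four
neural-operator architectures to recover the insult fields from the maps.

# The wall model

Each node of a 41 × 41 periodic `(θ, z)` grid carries an independent
thin-walled membrane in mechanobiological equilibrium — a deliberately
reduced constrained-mixture growth-and-remodeling (G&R) closure, not a
finite-element model. The wall is a mixture of elastin (deposited once with
prestretch `G_e`, fiber stress `σ_e(λ) = c_e((G_e λ)² − (G_e λ)⁻²)`) and a
turnover pool of collagen and smooth muscle, continuously deposited at
prestress `s_h` with exponential stiffening
`σ_c(λ_rel) = s_h λ_rel² exp(k_c(λ_rel² − 1))` about its deposition
configuration.

**Insults.** The elastic-fiber insult `ϑ_ce ∈ [0, 0.48]` scales the
surviving elastin stress by `η = 1 − ϑ_ce`. The mechanosensing insult
`ϑ_δ ∈ [0, 0.28]` scales the sensed stress: cells regulate against
`Δσ = ((1 − δ)σ/σ_o) − 1`, so they are satisfied only at the elevated
target `σ* = σ_o/(1 − δ)`.

**Equilibrium.** At the G&R pressure `P_gr` (systole), mass turnover
continues until the mixture carries `σ*` under thin-wall Laplace
equilibrium. With total areal mass `M(λ) = P_gr λ r_0 ρ/σ*` and elastin
fraction `φ_e = m_e/M`, the grown stretch solves

    R(λ) = φ_e η σ_e(λ) + (1 − φ_e) s_h − σ* = 0,

by bisection on `λ ∈ [0.5, 4]`. At zero insult the homeostatic identity
`φ_e⁰ σ_e(1) + (1 − φ_e⁰) s_h = σ_o` makes `λ = 1` the exact fixed point.

**Cardiac cycle.** An elastic stretch `λ'` about the grown state solves the
membrane balance at diastolic/systolic pressure, with incompressibility
thinning the wall by `1/λ'`. The collagen pool responds with a locally
stiffened exponent `k_c ζ^q`, where `ζ` is the turnover mass ratio
(`m_plus/m_plus⁰`): newly remodeled lesion collagen is stiffer. This
turnover-stiffening term is the one addition to the equilibrium closure
above; without it, mechanosensing-dominated lesions would *increase* local
distensibility (their target stress grows faster than the uniform-exponent
tangent stiffness), contradicting the suppressed distensibility these
lesions are known to show. The exponent `q = 2.5` was chosen so that a pure
mechanosensing lesion at the aneurysmal threshold suppresses distensibility
by roughly 20–25%, with elastic-fiber-dominated lesions suppressing more —
the ordering the study reproduces.

**Parameters** (nondimensional, `r_0 = ρ = 1`):

| parameter | default | meaning / why |
|---|---|---|
| `h0` | 0.1 | baseline thickness/radius ratio of a rodent ascending aorta |
| `P_dia/P_sys` | 80/120 | diastole/systole at the conventional 2:3 ratio; `P_gr = P_sys` |
| `σ_o` | 1200 | `P_gr r_0/h0`, Laplace at baseline |
| `φ_e⁰` | 0.45 | baseline elastin areal mass fraction |
| elastin load share | 0.15 | fixes `c_e`; large enough that elastin damage stiffens the cycle response, small enough that a capped mechanosensing insult can still reach dilatation 1.5 (see below) |
| `G_e` | 1.4 | typical elastin deposition prestretch |
| `k_c` | calibrated | collagen stiffening exponent, set by the distensibility calibration |
| `q` | 2.5 | turnover-stiffening exponent (above) |
| smoothing width | 3 nodes | circumferential moving average on radius fields, mimicking the membrane continuity a per-node model lacks |

`homeostaticCalibration()` performs the one free root-find: a global
stiffness scaling applied jointly to `(c_e, k_c)` (with `σ_o` and `s_h`
re-derived so the homeostatic identity holds exactly) until the zero-insult
vessel's distensibility equals 0.05442, the non-aneurysmal reference value,
to 1e-5.

# The synthetic data generator

Normalized severity profiles `ϑ*(θ,z) ∈ [0,1]` are draws of a Gaussian
random field with a squared-exponential kernel, chordal distance in `θ`
(exactly periodic covariance), correlation lengths 1 rad circumferentially
and `0.25 L` axially — single-lobe lesions. Each draw is min-max
normalized, multiplied by an axial half-sine window (lesions vanish at the
clamped vessel ends, keeping the end rows non-aneurysmal — they are the
dilatation normalization reference), floored at `t0 = 0.3` of the range via
the continuous rescale `max(0, ϑ − t0)/(1 − t0)` (compact support, maximum
exactly 1).

A profile becomes a two-contributor insult pair through a mixture weight
`w` and scale `s`: `ϑ_ce = s·w·0.48·ϑ*`, `ϑ_δ = s·(1 − w)·0.28·ϑ*`. The
scale of every (profile, w) combination is bisected until the simulated
maximum dilatation is 1.5 ± 0.01 — aneurysmal status. The default mixture
weights are `{0, 0.15, 0.30, 0.45, 0.60}`. The upper end is not 1: under
the equilibrium closure above, one can show that with `s_h > σ_o` a pure
elastic-fiber insult at its cap equilibrates well below λ = 1.5 (the
turnover term `(1 − φ_e)s_h` plus surviving-elastin stress exceeds `σ_o`
already at moderate stretch), and similarly for weights above about 0.65.
The chosen set spans the reachable dominance axis from pure mechanosensing
to the most elastic-fiber-dominated combination that attains the
dilatation target, each end with calibration margin (cap-saturated
dilatation ≥ 1.55).

The default study is 100 profiles × 5 combinations = 500 records, split
450/450 + 50 at random, all derived deterministically from one base seed.
Maps are stored both as physical-valued "heat" grids and as 8-bit
"grayscale" grids quantized under dataset-wide fixed ranges (dilatation
`[0.9, 1.8]`, distensibility `[0, 0.08]`, recorded in the container;
round-half-away-from-zero, clipping counted). The container is a
`SummarizedExperiment` (rows = grid nodes, columns = records) persisted
with R serialization plus a CSV manifest.

**What the generator emulates and what it does not.** It reproduces the
study conditions: mixed localized insults, aneurysmal calibration,
diastolic dilatation maps, suppressed lesion distensibility with the
elastic-dominance ordering, elevated lesion wall stress under
mechanosensing dominance, and exact rotational equivariance. Because every
node is mechanically independent (with only a narrow smoothing kernel),
the maps carry no long-range structural coupling: the remote ("opposite
the lesion") distensibility reduction of full FE simulations does not
occur, curvature and axial bending are absent, and the map-to-insult
relation is more local — hence easier to invert — than FE data. Passing
tests therefore demonstrate the pipeline and the architectures, not
clinical-grade inversion accuracy.

One measurable consequence: dilatation-only training is *much* worse here
than with FE data. All combinations are calibrated to closely matched
dilatation, so the mixture weight is nearly unidentifiable from `d` alone,
and the dilatation-only/two-channel error ratio computes to roughly an
order of magnitude rather than the factor ~2 reported for FE-generated
maps. The direction (distensibility is decisive) is the same; the
magnitude is a property of the reduced generator.

# The four inverse operators

All architectures map `41 × 41 × {1,2}` input maps (grayscale rescaled to
`[0,1]`; min-max normalization fitted on the training split for inputs and
targets) to the two insult fields. All are implemented on a small
reverse-mode core in this package (flat `(H·W·B) × C` activations, im2col
convolutions through compiled kernels, Adam, cosine/exponential/constant
schedules); analytic gradients are verified against finite differences in
the test suite.

* **CNN-DeepONet / FNN-DeepONet.** A branch network (three conv/max-pool
  stages + dense, or a two-hidden-layer MLP on the flattened maps) embeds
  the input; a trunk MLP embeds the output coordinate. Each insult head is
  the dot product of its half of the branch and trunk embeddings plus a
  scalar bias — one shared parameter set, split embedding. SiLU
  activations; mean-squared-error loss. The trunk consumes the cylindrical
  coordinates as a harmonic encoding (circular harmonics of `θ` up to
  order 4; `ẑ` plus its sine/cosine harmonics): with raw coordinates the
  trunk basis converges to localized lesion shapes far too slowly for
  desk-scale budgets.
* **UNet.** Reflect-pad 41 → 48 (so two 2 × 2 max-pool stages divide
  evenly), Conv/GroupNorm/GELU stages, transpose-convolution upsampling,
  skip connections, crop back to 41. Relative-L2 loss (the evaluation
  metric; the loss is otherwise unspecified for this architecture). The
  publication-scale configuration (width 64, double stages, ≈1.9M
  parameters) is the constructor default; the reduced tier trains a
  single-stage width-10 variant.
* **LNO.** Lift → four Laplace layers → projection, sine activations. Each
  layer acts separably along the two axes: the input enters through its
  first DFT modes (input poles `iω_ℓ`, coefficients `α_ℓ`), a learned
  rational kernel `K(s) = Σ_n β_n/(s − γ_n)` (matrix residues mixing
  channels) produces the steady-state response at the input poles plus the
  transient response at the system poles, and a pointwise linear bypass
  completes the layer. Poles are parameterized `Re(γ) = −softplus(ρ)` so
  transients always decay; pole/residue gradients are exact (Wirtinger
  calculus) and finite-difference-checked. Best-on-validation selection
  uses a 10% carve-out of the training records.

**Budget tiers.** The `full` tier records the publication-scale budgets
(200,000 weight updates, 225,000 for the LNO; batch 250 for the UNet,
20 for the LNO; learning rates 1e-3 constant / 1e-4 cosine / 1e-3
exponential). The `reduced` tier — what the bundled study harness and the
acceptance run use — trains 2,000 updates (1,500 for the LNO) at batch
10–20 with proportionally higher initial learning rates, and slimmer
widths. Problem sizes were chosen so one training condition takes minutes
on a single CPU; at that budget the two-channel UNet still inverts both
contributors to ~2–5% test relative-L2 error.

# Evaluation

Per-record relative-L2 error per contributor, whole-domain and restricted
to the lesion core (`ϑ* ≥ 0.50`). Records whose true contributor field is
identically zero (the pure single-contributor combinations) are excluded
from that contributor's aggregate — the relative error is undefined there.
Both the mean-of-records aggregate (headline) and the pooled-norm
aggregate are computed. Error maps are stored signed (`ϑ̂ − ϑ`).
`compareConditions()` assembles the architecture × channels × encoding
table, the per-architecture dilatation-only/two-channel error ratio, and
the ranking by two-channel error (a console note reports whether the UNet
ranks first, as a soft check).

# Numerical choices

* Bisection everywhere a root is needed (equilibrium stretch, elastic
  stretch, scale calibration, stiffness calibration): brackets
  `λ ∈ [0.5, 4]`, `λ' ∈ [0.25, 2.5]`, 60 iterations (relative tolerance
  far below 1e-10), explicit sign-change checks, monotonicity of the
  dilatation in the insult scale asserted during calibration.
* GRF covariance factorization: dense Cholesky with escalating jitter
  (1e-10 → 1e-4), factor reused across profiles.
* Degenerate inputs: constant raw fields normalize to the zero profile; a
  zero profile cannot be calibrated (explicit error); total sensing loss
  (`δ = 1`) is rejected as unsolvable.
* Quantization: round half away from zero; decoding error is bounded by
  half a step (range/510), asserted in tests.
* Seeds: child seeds derive from the base seed via R's own RNG
  (`sample.int` under a temporary seed), all below 2³¹; every stage that
  draws randomness restores the caller's RNG state.

# Known limitations

* The wall model is a per-node membrane closure calibrated to two printed
  anchors (baseline distensibility 0.05442, maximum dilatation ≈ 1.5); its
  material constants are not fitted to vessel-specific data, and
  quantities it reports beyond those anchors (stress magnitudes, thickness
  changes) are qualitative.
* Pure elastic-fiber insults cannot reach the aneurysmal threshold under
  this closure, so the mixture axis stops at w = 0.60.
* Dissection/rupture, unstable growth, 3-D curvature, and time-resolved
  G&R are out of scope.
* The reduced training tier is not a convergence study: architecture
  rankings at 2,000 updates need not match rankings at publication-scale
  budgets.
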