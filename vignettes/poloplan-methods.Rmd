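---
title: "Outcome-model-based proton plan optimization: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-model-based proton plan optimization: models, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Late contrast-enhancing brain lesions after proton therapy of low-grade
glioma cluster in regions of elevated dose-averaged linear energy transfer
(LET~d~) and near the cerebral ventricles. The probability-of-lesion-origin
(POLO) model captures this as a voxel-wise multivariate logistic regression,
and a serial-tissue argument lifts the voxel probabilities to a patient-level
normal tissue complication probability (NTCP). `poloplan` integrates this
outcome model directly into intensity-modulated proton plan optimization:
the model is evaluated in the forward pass of every objective evaluation,
and its analytic derivative is chained back to the beamlet fluence so that
a gradient-based solver can trade conventional dose goals against predicted
lesion risk.

# The voxel outcome model

For voxel $i$ with total physical dose $d_i$ (Gy), dose-averaged LET
$\ell_{d,i}$ (keV/µm) and a binary ventricular proximity factor
$b_i = \mathbf{1}\{\delta_i \le 4\,\mathrm{mm}\}$ (distance $\delta_i$ to the
ventricles), the linear predictor and probability are

$$\eta_i = -26.3 + 0.19\, d_i + 0.018\, (d_i \ell_{d,i}) + 1.19\, b_i,
\qquad p_i = \sigma(\eta_i) = \frac{1}{1 + e^{-\eta_i}}.$$

The coefficients are the published fit (per Gy, per Gy·keV/µm); the package
never refits them. Two extensions matter in planning practice:

* **Volume correction.** The model was fitted on a
  $0.6 \times 0.6 \times 3.0$ mm grid (1.08 mm³ voxels) while planning grids
  are coarser. Under a critical-element argument a voxel of $k$-fold volume
  behaves like $k$ independent sub-voxels, giving
  $p(\eta, k) = 1 - (1 - \sigma(\eta))^k$ with $k = v_\mathrm{new}/v_\mathrm{old}$.
  On the default 3 mm grid $k = 27/1.08 = 25$. `polo_params_for_grid()`
  applies this automatically; `polo_params(k = 1)` restores the original model.
* **Patient-level NTCP.** Assuming serial tissue response,
  $\mathrm{NTCP} = 1 - \prod_i (1 - p_i)$ over the evaluated voxels.

The model is evaluated on a *virtual segmentation*: all brain voxels outside
the gross tumor volume and outside the ventricles plus their 4 mm fringe,
further restricted by an index filter to voxels whose total physical dose is
at least 2 Gy. Dose enters the model as *total physical* dose; the constant
RBE factor 1.1 applies only to prescription-type (dosimetric) objectives and
constraints. Both views derive from the same dose-influence product.

Two conventions were genuinely open and are resolved as follows (users with
other conventions can override them):

* $\delta$ is measured voxel-center to voxel-center against the ventricle
  structure itself, so $b = 1$ covers the ventricles plus the 4 mm fringe,
  and the threshold is inclusive ($\delta \le 4$ exactly).
* The 2 Gy index filter applies to the total (not per-fraction) physical
  dose, consistently with the model being a total-dose model.
* Because the evaluation region excludes the ventricles-plus-fringe while
  $b$ flags exactly that set, $b$ is constant (zero) on the active voxels of
  a phantom plan; it is retained in the forward model for completeness and
  for users who re-define the evaluation region.

# From fluence to model: influence matrices and the chain rule

With fluence $\phi \in \mathbb{R}^m_+$, dose is $d = D\phi$ for the sparse
dose-influence matrix $D$. The dose-LET product is linear in the fluence:
the dose weighting of the LET average cancels against the dose factor, so
$(d \circ \ell_d) = M\phi$ with $M = L \circ D$ (elementwise), where $L$
holds per-beamlet LET values. Consequently

$$\nabla_\phi \eta = \beta_1 D + \beta_2 M =: C,$$

which is precomputed once. For an objective $f$ on the probability scale,
$\nabla_\phi f = C^\top(\partial p/\partial \eta \circ \nabla_p f)$ with

$$\frac{\partial p(\eta,k)}{\partial \eta} = k\,\sigma(\eta)\,(1-\sigma(\eta))^k,$$

reducing to $\sigma'(\eta)$ at $k = 1$. The *linear reformulation* uses the
predictor itself as the optimization quantity, $\tilde p = \eta$: monotone
transforms preserve minimizers, the sigmoid's vanishing tails disappear, and
the chain rule collapses to $\nabla_\phi f = C^\top \nabla_\eta f$.

# Objective catalogue

Four outcome-model objectives are provided:

| id | scale | value | gradient |
|---|---|---|---|
| `polo_ntcp` | $p$ | $1-\prod_i(1-p_i)$ | leave-one-out products |
| `polo_lse` | $\tilde p$ | $\log \sum_i e^{\tilde p_i}$ (max-shifted) | softmax |
| `polo_hellinger_p` | $p$ | $\sum_i p_i$ | $\mathbf{1}$ |
| `polo_hellinger_ptilde` | $\tilde p$ | $\sum_i \tilde p_i$ | $\mathbf{1}$ |

The Hellinger-type sum arises from the squared Hellinger distance to the
zero reference distribution after dropping constant factors and the monotone
root; it acts as a mean-value reduction. The log-sum-exp is a smoothed
maximum — convex on the decision scale — and the max-shift is always applied
so arbitrarily large predictors cannot overflow.

Dosimetric objectives are the standard inverse-planning penalty catalogue
(squared deviation, variance-type uniformity, one-sided squared under/over-
dosing, and DVH penalties thresholded at the structure's current volume
quantile), all normalized by structure voxel count so weights transfer
across grid resolutions. Min/max dose constraints are per-voxel box bounds.
The shipped template `inst/extdata/default_plan.yaml` carries the full
clinical objective and constraint set of the baseline plan (54 Gy(RBE)
prescription in 30 fractions); rows whose structure a given phantom does not
carry are dropped on load.

Two template rows deserve comment, since their structures are derived by
mask algebra: the "3 mm fringe in PTV" row is realized as the voxels within
3 mm of the ventricles *inside* the PTV, and the "ventricular fringe in
PTV−GTV" rows as the ventricles-plus-4-mm-fringe intersected with PTV∖GTV.
This reading makes the cap hierarchy self-consistent: the tighter 3 mm rind
receives the strictest cap (50.25 Gy(RBE)), the 4 mm fringe region an
intermediate one (52.3), while the PTV minimum-DVH goal (52 at 97% volume)
tolerates the small capped overlap. A maximum-DVH row "at 0% volume"
degenerates to a pure max-dose penalty and is implemented as such.

# The solver

The weighted-sum problem
$\min_\phi \sum_r w_r f_r(D_r \phi)$ s.t. $c_s^l \le D_s\phi \le c_s^u$,
$\phi \ge 0$, is solved by projected quasi-Newton iterations (L-BFGS-B) with
the box dose constraints softened to summed quadratic penalties (weight 200
by default; summed, not averaged, so a single-voxel bound violation carries
full weight). The interior-point solver used in the original study is
infrastructure, not method; the backend here is deliberately dependency-free
and deterministic, and the solver contract (objective/gradient callbacks,
nonnegativity bounds, feasibility reporting) is kept so another NLP backend
can be plugged in. Residual constraint violations are reported as a
feasibility measure in Gy(RBE) rather than silently accepted.

Numerical choices:

* Sigmoid, $(1-p)^k$ and the NTCP product are computed in log space
  (`plogis(log.p=)`, `expm1`, `log1p`), giving NaN-free evaluation for
  $\eta \in [-750, 750]$ and exact accumulation of thousands of tiny
  probabilities.
* The 2 Gy index filter is a hard gate. By default it is re-evaluated every
  iteration; `freeze_active = TRUE` freezes it at the initial fluence. The
  gate makes the objective piecewise-smooth: the decision-scale objectives
  (whose per-voxel terms are $O(|\eta|)$ at the gate boundary) are sensitive
  to gate chatter, so the scenario protocol in the tests runs all scenario
  solves with the frozen gate; the probability-scale objectives are
  insensitive either way ($p \approx 10^{-9}$ at the gate). The
  finite-difference gradient checker freezes the gate for the same reason.
* DVH penalties are nonsmooth at volume-quantile ties; the subgradient takes
  the lower branch. Gradient verification is therefore performed at
  tie-breaking randomized fluences.
* The initial fluence is uniform, scaled so the mean RBE-weighted PTV dose
  equals the prescription; all solves are bit-for-bit reproducible.
* `weight_search()` brackets the outcome-objective weight multiplicatively
  (×8) from a scale-aware initial guess (balancing the model term against
  the dosimetric objective value), then bisects on the log-weight until the
  plan's final NTCP enters the requested band; a non-monotone NTCP response
  triggers a warning but not an abort, and failure to converge within the
  trial budget is reported honestly.

# The synthetic phantom and beam model

No clinical data ship with the package. `make_phantom()` generates an
ellipsoidal head and brain, a paired ventricular system near the midline, a
spherical GTV placed temporo-insularly so that the margin-expanded PTV
(GTV → CTV by 5 mm, CTV → PTV by 3 mm, metric Euclidean dilations) visibly
overlaps the ventricles, an optional brainstem, and all derived planning
structures. Default grid: 60 × 60 × 40 voxels at 3 mm. A single integer seed
jitters centers and radii within ±1.5 mm; everything is deterministic given
the seed. The default GTV radius of 20 mm (≈34 cm³) is in the typical
low-grade-glioma range.

The influence model is an analytic stand-in for a pencil-beam kernel
database, which is out of scope: straight rays through a homogeneous
water-equivalent medium (geometric depth inside the external contour,
estimated per lateral pencil column), a piecewise-analytic Bragg-like depth
dose (entrance/peak ratio ≈ 0.3, Gaussian distal falloff of 5 mm width), a
Gaussian lateral profile (σ = 5 mm), and a monotone logistic depth-LET ramp
from 2 keV/µm at the entrance to 12 keV/µm just beyond the range. These
defaults were set once so the default phantom reproduces the qualitative
dose/LET~d~ topography of a three-field proton plan — in-target LET~d~
roughly 2–5 keV/µm and distal values above 8 keV/µm — which is exactly the
regime in which the outcome model's dose × LET term matters. Spots tile the
PTV's beam's-eye-view bounding box (8 mm lateral spacing) with energy layers
tiling the PTV depth extent (8 mm); influence entries below 10⁻³ of the
column maximum are dropped. Beam directions derive from the couch angle in
the axial plane (default three fields at 175°, 240°, 310°; the gantry angle
is metadata).

What the phantom does *not* emulate: tissue heterogeneity and raytracing
through it, nuclear halo and range straggling, Monte Carlo dose accuracy,
realistic multi-lobed target shapes, and the anatomical detail of optic
structures. Passing tests on the phantom therefore demonstrate the
correctness of the optimization machinery — forward model, gradients,
constraint handling, scenario protocol — not clinical dose accuracy on real
patients, and phantom NTCP levels are not comparable to any published
patient value.

# Problem sizes and verification scales

The test suite verifies each operation against an independent oracle at the
scale where the oracle is exact: all-pairs brute force for the distance
transform (grids up to 25³), dense matrix brute force for the dose-LET
product (50 random fluences), the direct product form for the NTCP
accumulation (up to 100 voxels), and central finite differences for every
objective's fluence gradient (a ~58k-voxel/4 mm phantom with ~200 beamlets
and thousands of active model voxels). Scenario-level properties — NTCP
decreasing monotonically in the outcome-objective weight for all four
objectives, the weight search reaching half-baseline NTCP within twelve
solves, and preserved PTV D95 under the probability-scale objectives —
run on the default 3 mm phantom at a fixed seed with the frozen-gate
protocol.

# Known limitations

* Constraints are penalized, not enforced exactly; feasibility is reported
  and typically settles well below 0.1 Gy(RBE), but hard guarantees would
  need an NLP backend with explicit constraint support.
* The decision-scale objectives can trade target coverage for risk
  reduction, consistent with their stronger penalties on large predictor
  values; coverage preservation is only asserted for the probability-scale
  objectives.
* The active-set gate makes the objective discontinuous at the 2 Gy
  threshold; with the re-evaluated gate, solver line searches may chatter
  when many voxels sit near the threshold.
* Robust (worst-case) optimization, machine deliverability constraints and
  variable RBE models are out of scope.
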