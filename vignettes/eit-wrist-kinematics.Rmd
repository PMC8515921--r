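---
title: "Estimating multi-DoF wrist kinematics from forearm EIT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multi-DoF wrist kinematics from forearm EIT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eitwrist)
```

## The problem

A fabric band with 16 electrodes around the forearm injects a small
alternating current through neighbouring electrode pairs and records the
voltages on all other neighbouring pairs. Because contracting muscle changes
its electrical conductivity, the cross-sectional conductivity image tracks
which forearm muscles are active, and therefore the posture of the wrist.
`eitwrist` implements the full estimation chain from raw voltage frames to
continuous three-DoF wrist angles — flexion/extension (F/E), radial/ulnar
deviation (RD/UD) and pronation/supination (P/S) — together with a synthetic
phantom that stands in for human recordings.

## Measurement protocol

With $n$ electrodes the adjacent protocol drives each neighbouring pair in
turn and, per injection, measures the $n-3$ neighbouring pairs that share no
electrode with the drive pair: $n(n-3)$ values per frame, 208 for $n = 16$,
sampled at 10 Hz. The pattern ordering (drive pairs ascending, measurement
pairs in rotational order starting two electrodes past the drive pair) is a
package convention; any fixed order works as long as the Jacobian rows use
the same one, which `forward_model()` guarantees by construction.

## Forward model

The potential $\phi$ inside the cross-section obeys
$\nabla \cdot \sigma \nabla \phi = 0$ with Neumann current boundary
conditions. We discretize with linear (P1) triangular finite elements on a
structured star-shaped mesh of a parameterized forearm outline (an ellipse
with a low-order cosine flattening term; a circle is the degenerate case).
Conductivity lives on elements; electrodes use the gap model (current split
uniformly over the electrode's boundary nodes, electrode potential read as
the node average), with the gauge fixed by zeroing the mean boundary
potential. The complete electrode model would add contact impedances that
nothing in a time-difference pipeline can identify, so it is left as an
extension point.

The sensitivity (Jacobian) matrix $J_{ke} = \partial V_k / \partial \sigma_e$
is assembled by the adjoint method: minus the integral over element $e$ of
the dot product of drive-field and measurement-field gradients. Unit tests
hold the forward model to reciprocity (swap drive and measurement pairs) at
$10^{-8}$ relative, conductivity-scaling $F(c\sigma) = F(\sigma)/c$ at
$10^{-10}$, and finite-difference agreement of $J$ at $10^{-4}$.

The drive current default is 400 µA RMS; the model is linear in it, so it
only sets the voltage scale. The baseline conductivity is homogeneous
$\sigma_0 = 1$ in arbitrary units: time-difference imaging never recovers
absolute tissue conductivity, it only needs a plausible linearization point.

## Image reconstruction

Time-difference EIT linearizes $V = F(\sigma)$ at $\sigma_0$ and solves, per
frame,
$$\hat{\delta\sigma} = (J^{T}WJ + \lambda^{2}Q)^{-1}J^{T}W\,\delta V,$$
the one-step regularized Gauss–Newton estimate with measurement weighting
$W$ (identity by default) and Tikhonov prior $Q$ (identity by default, NOSER
$\mathrm{diag}(J^{T}WJ)$ as an option). Numerically the operator is built
from the SVD of $W^{1/2} J Q^{-1/2}$ rather than the normal equations: EIT
sensitivity matrices are severely ill-conditioned (condition number about
$10^{14}$ even on a 64-element mesh), so forming $J^TWJ$ underflows to
numerical singularity at small $\lambda$, while the SVD filter
$d_i/(d_i^2 + \lambda^2)$ is stable at any $\lambda \ge 0$. The two routes
agree to $10^{-8}$ at ordinary $\lambda$, which the tests assert against a
dense ridge solve.

$\lambda$ is specified *relative* to the largest singular value
($\lambda_{abs} = \lambda \cdot d_1$, default $\lambda = 10^{-2}$), making
the choice independent of mesh density and current amplitude. The baseline
frame $V_0$ is the mean of the first 10 frames, which the recording protocol
guarantees are neutral-posture frames (see the phantom's rest hold below).

A consequence of the ill-posedness worth stating plainly: deep-interior
conductivity contrasts are invisible at the boundary, so *no* choice of
$\lambda$ recovers them. The package's inverse-consistency checks therefore
plant truths in the identifiable singular subspace ($d_i \ge 10^{-3} d_1$),
where recovery at $\lambda = 10^{-8}$ is exact to $10^{-4}$, and verify
full-space recovery only on well-conditioned synthetic systems.

## Features

Each reconstructed image is down-sampled onto an axis-aligned grid of equal
square cells overlaid on the mesh bounding box; empty cells are dropped and
the cell size is bisected until the non-empty count is within 5% of the
target $M$ (cells are geometrically equal; their element counts $K(i)$
differ, hence the $1/K(i)$ normalization). Feature $i$ is the mean
conductivity change over region $i$:
$$S(i) = \frac{1}{K(i)} \sum_{e \in \Omega(i)} \delta\sigma_e .$$

The augmented features are the vectorized upper triangle (diagonal included)
of the outer product,
$$\bar{S} = \mathrm{vec}\,\mathrm{triu}(S S^{T}),$$
all $M(M+1)/2$ pairwise products $S_i S_j$, $i \le j$ — 73,153 at the
full-image scale $M = 382$. Products of region pairs capture co-activation
of distinct muscle groups, which is what couples the three DoFs. The flat
ordering is row-major and `unmap_index()` is its exact inverse (tested
exhaustively for $M \le 10$).

Before any augmentation the pipeline re-centers each session's region
features to their session means (`center_features = TRUE`). This is
unsupervised per-recording calibration, not standardization: a
time-difference image is only defined relative to the estimated baseline
frame, and any residual baseline error — measurement noise in the baseline
window plus whatever postural micro-motion occurred during it — is a
*constant offset* for the whole session. Linear features absorb such an
offset in the intercept, but product features do not: $(s_i + p_i)(s_j +
p_j)$ contains $p_i s_j + p_j s_i$ cross terms that differ between training
and test sessions. Removing the per-session feature mean removes the offset
exactly, which measurably restores cross-session transfer for the
smallest-amplitude DoF and removes the optimism it induced in
within-session penalty selection. No variance scaling is applied; the Lasso
operates on the natural conductivity-product scale.

## Regression

**Lasso.** Each DoF gets an independent scalar model minimizing
$$\frac{1}{2N}\sum_i (\beta' x_i + \beta'_0 - y_i)^2 + \lambda \|\beta\|_1,$$
i.e. a Gaussian-deviance GLM with identity link and an L1 penalty that
performs the region selection. The solver is cyclic coordinate descent with
soft-thresholding, warm starts along the penalty path, sequential
strong-rule screening with a full KKT pass before any solution is accepted,
and an unpenalized intercept handled by centering. Convergence is declared
when the largest *standardized* coefficient change in a sweep,
$|d_j|\,\mathrm{sd}(x_j)/\mathrm{sd}(y)$, drops below `tol` (default
$10^{-4}$, which corresponds to a relative objective change of about
$10^{-8}$ — one decade stricter than the default of the field-standard
solver). A raw coefficient-change criterion would be dimensionally arbitrary
here because conductivity-product features are many orders of magnitude
smaller than the degree-valued targets. glmnet serves as an independent
cross-check in the test suite, never as the implementation.

**SVR.** The $\epsilon$-insensitive RBF support vector regressor solves the
standard dual quadratic program (box constraints $[0, C]$, equality
$\sum_i (\alpha_i - \alpha_i^*) = 0$) via the libsvm SMO solver behind
`fit_svr()`; the model is stored in dual form and predictions are evaluated
by the package from the kernel expansion
$\hat y(x) = \sum_i (\alpha_i - \alpha_i^*)\,e^{-\gamma\|x_i - x\|^2} + b$.
The kernel width is called `gamma` to avoid any collision with the
conductivity $\sigma$. The intercept is averaged over free support vectors —
equivalent at the exact optimum to reading it off a single tube-boundary
point, but stable in floating point. A dense interior-point QP solve is the
independent oracle in the tests.

**Hyperparameters.** Neither penalty weights nor SVR constants are fixed a
priori; they are chosen by 3-fold cross-validated MSE on the training
session only. The default grids are: 50 log-spaced $\lambda$ over
$[10^{-4}, 1]\,\lambda_{max}$; $C \in \{0.1, 1, 10, 100\}$,
$\epsilon \in \{0.01, 0.1\}\,\mathrm{sd}(y)$, and
$\gamma \in \{0.01, 0.1, 1\}/\mathrm{median}\|x_i - x_j\|^2$. CV folds are
contiguous blocks *within each DoF segment* (block $f$ of every segment
forms fold $f$): plain contiguous thirds of a session would coincide with
the three DoF segments, so every training fold would be missing one DoF's
entire signal and the selection degenerates to $\lambda_{max}$. Ties break
toward stronger regularization (larger $\lambda$, smaller $C$).

## Evaluation

Session-wise cross-validation trains on one session, tests on the other,
swaps, and *averages* the two folds' metrics (they are not pooled). Metrics
per DoF: RMSE in degrees; NRMSE = RMSE divided by the range
$y_{max} - y_{min}$ of the test-segment reference angles (the only
self-contained reading of the range); and $R^2$. Both NRMSE and $R^2$ raise
an error on constant references instead of silently returning NaN.

The 3×3 cross table probes transfer: entry $(d, c)$ trains a model only on
the training session's DoF-$d$ segment and evaluates the DoF-$d$ angle
during the test session's DoF-$c$ segment. Its diagonal is the principal
DoF; off-diagonal references are near-constant idle jitter, so off-diagonal
NRMSE is large — the qualitative signature that single-DoF training does not
transfer across DoFs. Cross-table models reuse the per-DoF hyperparameters
selected on the full training session.

For Lasso on augmented features, `selection_summary()` reports the number of
non-zero weights per DoF, how many lie on the outer-product diagonal (pure
single-region squares — typically a small minority, meaning inter-region
products carry the signal), and a per-region heat map accumulated by adding
one count to each endpoint region of every selected product.

## The synthetic phantom

No public recordings accompany this problem, so the package ships a phantom
that emulates the recording protocol and the statistical structure the
estimator assumes, and is itself first-class tested code.

* **Trajectory.** Two sessions; each starts with a 2 s neutral rest hold
  (the frames the baseline is estimated from — omitting the hold measurably
  biases the baseline with early-cycle flexion frames), then exercises F/E,
  RD/UD, P/S in order for 20 sine-shaped cycles each (neutral → +max →
  neutral → −max per 4 s cycle, reaching both extremes of the stated
  excursion), with 5% per-cycle extent jitter for self-paced motion. Idle
  DoFs carry ±2° postural micro-motion modelled as a smoothed stationary
  AR(1) with a 1.5 s correlation time: a low-dimensional deterministic
  jitter curve (e.g. a fixed sum of sinusoids per segment) would be
  artificially predictable, letting within-session cross-validation exploit
  structure that does not transfer across sessions. Ranges of motion default
  to ±60° (F/E), ±25° (RD/UD), ±70° (P/S) — physiological values, with
  RD/UD deliberately the smallest.
* **Conductivity.** Three antagonistic muscle groups stand in for the
  forearm compartments, one per DoF emphasis. Each group has a scalar drive
  $u = g \cdot a / 90°$ (gain vector $g$ over the three DoFs) and two
  Gaussian lobes on opposite sides of the cross-section: the agonist lobe
  responds with $\mathrm{act}(u)$ and the antagonist lobe with
  $\mathrm{act}(-u)$, where
  $\mathrm{act}(v) = (v + \mathrm{asym}\,|v|)/(1 + \mathrm{asym})$ and
  $\mathrm{asym} = 0.8$ — close to the fully rectified activation of paired
  flexor/extensor compartments, which contract (and change conductivity) for
  their own half of the motion only. Peak changes are 10–20% of baseline, in
  line with the tens-of-percent conductivity swings of contracting muscle.
  This structure is not decoration but a requirement of the
  augmented-feature design, found the hard way: every augmented feature is a
  product of two responses that vanish at neutral, so (i) a strictly odd
  (linear) response makes the *sign* of the angle unidentifiable from
  $\bar S$ (the penalty selection collapses to $\lambda_{max}$ and
  $R^2 \approx 0$), and (ii) three single-location groups span only six
  effective products — demonstrably too few to disentangle three DoFs even
  on noise-free fields (RD/UD caps near $R^2 = 0.58$). Directionally
  selective lobe pairs provide both the sign channel ($\theta|\theta|$
  content, correlation $\approx 0.98$ with $\theta$) and the spatial rank;
  with them, regression on features of the *true* fields reaches
  $R^2 \approx 0.96$ for every DoF. Setting `asym = 0` recovers a strictly
  linear (odd) map for the algebraic unit tests.
* **Noise.** I.i.d. Gaussian on the RMS voltages with sd equal to
  $10^{-3}$ of the baseline frame RMS — a minimal stand-in, since no noise
  characterization is available for the real hardware. Conductivities driven
  non-positive are clipped at 5% of baseline with a warning.
* **Determinism.** Session $s$ uses RNG stream `seed + 1000(s-1)`; reruns
  are bit-identical, sessions differ only in noise and pace/extent jitter.

What passing on the phantom does and does not show: the phantom is smooth,
low-rank (three blobs), exactly time-synchronized and drift-free. Real
recordings add electrode-contact drift, band slippage, anatomy that is not a
sum of Gaussian blobs, and angle references with their own error. Phantom
results validate the *pipeline* — protocol bookkeeping, forward/inverse
consistency, feature algebra, selection and evaluation machinery — not
human-subject performance.

## Problem sizes and numerical choices

The end-to-end study runs at a coarse mesh of ~800 elements with $M \approx
100$ regions (augmented dimension 5,050), 20 cycles per DoF and two sessions
(2,420 frames each), chosen so the full protocol, including per-session
hyperparameter re-selection, completes in a few minutes on one core while
preserving every structural property of the full-scale configuration
(~5,900 elements, $M = 382$). Finite-difference Jacobian checks use a
64-element mesh; reciprocity checks use ~500 elements. Degenerate inputs are
errors, not silent results: non-positive conductivities, constant metric
references, mismatched frame lengths, empty hyperparameter grids and
out-of-range flat indices all raise typed messages.

With the default conditions the session-wise CV on the phantom attains
$R^2$ above 0.9 for every DoF, with the cross-table diagonal NRMSE two
orders of magnitude below the off-diagonal mean; `scripts/acceptance.R`
recomputes all of these from scratch at any seed.

## Known limitations

2D cross-section only; gap electrode model (no contact impedances); one-step
linearized reconstruction (no iterated Gauss–Newton, no electrode-movement
compensation); diagonal regularization priors; single-subject phantom
geometry; repeated-measures significance testing is out of scope — the
report exports per-run metric tables for external statistics.
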