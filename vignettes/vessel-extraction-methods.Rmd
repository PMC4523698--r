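---
title: "Multi-modal tensor-voting vessel extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal tensor-voting vessel extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselvote)
```

## The problem

Planning safe trajectories for intracranial depth electrodes requires a
reliable map of the cerebral vasculature. Angiographic volumes from
different modalities — contrast CT angiography (CTA) and flow-sensitive MR
sequences such as 3-D phase contrast — show the same vessels with
complementary strengths and weaknesses: each suffers its own noise, partial
volume losses and local signal dropouts, so single-modality extractions are
prone to discontinuities and false positives. `vesselvote` implements a
fully automated pipeline that (i) screens voxels with a multi-scale
Hessian vesselness filter, (ii) refines the evidence with tensor voting in
a scale-adaptive neighbourhood, and (iii) fuses per-modality results into a
single vessel-probability volume using a directional-consistency (cosine)
measure, so that structures confirmed by several modalities are reinforced
and discordant responses are suppressed.

## Multi-scale analysis and voxel selection

For an input volume $I(\mathbf{x})$ the Hessian $H_\sigma(\mathbf{x})$ is
computed with separable Gaussian derivative kernels at physical scale
$\sigma$ (mm). Scales are specified in millimetres and converted per axis
to voxel units, so anisotropic voxels are handled without resampling;
boundaries are reflect-padded. Derivatives are $\gamma$-normalised with
$\gamma = 1$ (multiplied by $\sigma^2$): without this, responses at
different scales are not comparable and the per-voxel argmax below is ill
posed.

Eigenvalues are ordered by magnitude, $|\kappa_3| \ge |\kappa_2| \ge
|\kappa_1|$. A bright tubular structure has $\kappa_2 < 0$, $\kappa_3 < 0$
and $\kappa_1 \approx 0$, with the $\kappa_1$ eigenvector $v_1$ pointing
along the tube. The vesselness $\nu(\mathbf{x}, \sigma) \in [0, 1]$ is the
smooth tube-likeness function used for vessel-enhancing diffusion: the
classic three-factor form
$$\nu = \left(1 - e^{-R_A^2 / 2\alpha^2}\right)
  e^{-R_B^2 / 2\beta^2}
  \left(1 - e^{-S^2 / 2c^2}\right)
  e^{-2C^2 / (|\kappa_2|\kappa_3^2)},$$
with $R_A = |\kappa_2| / |\kappa_3|$ (plate vs line), $R_B = |\kappa_1| /
\sqrt{|\kappa_2 \kappa_3|}$ (blob), $S$ the Hessian Frobenius norm
(structureness), and a final smoothing factor that removes the hard cutoff
at $\kappa_2 = 0$. Setting `C = 0` (or `variant = "frangi"`) recovers the
classic form. Defaults follow the published guidelines: $\alpha = \beta =
0.5$; $c$ is resolved adaptively to half the maximum Frobenius norm over
the whole scale ladder (a per-scale $c$ would distort the cross-scale
argmax); $C = 10^{-6}$ only regularises the sign boundary.

Scales form a log-uniform ladder (default 10 scales, 1.0–4.5 mm — a range
that brackets intracranial vessel calibres at clinical voxel sizes). The
*optimal-scale image* is
$$M(\mathbf{x}) = \arg\max_{\sigma} \nu(\mathbf{x}, \sigma),$$
with ties broken toward the smallest scale (thin-vessel fidelity). A voxel
is admitted as a *token* iff $\kappa_2 < 0 \wedge \kappa_3 < 0$ at at
least one scale; admitted voxels carry the Hessian eigensystem at
$M(\mathbf{x})$. Numerically, the strict sign test is guarded by a
curvature significance floor ($10^{-12}$ of the intensity range): an
exactly flat region otherwise passes it with convolution roundoff.

On a Gaussian tube of cross-sectional standard deviation $s$, the
$\gamma$-normalised response peaks analytically at $\sigma = s$; the
scale-recovery experiments in the test suite therefore parameterise
"Gaussian tubes of size $r$" by their profile sd. The phantom generator's
*truth* radius is a separate quantity (default profile sd = radius/2,
giving realistic partial-volume boundaries).

## Token encoding

Each token's evidence is a symmetric positive-semidefinite tensor
$T = \sum_i \lambda_i e_i e_i^T$, $\lambda_1 \ge \lambda_2 \ge \lambda_3
\ge 0$, equivalently a *stick* ($\lambda_1 - \lambda_2$, orientation
$e_1$), *plate* ($\lambda_2 - \lambda_3$) and *ball* ($\lambda_3$)
mixture. Six initialisations are provided (`init_tokens()`):

| strategy             | tensor                         | saliency                  |
|----------------------|--------------------------------|---------------------------|
| `ball_k`             | isotropic                      | constant $K$ (default 1)  |
| `ball_intensity`     | isotropic                      | $I(\mathbf{p})$, rescaled |
| `ball_vesselness`    | isotropic                      | $\nu(\mathbf{p})$         |
| `hessian_kappa`      | $\lambda_i = |\kappa_i|^{-1}$, axes $v_i$ | spectrum-derived |
| `hessian_vesselness` | stick along $v_1$              | $\nu(\mathbf{p})$         |
| `structure_tensor`   | stick $\nabla I \nabla I^T / \lVert\nabla I\rVert^2$ | $\lVert\nabla I\rVert^2$, rescaled |

Intensity-derived saliencies (intensity ball, structure tensor) are
rescaled to $[0, 1]$ by their 99.9th percentile so that modalities with
different intensity units remain commensurable at the fusion stage.
$|\kappa_i|^{-1}$ is capped at $10^3$ times the median non-zero
$|\kappa|^{-1}$ (the formula is singular at $\kappa = 0$). Structure-tensor
gradients are taken at $\sigma = M(\mathbf{p})$ and $\sigma$-normalised,
mirroring the Hessian treatment. The default strategy is
`hessian_vesselness` — the simplest tensors among the best-performing
configurations.

## Tensor voting

Every token $\mathbf{q}$ propagates its tensor to the voxels of a
scale-adaptive window and votes are summed,
$$TV(\mathbf{p}) = \sum_{\mathbf{q}} \big(SV + PV + BV\big)(\mathbf{p} -
\mathbf{q}).$$
The window half-width is $N = 2 M(\mathbf{q})$ mm, converted per axis to
voxels (ceiling, floor of one voxel). Windows are indexed by the *voter*:
this allows vote stencils to be cached per scale, and for smoothly varying
$M$ covers the same pairs as receiver-indexed windows. Votes are
accumulated at every voxel of the window, not only at tokens, so the
saliency maps are dense.

The stick kernel is the classic arc connection in the *tangent*
convention: the voter's stick orientation $e_1$ is the local curve tangent
(for vessels, the direction along the vessel). For a receiver at
displacement $v$, with $\theta$ the angle between $v$ and $\pm e_1$, the
connecting circular arc has length $s = \lVert v\rVert\,\theta /
\sin\theta$ and curvature $\kappa_a = 2 \sin\theta / \lVert v\rVert$; the
vote is the rank-1 tensor of the arc-rotated tangent scaled by
$$DF = \exp\!\big(-(s^2 + c\,\kappa_a^2) / \sigma_d^2\big),$$
zero beyond the angular cutoff (default 45°). The decay width is tied to
the window, $\sigma_d = N/3$, so votes fall to $e^{-9}$ at the window
edge; the curvature penalty is $c = b\,\sigma_d^4$ with dimensionless
weight $b$ (default 1), i.e. an arc whose curvature radius equals
$\sigma_d$ costs $e^{-b}$. Plate votes integrate unit stick votes over the
plate plane's orientation circle with an exact 16-node rule (the
integrand is a trigonometric polynomial over a period-$\pi$ circle); ball
votes reduce, by azimuthal symmetry, to a 1-D polar integral evaluated
with 48-node Gauss–Legendre quadrature. Self-votes return the component
itself. The compiled accumulator and the plain-R single-vote functions
share these node definitions exactly, so the naive double-loop reference
in the test suite matches the production path to $10^{-8}$, while the ball
reduction is independently validated against Monte-Carlo orientation
sampling to within 2%.

A consequence of the tangent convention, verified by that quadrature
oracle, is that ball votes are dominated by the direction joining voter
and receiver. For tokens spread through a *volumetric* cluster (a thick,
resolved tube filled with unoriented ball tokens) votes arrive from all
directions and largely cancel: the surface saliency $\lambda_1 -
\lambda_2$ then concentrates on the cluster's shell rather than its core.
Oriented (stick) initialisations do not suffer from this. The
no-preferred-orientation strategies are therefore at their best on vessels
near the resolution limit — one or two voxels across, where the token
cloud is curve-like — which is also the regime of intracranial vessels at
clinical voxel sizes; the bundled initialisation-comparison phantom uses
such thin tubes. Inside this degenerate regime the relative ranking of the
weakest ball saliencies (image intensity vs constant $K$) is not
reproducible and should not be over-interpreted; the test suite documents
this as an expected failure of one ordering assertion.

## Voting analysis and fusion

The accumulated field is eigendecomposed per voxel ($\lambda_1 \ge
\lambda_2 \ge \lambda_3 \ge 0$, tiny negatives clamped, violations beyond
$10^{-8}$ of the trace are an error naming the voxel) into three maps of
tuples $(s, w)$: the S-map ($\lambda_1 - \lambda_2$, $e_1$) — for vessels,
a consensus vesselness and the direction along the vessel; the C-map
($\lambda_2 - \lambda_3$, $e_3$); and the J-map ($\lambda_3$, direction
free). Zero tensors yield $s = 0$ with the sentinel direction $(0,0,0)$.
Only the S-map feeds the vessel pipeline.

Per-modality S-maps (after percentile normalisation, and resampled onto
the first modality's grid by trilinear interpolation with renormalised
directions if needed) are fused voxel-wise:
$$\varphi = \tfrac12\,\lvert w_1 \cdot w_2\rvert\,(s_1 + s_2),
\qquad
\varphi = \tfrac1L \sum_i s_i \sum_{j \ne i} \lvert w_i \cdot w_j\rvert$$
for two and $L$ modalities (the latter reduces exactly to the former at
$L = 2$). Complete directional agreement yields the average saliency;
perpendicular directions yield zero; sentinel directions contribute zero
alignment, so a voxel where one modality found nothing is penalised —
deliberately, as the operator rewards consensus and punishes discord.
Voxel-wise `min` and `max` of the saliencies are provided as the
probabilistic analogues of AND/OR baselines: `min` propagates
single-modality gaps, `max` favours continuity at the cost of
false-positive volume (it bounds the cosine map from above wherever
saliencies are non-negative).

## Evaluation

Probabilistic maps are compared with the fuzzy Dice coefficient,
$$\mathrm{DSC} = \frac{2 \sum \min(S, M)}{\sum S + \sum M},$$
which reduces to the classic Dice on binary inputs; both-empty inputs give
1 by convention. Maps are brought to $[0, 1]$ by 99.9th-percentile
normalisation first; for binary comparisons a global Otsu threshold is
applied. Multi-rater reference standards are built by voxel-wise voting
(`consensus_mask()`, default majority). `run_comparison()` crosses
initialisation strategies with fusion operators on a phantom over seeds
and reports mean ± sd of both DSC variants; no significance test is
performed — only descriptive statistics are reported.

## The phantom generator

`generate_phantom()` renders tubes (straight, helical, bifurcating
polylines) with Gaussian radial intensity profiles (default sd =
radius/2, emulating partial-volume boundaries) into two or more
co-registered modalities sharing identical geometry. Per modality it
applies a signal gain, optional Gaussian smoothing, additive Gaussian
noise, and optional *dropout segments* — contiguous fractions of the
centerline with attenuated signal — emulating the modality-specific weak
responses and discontinuities of clinical angiography. The default
modality pair mimics the asymmetry of a cleaner CT-like channel (noise sd
0.02 on unit peak intensity) and a noisier MR-like channel (sd 0.06). The
`dropout_pair` preset attenuates disjoint centerline fractions
(0.15–0.40 and 0.60–0.85, attenuation 0.1) in the two modalities, the
setting under which fusion benefits are measured. Ground truth (voxels
within the tube radius of a centerline) depends only on geometry, never on
modality settings, and all randomness is fixed by one seed.

What the phantoms do *not* emulate: acquisition physics (beam hardening,
flow artefacts, bias fields), registration error (modalities are perfectly
aligned), anatomy (no surrounding tissue contrast), and realistic vessel
tree complexity. Passing phantom-based checks demonstrates the internal
consistency and the qualitative behaviour of the method, not clinical
accuracy.

## Numerical choices

* Eigenvector signs: largest-magnitude component positive (first on ties) —
  determinism for tests; tensors are sign-free so results are unaffected.
* Optimal-scale ties go to the smallest scale.
* Derivative kernels carry discrete moment corrections (exact responses to
  constants, ramps and quadratics), radius $4\sigma$, reflect padding.
* Significance floors ($10^{-12}$–$10^{-10}$ of the intensity scale) guard
  the token sign test and the structure-tensor gradient against
  convolution roundoff on flat regions.
* Quadrature: 16-node circle rule (exact for the plate integrand), 48-node
  Gauss–Legendre for the ball's polar integral.
* Dark-vessel inputs are handled by intensity inversion (`invert = TRUE`),
  never by flipping the sign test.

## Problem sizes

The test-suite and acceptance-script experiments use phantoms of
$32^2 \times 48$ to $40^2 \times 24$ voxels at 1 mm spacing with the
default 10-scale ladder — large enough to contain the widest kernels and
voting windows, small enough that the full suite runs in under two
minutes on a single core. Scale-recovery tubes use profile sds 1.5, 2.5
and 3.5 mm, bracketed by the ladder; the initialisation comparison uses
tubes of radius 1.0–1.3 mm (see the tangent-convention discussion above);
the sub-voxel recall experiment pairs a 2.5 mm with a 0.7 mm tube.

## Known limitations

* Single-threaded; volumes much beyond $256^3$ with dense token sets will
  be slow.
* Inputs must be affinely co-registered; only grid resampling is provided.
* The no-preferred-orientation initialisations degrade on thick, fully
  resolved tubes (see above); the Hessian-oriented default does not.
* The fuzzy DSC of a probabilistic map against a binary reference depends
  on the normalisation percentile; both the fuzzy and the Otsu-binarised
  variants are reported by `run_comparison()` for this reason.
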