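# vesselvote

Multi-modal, multi-scale tensor-voting extraction of vascular structures
from 3-D angiographic volumes, for users who need a single fused
vessel-probability map from two or more co-registered modalities (e.g. CT
angiography and phase-contrast MRA) — typically as input to surgical
planning, visualisation or downstream segmentation.

## The method

Vessels are bright tubes on a dark background. For each modality the
pipeline:

1. **Multi-scale vesselness.** Computes γ-normalised Gaussian-derivative
   Hessians over a log-spaced scale ladder (default 10 scales, 1.0–4.5 mm)
   and a smooth tube-likeness response ν(**x**, σ) ∈ [0, 1] from the
   magnitude-ordered eigenvalues |κ₃| ≥ |κ₂| ≥ |κ₁|. The *optimal-scale
   image* M(**x**) = argmax_σ ν(**x**, σ) fixes the scale of all later
   steps. Voxels with κ₂ < 0 ∧ κ₃ < 0 at some scale become *tokens*.
2. **Token encoding.** Each token carries a symmetric PSD tensor
   T = Σ λᵢ eᵢeᵢᵀ; six initialisations are provided (isotropic ball with
   constant / intensity / vesselness saliency; Hessian-oriented sticks
   with |κᵢ|⁻¹ or vesselness saliency; the structure tensor ∇I∇Iᵀ).
3. **Tensor voting.** Tokens cast stick, plate and ball votes over a
   scale-adaptive window N = 2 M(**q**) mm with an arc-connection kernel
   (decay exp(−(s² + c κ_arc²)/σ_d²), 45° cutoff, σ_d = N/3); votes are
   summed into a tensor field (compiled accumulator).
4. **Voting analysis.** The field decomposes into S/C/J saliency maps;
   the S-map tuple (λ₁−λ₂, e₁) is the consensus vesselness and the
   direction along the vessel.
5. **Fusion.** Per-modality S-maps combine through the cosine consistency
   measure φ = ½ |w₁·w₂| (s₁ + s₂) (L-modality generalisation included),
   with voxel-wise min/max as AND/OR-style baselines.

Evaluation tools include the fuzzy Dice coefficient
DSC = 2 Σ min(S, M) / (ΣS + ΣM), multi-rater consensus by voxel voting,
and a comparison harness crossing initialisations × fusion operators on
synthetic phantoms. A phantom generator renders multi-modal tube phantoms
(straight / helix / bifurcation, modality-specific noise and signal
dropouts) with exact ground truth, so the whole pipeline is testable
without clinical data.

## Worked example

Two-modality phantom with complementary signal dropouts, fused with the
cosine operator:

```r
library(vesselvote)
ph <- generate_phantom(phantom_preset("dropout_pair", seed = 7))
fused <- vessel_extract(ph$modalities, config = vessel_config())
fused
#> <fused_map> op 'cosine' over 2 modalities, 32x32x48 voxels, max 1
round(c(cosine = fuzzy_dice(fused$phi, ph$truth + 0),
        m1 = fuzzy_dice(fused$smaps[[1]]$s, ph$truth + 0),
        m2 = fuzzy_dice(fused$smaps[[2]]$s, ph$truth + 0)), 3)
#> cosine     m1     m2
#>  0.533  0.511  0.491
```

The fused map scores a higher fuzzy Dice against ground truth (0.533)
than either modality alone (0.511 / 0.491): each modality's dropout gap is
filled by the other wherever their vessel directions agree. The
comparison harness reports the fusion-operator sweep (`dsc` is the fuzzy
Dice of the normalised map, `dsc_otsu` after Otsu binarisation):

```r
run_comparison(phantom_preset("dropout_pair", seed = 7),
               strategies = "hessian_vesselness",
               fusion_ops = c("cosine", "min", "max", "single"),
               seeds = 7:8)
#>             strategy    fusion n_seeds  dsc_mean  dsc_sd dsc_otsu_mean
#> 1 hessian_vesselness    cosine       2 0.5335459 0.00117     0.7375339
#> 2 hessian_vesselness       min       2 0.4010118 0.00091     0.5028728
#> 3 hessian_vesselness       max       2 0.5881246 0.00125     0.9947743
#> 4 hessian_vesselness single_m1       2 0.5109376 0.00044     0.7841685
#> 5 hessian_vesselness single_m2       2 0.4904294 0.00080     0.7773701
```

`min` fusion propagates the dropout gaps (lowest DSC); `max` favours
continuity but accumulates the largest false-positive volume (see the
acceptance report below for that measure).

A thin command-line interface over the same functions is installed at
`inst/cli/vesselvote` (subcommands `extract`, `fuse`, `evaluate`,
`phantom`, `compare`), e.g.

```sh
Rscript inst/cli/vesselvote extract cta.nii.gz pcmra.nii.gz \
    --out phi.nii.gz --fusion cosine
```

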