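# fusionsynth

Multimodal MR image synthesis in R: predict a missing MRI contrast (e.g.
FLAIR) from two acquired contrasts (e.g. T1 and T2) with a layer-wise
attention fusion network trained adversarially, with self-supervised
pretraining of the per-modality feature extractors.

Clinical MR protocols rarely yield every contrast for every patient —
scanning time, cost and patient condition get in the way — yet the missing
contrast often carries diagnostic information the acquired ones hint at.
`fusionsynth` is for researchers in medical image computing who want a
fully inspectable, CPU-runnable implementation of this synthesis approach:
every layer (convolution, batch normalization, pooling, channel attention)
and its reverse-mode gradient is implemented in the package (C++ kernels +
R composition) and verified against finite differences, so the pipeline
has no deep-learning-framework dependency and every numerical claim in the
test suite is checkable.

## The model

Three stages, trained end to end after pretraining:

1. **Feature extraction** — one symmetric U-Net auto-encoder per source
   modality (two skip connections, conv+BN throughout, LeakyReLU encoder /
   ReLU decoder), supervised by a pixel-wise L1 reconstruction loss
   `L_Rec = Σ_i ‖x_i − x̂_i‖₁` and pre-trained with two self-supervised
   pretext tasks: masked-patch inpainting and slice-index regression
   (`L = Σ_i ‖x_i − x̂_i‖₁ + ‖y_i − ŷ_i‖₂²` on three adjacent slices).
2. **Fusion** — three multimodal attention feature fusion blocks (MAFFB).
   Each fuses the two modalities' unique features S⁽¹⁾, S⁽²⁾ by
   element-wise sum, product and maximum, stacks them
   (`F_concat ∈ R^{3C×H×W}`), gates channels with
   `M_c = σ(MLP(AvgPool) + MLP(MaxPool))`, and convolves together with the
   previous block's common features — giving common representations F₁–F₃.
3. **Generation** — a generator built from three further MAFFBs maps the
   common and unique features back to the target contrast; a pixel-level
   discriminator (raw patches) and a feature-level discriminator (Canny
   edge maps) supply non-saturating adversarial losses.  The composite
   objective is
   `L = L_pixel-adv + L_feature-adv + λ₁ L_GRec + λ₂ L_Rec`
   with λ₁ = 100, λ₂ = 10 by default.

Synthesis quality is scored by MSE, PSNR (peak = maximum intensity over
both images) and SSIM.  A seeded phantom generator produces co-registered
multimodal Gaussian-blob volumes whose target modality is a known smooth
function of the sources, so the whole pipeline is testable without
external data; a PCA interpretability module visualizes how the fused
"common" features sit between the two modalities' "unique" features.

## Worked example

```r
library(fusionsynth)

# a seeded multimodal phantom: two source contrasts + a target that is a
# known smooth function of them
spec <- phantom_spec(shape = c(12, 64, 64), background_margin = 6, seed = 1)
spec
#> phantom_spec: 12x64x64, 6 blobs, margin 6, rule 'blend', seed 1
case <- generate_case(spec, "case_01")
case$source1
#> volume [case_01/source1]: 12 slices of 64x64, range [0, 0.713]

# the four 32x32 inpainting masks cover a quarter of a 128x128 patch
m <- sample_masks(c(128, 128), 4, c(32, 32), seed = 1)
mean(m$mask)
#> [1] 0.25

# binary images differing on half their pixels: PSNR = 10*log10(2) dB
psnr(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 0, 1), 2))
#> [1] 3.0103

# full tiny-profile pipeline: pretraining, adversarial training,
# evaluation on the held-out case (several minutes on one CPU)
cfg <- default_config("tiny", seed = 1, output_dir = "run1")
res <- run_pipeline(cfg, visualize = TRUE)
res$metrics$case_02
#> MSE 0.0010341 | PSNR 26.19 dB | SSIM 0.965062 (n = 49152)
```

The held-out PSNR of 26.2 dB compares against 24.3 dB for simply copying
source 1 onto the target's intensity scale: the network has learned part
of the cross-modality mapping, not just the shared geometry.  `run1/`
contains stage checkpoints, a JSONL training log, PCA feature plots per
MAFFB and a manifest with the seed and split.

A command-line front end wrapping the same functions ships at
`inst/cli/fusionsynth.R`
(`make-phantoms | pretrain | train | synthesize | evaluate | visualize`).

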