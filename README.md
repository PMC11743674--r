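# msgunet

Lightweight multi-scale Ghost U-Net (MSGU-Net) for binary segmentation of
dermoscopic skin-lesion images, implemented natively in R.

Dermoscopy apps and bedside imaging devices need segmentation networks that
fit phone-class hardware. MSGU-Net is a U-shaped encoder–decoder that
replaces the standard double 3×3 convolutions with cheap composite blocks —
four-branch **SPP-Inception** (1×1 / 3×3 / 5×5 / max-pool→1×1, each branch
emitting `out/4` channels), **Ghost modules** (an intrinsic pointwise half
plus a depthwise "ghost" half, `Y = Concat(Y', Y' ∗ F_dp)`) gated by **DFC
attention** (a half-resolution sigmoid gate from 1×1 + (1,5) + (5,1)
convolutions), **ELA** (strip pooling `z_c^h(h) = 1/W Σ_w x_c(h,w)` →
depthwise 1-D conv (k=7) → 16-group norm → sigmoid, per axis:
`Y = x · y^h · y^w`) and **attention gates** on the skip connections
(`w = σ(ψ(ReLU(A·g + B·x)))`, one scalar per patch). Stage widths are
C1..C5 = 32/64/128/256/512; the head emits raw logits for a
BCE-with-logits loss.

The package is aimed at people who want to study, profile or reproduce this
family of lightweight segmentation architectures without a GPU stack: the
blocks are standalone testable units, the profiler reproduces the published
cost figures, and a seeded synthetic dermoscopy generator makes the whole
pipeline runnable offline. Everything — including reverse-mode automatic
differentiation over `(H, W, C, N)` arrays with compiled convolution
kernels, Adam, and a reduce-on-plateau scheduler — lives in this package.

## Worked example

```r
library(msgunet)

## cost profile ------------------------------------------------------------
net  <- buildMSGUNet(seed = 1)          # 32/64/128/256/512, RGB in, 1 logit out
base <- buildUNetBaseline(seed = 1)     # canonical U-Net, 64..1024
profileNetwork(net)
#> ProfileReport at input 3x256x256
#>   params: 1,224,397 (1.2244 M)
#>   MACs:   2,054,012,928 (2.0540 G, 1 FLOP per MAC)
#>   modules: 94
reductionReport(profileNetwork(net), profileNetwork(base))
#>   params     macs
#> 96.09876 96.31128

## train on synthetic dermoscopy and evaluate ------------------------------
ds  <- generateSynthetic(synthConfig(nSamples = 16, imageSize = 64, seed = 11))
cfg <- trainConfig(epochs = 100, batchSize = 8, seed = 11, augment = FALSE)
res <- trainNetwork(buildMSGUNet(seed = 11), ds, cfg)   # ~4 min on one core
evaluateNetwork(res$net, ds)
#> MetricsReport (16 images, threshold 0.50)
#>   DSC 0.9540 | mIoU(fg) 0.9123 | mIoU(2-class) 0.9357
#>   Acc 0.9731 | Sen 0.9874 | Spe 0.9630
```

The profile says the lightweight network carries 1.22 M trainable
parameters — 3.9% of the 31.38 M baseline (a 96.1% reduction) — and costs
2.05 GMACs per 256×256 image against the baseline's 55.68 GMACs. The
training run overfits 16 synthetic images in 200 iterations to a train DSC
of 0.95+, the desk-scale sanity check that gradients, loss and metrics all
cooperate end to end. A note on conventions: the profiler counts one FLOP
per multiply-accumulate (the convention under which the baseline's
published 55.84 figure reproduces); sources that count two FLOPs per MAC
will print twice the MSGU-Net number (2 × 2.054 ≈ 4.11). See the methods
vignette (`vignettes/msgunet-methods.Rmd`) for the full analysis.

## Command line

```sh
Rscript inst/scripts/msgunet.R synth   --n 16 --seed 1 --image-size 256 --out data/
Rscript inst/scripts/msgunet.R profile --model msgunet --input-size 256 --out profile.json
Rscript inst/scripts/msgunet.R train   --data-dir data/ --out run1/ --epochs 100
Rscript inst/scripts/msgunet.R eval    --checkpoint run1/checkpoint.rds --data-dir data/ --out metrics.json
```

Flags override YAML config values, which override the built-in defaults;
each run writes its merged effective configuration next to its outputs.

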