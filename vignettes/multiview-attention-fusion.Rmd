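---
title: "Multi-view attention fusion for key-region insect recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view attention fusion for key-region insect recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(camfuse)
```

## The problem and the method

Fine-grained insect recognition is hard because inter-species appearance
differences are subtle while intra-class variation (growth stages, pose,
background) is large. A useful observation is that different backbone
families attend to *different* parts of the same insect: a residual CNN
tends to highlight one contiguous local region, while ViT-style and
Swin-style transformers pick up finer, more scattered global structure.
Each view is partial; together they can cover the discriminative evidence.

camfuse implements that idea end to end:

1. **Grad-CAM per view.** For each of three backbones, the importance map is
   `ReLU(sum_k alpha_k A_k)`, where `A_k` are the activation channels at a
   target layer and `alpha_k` is the spatial mean of `d score / d A_k` (the
   neuron-importance weight). Transformer token outputs are first passed
   through a *patch transformation*: the `(K) x (C*)` token matrix is
   reshaped row-major into a `sqrt(K) x sqrt(K)` spatial map with `C*`
   channels (for the ViT-style model the class token is dropped first, so
   `K - 1` tokens form the grid). This reshape is what makes Grad-CAM
   applicable to attention models at all; it is a pure permutation and is
   exactly invertible.
2. **Attention-selection fusion.** The three maps enter a small image-fusion
   network (extract -> select -> reconstruct). CONV1 (7x7) and CONV2 (3x3),
   shared across views, produce per-view feature stacks `alpha_i^k`,
   per-channel min-max normalized. The selection rule combines, per channel
   and pixel, the *consensus* of the views with their *complement*:

   `fused_k = Eigen{ w0 * min_i alpha_i^k + w1 * (max_i alpha_i^k - min_i alpha_i^k) }`

   Intersection and union of continuous weights are read as elementwise
   min and max (the fuzzy-set interpretation; for values in [0, 1] no other
   pointwise reading is available). `Eigen{}` denoises the fused channel
   stack by replacing it with its leading rank-1 reconstruction. CONV3
   (3x3) tunes the selected features and CONV4 (1x1) reconstructs a
   3-channel image whose luminance, min-max normalized, is the fused map.
3. **Key regions.** Pixels whose normalized importance is at or above a
   threshold `tau` are kept; everything else is masked to black. The masked
   image, resized and flattened, is the feature vector of an SVM classifier
   -- the classifier only ever sees the evidence the backbones used.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `w0` | 1.0 | weight of the consensus (intersection) term |
| `w1` | 0.5 | weight of the complement (union minus intersection) |
| `eigen` | TRUE | rank-1 smoothing of the fused channel stack |
| `conv_channels` | 64/64/64 | CONV1..CONV3 output channels |
| `tau` | 0.5 | key-region threshold on the normalized map |
| `feature_side` | 64 px | resize edge of the SVM feature image |
| SVM | RBF, C = 1, gamma = "scale" | classifier stage defaults |
| split | 80/20 stratified | train/test protocol |

`w0 >= w1 >= 0` is enforced: consensus regions are always weighted at least
as strongly as single-view regions. The defaults `w0 = 1, w1 = 0.5` respect
that ordering while keeping single-view evidence above a `tau = 0.5`
threshold after normalization; all are config-exposed. The threshold is
read as *at or above* `tau` on the per-image min-max normalized map
(a relative threshold; absolute map magnitudes are not comparable across
backbones).

Two fusion modes exist. The `"network"` mode is the full conv pipeline
above. The `"map"` mode applies the selection rule directly to the raw maps
(`K = 1`), bypassing the convolutions; it is the convolution-free reference
used in the algebra tests and for analysis.

### Untrained fusion weights

The fusion network is usable without training: kernels are drawn
nonnegative (`|N(0,1)|`) and normalized to unit sum per output channel, with
zero biases, so CONV1--CONV3 act as an ensemble of random local averaging
filters and CONV4 as a random convex-ish recombination. Features then remain
faithful smoothed copies of the input maps, which keeps the min/max algebra
of the selection rule meaningful out of the box. Reference weights trained
on a multi-focus fusion task can be imported with `load_fusion_weights()`;
no test depends on them.

### Backbones at desk scale

The three backbone families are small, seeded variants of their full-size
namesakes: a residual CNN (stride-2 stages, each with a two-conv residual
block), a ViT-style model (patch embedding, class token, pre-norm blocks)
and a minimal Swin-style hierarchy (4x4 patch embedding, window attention
with one cyclic shift, three 2x2 patch mergings, so the output grid is
`H/32 x W/32` with `8 x embed_dim` channels). The classification head reads
the CAM target layer through global average pooling and (by default) a tanh
hidden layer; consequently the gradient of a logit with respect to the
target-layer activations has a closed form, which the test suite validates
against central finite differences at relative error 1e-3. The contribution
is the method around the backbones, not the weights: full-size pretrained
models are deliberately out of scope, and classification tests use the
*precomputed-map* pipeline mode so they do not depend on random-weight CAM
quality.

## What the synthetic generator emulates

`synthetic_dataset()` builds the study conditions for all end-to-end
claims: a textured ellipse ("insect") on a textured background, with class
identity carried by eccentricity, texture frequency and orientation --
whole-body cues, so recognition genuinely benefits from coverage. Gaussian
pixel noise (sd 0.08) keeps single patches from being trivially
sufficient.

The three per-image view maps emulate complementary CAMs: each highlights
one 150-degree sector of the ellipse (centers 120 degrees apart, random
global rotation per image), blurred and topped with low-level background
noise. By construction every single view covers under 60% of the body
(150/360 of the angular measure) while the union covers it all -- the
complementary-coverage structure that motivates fusion. Fusion superiority
on this task is therefore a *designed consequence* tested as a property,
not an empirical claim about real insect photographs. What passing tests
show is that the fusion machinery preserves and combines complementary
evidence as specified; what they cannot show is how much complementary
information real backbones extract from real images.

Robustness fixtures (`make_robustness_pairs()`) pair each scene with a
perturbed partner whose sector centers are jittered in *complementary
directions* (alternating signs, around 30 degrees), emulating how
augmentation deviates each backbone's attention differently; maps of both
members live in a common frame so thresholded-map IoU is directly
comparable. The partner image itself is a rotated copy (reflection
padding).

The quantitative fusion comparison uses the plain elementwise-*mean* rule
inside the *same* network (same CONV1--CONV4, same normalizations) as the
baseline, so the only difference is the selection rule -- mirroring a
comparison of an unmodified fusion framework against the attention-selection
modification. Spatial frequency is reported on the unit intensity scale and
average gradient on the 8-bit scale (the two conventions in which these
statistics are usually quoted).

## Numerical choices

- **Normalization.** CAMs are min-max rescaled per map after ReLU; an
  all-zero map stays zero (suppressed evidence is a legal outcome), a
  positive constant map becomes one. Per-channel normalization of CONV2
  features makes the selection algebra well-defined on [0, 1].
- **Resampling.** Bilinear, `align_corners = FALSE` (output pixel centers at
  `(i + 0.5) / n`), edge-clamped. Stated explicitly because fusion compares
  maps originating at different native resolutions.
- **Eigen smoothing** is computed as the projection of the `K x (u*v)`
  channel matrix onto its leading left singular vector (via the `K x K`
  cross-product eigendecomposition, which is exact and cheap); negatives are
  clipped. Applied across the channel stack, not per 2-D channel -- the
  per-channel alternative would be the identity for `K = 1` slices and
  smooth nothing.
- **Geometric augmentation** uses reflection padding and bilinear
  interpolation; the shift limit (-0.65, 0.65) is read as a fraction of
  each image dimension (a pixel reading of that interval would be
  degenerate), drawn per axis; the blur kernel is an odd integer in {3, 5,
  7} with the usual kernel-size-to-sigma heuristic; brightness/contrast is
  `out = (in - 0.5)(1 + contrast) + 0.5 + brightness`; sharpening is the
  unsharp blend `out = (1 - alpha) in + alpha (in + lightness (in -
  blur(in)))`. Application order is the fixed listing order of
  `augmentation_specs()` for determinism.
- **Reports** round percentages to one decimal; macro averaging over
  classes, with empty-prediction classes contributing zero precision/F1.
  The SVM stage standardizes per feature on the training split only;
  multi-class handling is libsvm's pairwise voting.
- **Determinism.** Every stochastic entry point takes a seed and restores
  the caller's RNG state; report artifacts contain no timestamps, so a rerun
  of the same configuration is byte-identical.

## Problem sizes used by the checks

The end-to-end classification property runs 3 classes x 100 images at
64 x 64 over three dataset seeds with an 80/20 stratified split; robustness
uses 50 pairs; metric comparisons use 50 fixtures; oracle suites use
100--1000 random cases each. These sizes make every directional claim
measurable on one CPU core in a few minutes.

## A small worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(n_classes = 3, per_class = 20, image_side = 64,
                       seed = 1)
manifest <- synthetic_dataset(spec, tempfile("camfuse_demo_"))
cfg <- pipeline_config(manifest, split = split_spec(0.8, TRUE, 1))
fused <- run_pipeline(cfg)
single <- run_pipeline(modifyList(cfg, list(views = "cnn")))
glance(fused)
glance(single)
```

```{r plot, eval = FALSE}
sc <- synthetic_scene(spec, class_id = 1, scene_seed = 42)
autoplot(fuse_cams(sc$views, fusion_config(), mode = "network"))
```

## Known limitations

- The tiny backbones have random (seeded) weights; their CAMs locate
  class-agnostic structure at best. All classification claims therefore run
  in precomputed-map mode; backbone mode is exercised for contract
  correctness, not accuracy.
- The Swin-style model realizes window attention and one shift minimally;
  its fidelity target is the output tensor contract (`H/32` grid, `8C`
  channels), not Swin internals (no attention masks at shifted borders, no
  relative position bias).
- The selection rule's benefit depends on views being complementary; with
  three near-identical views it degenerates (by design) to `w0 * alpha`.
- One insect per image is assumed; multi-object scenes would need
  per-instance maps before fusion.
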