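# camfuse

Multi-view class-activation fusion for fine-grained insect recognition.

Fine-grained insect classification suffers from subtle inter-species
differences and large intra-class variation (egg, larva, pupa, adult).
Different backbone families attend to different, partial parts of the same
insect: residual CNNs highlight contiguous local regions, transformer
models pick up scattered global structure. camfuse is for researchers in
image-based ecology and agricultural monitoring who want to exploit that
complementarity: it localizes each backbone's evidence with Grad-CAM,
fuses the per-view importance maps with an attention-selection mechanism,
and classifies only the resulting *key regions*.

## The method

For backbone view `i`, Grad-CAM weights each activation channel `A_k` at a
target layer by the spatially pooled gradient of the class logit,
`alpha_k = mean(d y_c / d A_k)`, and the importance map is
`ReLU(sum_k alpha_k A_k)`, min-max normalized. Token outputs of the
ViT-style and Swin-style backbones are first reshaped by a *patch
transformation* into `sqrt(K) x sqrt(K)` spatial maps (dropping the class
token for ViT), which is what makes Grad-CAM applicable to attention
models.

The three maps are fused by an attention-selection rule inside a small
image-fusion network (CONV1/CONV2 shared feature extraction, selection,
CONV3 tuning, CONV4 3-channel reconstruction). With per-view feature
weights `alpha_i^k` in [0, 1]:

```
fused_k = Eigen{ w0 * min_i alpha_i^k  +  w1 * (max_i alpha_i^k - min_i alpha_i^k) }
```

intersection/union read as elementwise min/max, `w0 >= w1 >= 0`, and
`Eigen{}` a rank-1 smoothing of the fused channel stack. Pixels of the
fused map at or above a threshold `tau` are kept; the rest are masked to
black, and the masked image feeds an RBF-kernel SVM. Fusion quality is
quantified by spatial frequency (SF) and average gradient (AG);
classification by macro F1/recall/precision and accuracy.

## Worked example

```r
library(camfuse)

spec     <- synthetic_spec(n_classes = 3, per_class = 20, image_side = 64, seed = 1)
manifest <- synthetic_dataset(spec, tempfile("camfuse_demo_"))   # images + 3 view maps each
cfg      <- pipeline_config(manifest, split = split_spec(0.8, TRUE, 1))

fused  <- run_pipeline(cfg)                                      # fuse all three views
single <- run_pipeline(modifyList(cfg, list(views = "cnn")))     # one view only

glance(fused)
#> # A tibble: 1 x 8
#>   views        mean_kept config_hash          f1 recall precision accuracy     n
#>   <chr>            <dbl> <chr>             <dbl>  <dbl>     <dbl>    <dbl> <int>
#> 1 cnn+vit+swin     0.299 1bd2f5253c317926...  91.5   91.7      93.3     91.7    12

glance(single)
#> 1 cnn              0.123 40cbff366e05c4f0...  54.4   58.3      57.9     58.3    12
```

The synthetic task is built so that each view covers under 60% of the
insect body while the union covers all of it: the fused key region keeps
about 30% of the image (the whole body) versus 12% for a single view, and
held-out accuracy rises from 58.3 to 91.7 on this 60-image toy run.
`ablation()` tabulates every view subset; `robustness_check()` reports how
stable thresholded maps are across perturbed image pairs; `autoplot()`
renders maps, key regions and reports.

A command-line front end with `synth / cam / fuse / extract / augment /
metrics / run / robustness` subcommands is installed at
`inst/cli/camfuse.R`.

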