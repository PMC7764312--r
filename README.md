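# sauseg — split-attention nested U-Net segmentation of 3D brain MRI

`sauseg` is a pure R + Rcpp implementation of a three-dimensional
split-attention nested U-Net for whole-brain multi-label segmentation,
together with the complete pipeline around it. It targets researchers who
want an auditable, CPU-only, dependency-light reference implementation of
this architecture family — every layer, gradient, and pipeline stage is
plain code in this package (no torch/tensorflow), verified against finite
differences and independent oracles.

## What it implements

* **Architecture** — a nested (dense skip pathway) encoder–decoder. Node
  `x^{p,q}` at pyramid level `p` consumes all same-level predecessors plus
  the upsampled deeper node; convolution units are 3×3×3 convolutions with
  EvoNorm-S0, `y = γ · x σ(vx) / sqrt(Var_g(x) + ε) + β`; skip-pathway
  outputs pass through a ResNeSt block with split attention (cardinality
  K = 2, radix R = 2, G = K·R = 4 feature groups, per-channel softmax over
  the R splits); a 1×1×1 classifier head with per-voxel softmax over N = 34
  classes (33 structures + background).
* **Pre-processing** — pluggable rigid-registration contract (256³
  template grid), zero padding (16 train / 24 test), Nyúl-style
  histogram-landmark intensity standardization.
* **Augmentation** — Gaussian noise (sd ∈ [0, 0.2]), polynomial bias field
  (coefficients ∈ [−0.5, 0.5]), random affine (scale ∈ [0.9, 1.1],
  rotation ∈ ±10°), elastic deformation from a 7³ control grid.
* **Training** — random 96³ patches, cross-entropy, AdamW + AMSGrad
  (lr 0.001 pre-train / 0.0001 fine-tune, batch 4), and the two-step
  strategy: pre-train on auxiliary labels, fine-tune on manual labels.
* **Inference** — patch plans covering the padded volume (grid stride
  `96 − 12 = 84`, or 128 random patches with coverage repair), OR-logical
  label fusion (background never beats a structure claim; conflicts go to
  the largest summed probability), and mapping back to native space.
* **Metrics** — Dice, average symmetric surface distance (mm), structure
  volumes (cc), intra-session CV (`CVs_avg`) and total CV (`CVt`) in
  percent.
* **Phantoms** — a deterministic generator of T1-like volumes (nested
  bilateral ellipsoids, per-tissue intensities, noise, multiplicative bias
  field), corrupted "auxiliary" labels, test–retest pairs and multi-center
  sets, so the whole pipeline is testable with no imaging data.

## Worked example

```r
library(sauseg)

# a 64-voxel desk phantom: 8 bilateral structures in 2 hemispheric shells
spec <- default_phantom_spec(seed = 1)
ph   <- make_phantom(spec)
ph$volume
#> <volume3d> 64 x 64 x 64, spacing 1 x 1 x 1 mm
#>   intensity range [-0.3595, 1.12]

# train the desk preset (3 levels, 8 base channels) on 4 phantoms
phs  <- lapply(1:4, function(i) make_phantom(default_phantom_spec(seed = i)))
lm   <- learn_landmarks(lapply(phs, `[[`, "volume"))
prep <- function(p) list(
  volume = pad_volume(standardize_intensity(p$volume, lm), 4L),
  labels = pad_volume(p$labels, 4L))
ck <- run_stage(
  train_config("pretrain", iterations = 150L, patch_size = 32L,
               network = desk_network_config(n_classes = 9L),
               augment = NULL, balanced_sampling = TRUE, seed = 7L),
  lapply(phs, prep))
tail(ck$loss_trace, 3)
#>     iteration      loss
#> 148       148 0.4419303
#> 149       149 0.3772288
#> 150       150 0.4314903

# segment a held-out phantom and evaluate against ground truth
held <- make_phantom(default_phantom_spec(seed = 99))
seg  <- segment_volume(ck, held$volume, spec$schema,
                       pipeline_config(pad = 4L, patch_size = 32L,
                                       landmarks = lm))
rep  <- evaluate_report(seg, held$labels)
round(attr(rep, "summary"), 3)
#> dice_mean   dice_sd assd_mean   assd_sd
#>     0.200     0.370    15.272    10.408
```

The loss is the per-voxel cross-entropy (ln 9 ≈ 2.20 at random
initialization for 9 classes); `dice_mean` is the unweighted mean Dice
over the 8 foreground structures; `assd_mm` is the mean boundary distance
in millimeters. This 150-iteration run is deliberately tiny — it shows the
API, and that the large structures are already being found while the small
ones are not yet. Trained as in the acceptance experiment (20 phantoms,
same desk network), held-out mean foreground Dice is 0.305 after 250
iterations, 0.457 after 500, 0.687 after 750, and **0.901 after 1,000
iterations** (~40 CPU-minutes), crossing the 0.80 recovery target well
inside the 2,000-iteration cap of the desk protocol.

## Command line

```sh
Rscript inst/cli/sauseg phantom --out out/
Rscript inst/cli/sauseg preprocess --in t1.nii.gz --out std.nii.gz --pad 24
Rscript inst/cli/sauseg segment --ckpt model.rds --in t1.nii.gz --out seg.nii.gz
Rscript inst/cli/sauseg evaluate --pred seg.nii.gz --truth gt.nii.gz --out report.csv
```

## Documentation

The methods vignette (`vignettes/sauseg-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with its default and origin,
what the phantom generator does and does not emulate, the numerical
choices (float32 convolutions, boundary conventions, fusion tie-breaks),
and known limitations.
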