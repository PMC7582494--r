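# pointattn

Attention-weighted edge convolution networks for 3-D point sets, in R.

Point clouds — unordered sets of N points in space — are the working
representation for everything from CAD models and LIDAR scans to
macromolecular densities extracted from electron cryo-tomography. Networks
that classify or segment them typically treat every point and every feature
channel as equally informative, which blurs exactly the small characteristic
regions (a corner, a strap, a binding interface) that distinguish similar
objects. `pointattn` implements a point-set architecture that addresses this
with two attention mechanisms layered onto dynamic-graph edge convolution,
together with everything needed to train, evaluate, and probe it on
synthetic data: exact hand-written gradients, an SGD trainer, robustness
protocols, metric evaluators, point-cloud generators and file I/O. It is
aimed at method developers who want a fully inspectable, dependency-light
reference implementation of channel- and point-attention for point sets.

## The model

The trunk is a stack of **channel-weighted edge convolutions**. One layer,
for each point *x<sub>i</sub>*:

1. a kNN query groups *x<sub>i</sub>* with its k−1 nearest neighbors
   (recomputed per layer — on coordinates or in the current feature space);
2. each edge is lifted by a shared MLP h<sub>Θ</sub>(x<sub>j</sub>−x<sub>i</sub>, x<sub>i</sub>)
   with batch normalization and a leaky-ReLU activation;
3. a **squeeze-and-excitation gate** rescales every feature channel by a
   learned scalar s<sub>c</sub> ∈ (0,1) — full channel width, no bottleneck
   reduction;
4. a max over the group aggregates neighbors:
   x<sub>i</sub><sup>CW</sup> = max<sub>j</sub> F<sub>se</sub>(h<sub>Θ</sub>(x<sub>j</sub>−x<sub>i</sub>, x<sub>i</sub>)).

A second branch computes a **global attention mask**: the first layer's
grouping is re-described by the 10-channel geometric descriptor
{x<sub>i</sub>, x<sub>j</sub>, x<sub>j</sub>−x<sub>i</sub>, ‖x<sub>j</sub>−x<sub>i</sub>‖₂},
mapped through a two-stage shared MLP and a sigmoid, and reduced by a max
over each group — one soft weight per point in (0,1). The per-point global
feature g (built from the concatenated layer outputs through a gated MLP) is
multiplied by this mask and rectified, g<sub>m</sub> = ReLU(g · mask), before
max- and average-pooling feed the classification head. The segmentation head
tiles the object's one-hot category alongside g<sub>m</sub> and its pooled
summary and scores every point over the part vocabulary. Two alternative
attention modules — a hard (boolean, thresholded at 0.5) mask and a
spatial-attention edge convolution whose mask branch uses the distance-free
9-channel descriptor — are included for comparison.

Training follows the point-set convention: SGD with momentum, initial
learning rate 0.03 annealed by lr(e) = 0.015·(1 + cos(πe/E)) to zero, and
augmentation by per-cloud translation in [−0.2, 0.2], anisotropic scaling
and point shuffling (no rotation — so rotation robustness can be probed on a
model that never saw rotated data).

## A worked example

```r
library(pointattn)

# 4 shape classes (sphere, cube, torus, cylinder), 256 points per cloud
ds <- make_dataset(4, 125, split = 0.8, seed = 1, n = 256)

cfg <- classifier_config(n_classes = 4, layers = c(16L, 16L, 32L), k = 20L,
                         global_width = 64L, mask_hidden = 32L,
                         head = c(32L, 16L), graph = "coords")
model <- init_classifier(cfg, seed = 1)
set.seed(1); vi <- sample(length(ds$train), 40)
fit <- train_model(ds$train[-vi], model,
                   train_config(epochs = 30, seed = 1, early_stop_oa = 100),
                   val = ds$train[vi], verbose = TRUE)
#> epoch   0  lr 0.03000  loss 1.2610  train OA 47.2%  val OA 50.0%
#> epoch   1  lr 0.02992  loss 0.8407  train OA 62.8%  val OA 100.0%

evaluate_model(ds$test, fit$model)
#> <eval_report> n=100  OA=99.00%  mean class acc=99.00%

# which points does the model consider characteristic?
w <- export_attention(ds$test[[1]], fit$model)
range(w)
#> [1] 0.01402059 0.99180539

# robustness without retraining: rotation about the gravity axis
perturb_eval(ds$test, fit$model, rotations = c(0, 10, 20, 30))
#>   protocol level model oa mean_class_acc
#> 1   rotate     0     1 99             99
#> 2   rotate    10     1 98             98
#> 3   rotate    20     1 97             97
#> 4   rotate    30     1 93             93
```

The printed numbers are what the code produces on this machine for seed 1:
training converges within a couple of epochs on the toy task, held-out
accuracy is near-perfect, and accuracy degrades gracefully with rotation
angle — the model was never shown rotated clouds.

A command-line interface wrapping the same functions is installed under
`inst/cli/pointattn.R` with subcommands `fixtures`, `train`, `eval`,
`perturb-eval` and `export-attention`.

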