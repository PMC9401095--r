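---
title: "Methods: a dual-pipeline attention network for capsule-endoscopy frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-pipeline attention network for capsule-endoscopy frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wireless capsule endoscopy (WCE) produces hours of low-resolution video of
the gastrointestinal mucosa in which pathological findings — ulcers,
erosions, blood, angiectasia, lymphangiectasia — occupy a small fraction of
frames and often a small fraction of pixels within a frame. Two properties
make frame classification hard: the images lack the resolution of
conventional endoscopy, and a lesion is defined as much by its *relation to
the surrounding mucosa* (a pale patch inside reddish tissue, a saturated red
region against pink) as by its own appearance. `ratcapsnet` implements a
convolutional classifier designed around both difficulties, together with
the data protocol needed to train it on heavily class-imbalanced data, a
seeded synthetic-image generator so the whole stack is testable offline,
evaluation metrics, and a CLI.

Because no deep-learning framework ships with this R stack, the network —
convolutions, depthwise and transposed convolutions, pooling, dense layers,
and full backpropagation — is implemented natively (RcppArmadillo, BLAS
`gemm` through chunked im2col buffers). The backward pass of every block is
verified against central-difference numerical gradients in the test suite,
which is the load-bearing correctness argument for everything trained here.

## The model

The network has three cooperating parts.

**Compression pipeline.** A chain of `num_stages` (default 5) encoder
stages. Stage $l$ applies two same-padded $3\times3$ convolution blocks
(convolution + LeakyReLU, slope $\alpha = 0.1$) producing the *registered
tap* $X_r \in \mathbb{R}^{H\times W\times C}$, where the channel rule sets
$C = n$ (default $n = 32$) for the RGB input and $C = 2C_0$ afterwards —
so the channel sequence is $32, 64, 128, 256, 512$. An attention block (below)
produces $F$, and a $2\times2$ stride-2 max-pool halves the spatial dims.
After stage 5 a $H/32 \times W/32 \times 16n$ tensor is globally
average-pooled into $\tilde{y}_5 \in \mathbb{R}^{16n}$.

**Volumetric attention (VAM).** Inside each stage, between the second
convolution and the pool:

1. *spatial condensation*: $3\times3$ stride-2 convolution to $C/2$
   channels, $x_s \in \mathbb{R}^{H/2\times W/2\times C/2}$;
2. *channel-wise filtering*: depthwise $3\times3$ refinement $x_c$ of $x_s$;
3. volumetric map $x_v = x_s \oplus x_c$;
4. a $3\times3$ stride-2 **transposed** convolution (contracted to produce
   *exactly* $H \times W$), LeakyReLU, then a sigmoid, giving the
   single-channel mask $X_m \in [0,1]^{H\times W\times 1}$;
5. residual enhancement $F = X_r \oplus (X_r \otimes X_m)$, the mask
   broadcast across all $C$ channels.

Algebraically $F = X_r\,(1 + X_m)$ entrywise, which the tests assert to
1e-6; a closed gate ($X_m \approx 0$) reduces the block to the identity.
Note the pre-sigmoid LeakyReLU: the upsampling block is defined as
transposed convolution *followed by* LeakyReLU, and the sigmoid is applied
to its output. The composition $\sigma(\mathrm{LReLU}(\cdot))$ is monotone
and keeps the $[0,1]$ range, so the mask semantics are unchanged; we follow
the printed definition literally.

**Regional-correlative pipeline.** The taps of stages $l \in \{2,3,4,5\}$
feed a Pyramid Feature Extractor: four parallel convolution blocks with
kernels $1/3/5/7$ at $\varrho$ channels each (default $\varrho = 16$);
adjacent pairs concatenated to $2\varrho$ channels; each pair fused by a
block with kernels $8/9/10$; the three results concatenated ($6\varrho$) and
fused to $2\varrho$ by a kernel-11 block. Spatial dims are preserved
throughout, then each $P_l$ is globally average-pooled to
$\tilde{p}_l \in \mathbb{R}^{2\varrho}$.

**Decision pipeline.** $[\tilde{y}_5, \tilde{p}_2,\dots,\tilde{p}_5]$
(length $16n + 4\cdot2\varrho = 640$ at defaults) passes through dense
layers of 512 and 128 units with LeakyReLU, then a softmax over
`num_classes` (or a single sigmoid unit for binary tasks).

## Design choices where the design was open

* **$\varrho$ and the fusion widths.** The pyramid width is not pinned by
  the reference design; we default $\varrho = 16$ and fix every fusion
  block's output at $2\varrho$, which makes the final fusion consume
  $6\varrho$ and produce the documented $2\varrho$. With these choices the
  default model has **10,468,838** trainable parameters — the same order as
  the reference design's reported 9.56 M, which cannot be matched exactly
  because those widths are unspecified. The count is asserted in the tests
  and is invariant to the input size (all-convolutional body + global
  pooling).
* **Even kernels 8/9/10.** Implemented literally with same padding; when the
  total padding is odd the extra pixel falls bottom/right (the TensorFlow
  convention). An odd-kernel pyramid would be a one-line change but is not
  what the printed operation says.
* **Exactly-doubling transposed convolution.** Implemented as the adjoint of
  a stride-2 same-padded convolution mapping $2H \to H$; this is a shape
  *contract* (asserted by an adjoint-identity test), not a mechanism
  requirement.
* **The undefined parameter $N$.** The regional pipeline is said to require
  a parameter $N$ that is never defined (plausibly the number of pyramid
  blocks). We do not guess: the configurable object is the stage set
  `pfe_stages`.
* **Input size.** The native 336×336 of the public WCE dataset is not
  divisible by $2^5$; the default input is 256×256 with bilinear resampling,
  enforced at config validation.
* **Training hyperparameters.** Loss (cross-entropy), optimizer (Adam,
  1e-4), batch size 32, early stopping on validation loss with patience 10 —
  none are stated by the reference; all are `run_config()` fields. Short
  smoke runs in the tests use Adam's canonical 1e-3 with an explicit
  training-accuracy stop.

## The data protocol

For imbalanced class directories the split is *smallest-class-referenced*:
the smallest class is split 80/20, and its 20 % count $v$ becomes the
validation size drawn uniformly (without replacement) from **every** class,
so validation sets are equal-sized and the metric is not dominated by the
majority class. The protocol sentence describing the other classes' 20 % is
garbled in the reference text; we implement the equal-size reading and note
the alternative (20 % of each class) without guessing it. Remaining items
form each class's training pool — large classes are *not* subsampled first;
balancing happens at the next step, which preserves data while matching the
stated per-class target.

Each pool is then upsampled to a common target (default 3000) by pairing
uniformly re-drawn identifiers with random augmentation recipes: rotation
(±180°), flips, shear (±15°), smooth random warping, random erasing
(2–10 % area), additive Gaussian noise (σ 0.01–0.05) and Gaussian blur
(σ 0.5–1.5). "Wrapping" in the reference's augmentation list is read as
spatial warping, consistent with its grouping under positional
augmentation. Ranges are package defaults (the reference states none);
every operator preserves shape and the $[0,1]$ range, geometric operators
fill borders by reflection, and every recipe is deterministic under its
seed, so a split manifest fully reproduces the training stream.

## What the synthetic generator does and does not establish

`generate_image()` draws a textured pink-red mucosa (low-frequency
multiplicative noise over a jittered base tone) inside a circular
field-of-view vignette, then composites one lesion per abnormal class:
blood = large saturated-red blob (10–30 % area), ulcer = pale centre with a
red rim, erosion = small pale patch, angiectasia = thin tortuous red mark,
lymphangiectasia = small white dot. Default resolution is 64×64 so CPU
training stays within minutes. These morphologies claim *no clinical
fidelity*; they are chosen for visual plausibility and small-scale
separability (blood-vs-normal is nearly linearly separable by design, and a
test asserts the red-saturation gap over 100 seeds). Consequently a green
learning-sanity test establishes that the implementation *can optimize and
generalize on a separable task* — it says nothing about accuracy on real
capsule-endoscopy data, which would require the external dataset and
GPU-scale training that are out of scope here.

## Numerical choices

* Zero-denominator metrics are reported as 0 with a `degenerate` flag
  rather than raising, so batch evaluation never aborts; multi-class
  results are one-vs-rest with macro averaging.
* Contrast stretching for visualization is per-image min-max; a constant
  map renders mid-gray.
* Max-pool ties resolve to the first element in column-major window order;
  LeakyReLU's subgradient at 0 uses the negative slope.
* He-normal initialization throughout; every random draw in the package
  flows through a single seed via an RNG-state-preserving `with_seed()`.
* im2col buffers are chunked at ~64 MB so a 256×256 forward pass stays
  well inside an 8 GiB budget.

## Known limitations

Single-image (no batched) tensor ops — throughput is adequate for the
desk-scale configurations tested here but far from a GPU framework;
training at the default 256×256/width-32 configuration is intentionally out
of scope. The protocol's garbled-sentence alternative reading, the exact
reference parameter count, and photorealistic capsule artifacts
(specularities, bubbles, video compression) are documented non-goals.
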