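---
title: "FESW-UNet: model, blocks and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FESW-UNet: model, blocks and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Aphids colonise sorghum leaves in small, dense, low-contrast clusters.
Segmenting them pixel-wise from field photographs is hard for exactly the
reasons that make the imagery hard to look at: strong vein texture, uneven
illumination, specular glare, cast shadows, and foreground objects only a
few pixels across. `feswunet` implements FESW-UNet, an encoder--decoder
network that attacks these difficulties jointly in the spatial and
frequency domains.

The backbone is the canonical U-Net: five double-convolution stages
(3x3 conv + batch norm + ReLU, twice) with widths 64-128-256-512-1024,
four 2x downsampling steps, 2x2 transposed-convolution upsampling with
skip concatenation, and a 1x1 classifier to two classes (background,
aphid). Onto this, four blocks are grafted:

* **SimAM** (after every encoder stage) computes, for each neuron $t$ of a
  channel, the closed-form minimum of an energy that measures how linearly
  separable the neuron is from the other $M-1$ neurons of its channel:
  $$e^*_t = \frac{4(\sigma_t^2+\lambda)}{(t-\mu_t)^2+2\sigma_t^2+2\lambda},$$
  with $\mu_t, \sigma_t^2$ the mean and population variance of the
  remaining neurons. Attention is $\mathrm{sigmoid}(1/e^*) \odot X$.
  The block has no learnable parameters.
* **EMA** (bottleneck) splits the 1024 channels into $g$ groups and, per
  group, combines directional (height/width) average pooling through a 1x1
  convolution with a parallel 3x3 convolution; softmax-weighted channel
  descriptors of each branch are contracted against the spatial maps of
  the other, and their sigmoid re-scales the group.
* **HWD** replaces every max-pool with an orthonormal single-level 2-D
  Haar decomposition (four subbands, channel-stacked, lossless and
  energy-conserving) followed by a learned 1x1 conv + BN + ReLU head
  mapping $4C \to C$.
* **FEAM** (deepest skip connections) stores complex spectral weights
  $W_s = \alpha_s + j\beta_s$ on nominal $s \times s$ grids, projects them
  bilinearly to the feature resolution, and modulates each channel in the
  unitary FFT domain, $X^{freq}_s = \Re\,\mathcal F^{-1}(\mathcal F(X)
  \odot \tilde W_s)$, alongside a spatial pixel gate $\tilde\alpha_s
  \odot X$; branches are averaged over scales and passed through a
  channel gate (average+max pooled descriptors, shared $C \to C/r \to C$
  bottleneck, sigmoid).

Everything -- forward pass, reverse-mode gradients, Adam, the hybrid
cross-entropy + Dice loss -- is implemented in the package itself
(compiled single-precision im2col/GEMM kernels for the convolutions,
vectorised R elsewhere), since the network's internals are the point of
the package.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `simamLambda` | `1e-4` | energy regulariser; larger values flatten the attention map toward sigmoid(0.5) |
| `emaGroups` | 8 | channel groups at the 1024-wide bottleneck (so the shared convs are 128 -> 128); 8 uniquely reproduces the published +EMA size increment of 0.165 M |
| `feamCount` | 2 | FEAM blocks, attached deepest-first; 2 is the published best accuracy/speed point |
| `feamScales` | `[30,60], [60,120], [120,240], [240,480]` | nominal spectral grid sizes per block, matched to skip resolutions at 480x480 input |
| `feamGateReduction` | 4 | channel-gate bottleneck; 4 reproduces the published per-block gate increments (0.131/0.033/0.009/0.002 M) |
| `feamInit` | `"identity"` | $\alpha = 1, \beta = 0$, so an untrained FEAM is a benign 2x residual-like pass and the identity property is the literal initial state |
| `downsample` | `"hwd"` | `"maxpool"` recovers the classical U-Net |
| loss | CE + Dice, equal weights | standard hybrid for heavily imbalanced binary masks |
| learning rate | `1e-4` | Adam, constant |

Bias conventions (exposed as `convBias`, `upBias`, `hwdBias`): biases off
on convolutions that feed a batch norm, on for transposed convolutions and
the HWD head. Under these conventions the baseline counts 31,037,698
parameters (31.038 M), within 0.03% of the published 31.031 M; the
residual is attributable to unstated bias conventions and is documented
rather than tuned away.

## Design choices made where the design was open

* **SimAM statistics.** The energy's closed form is only *exactly* the
  minimiser when the statistics describe the same neuron set the energy
  sums over. We therefore use per-neuron leave-one-out statistics (mean
  and population variance of the other $M-1$ neurons, i.e. an $M-1$
  divisor). This keeps three properties simultaneously: the closed form
  agrees with brute-force minimisation of the canonical energy to 1e-5
  (a unit test, not an assumption), constant channels get energy exactly
  2 and weight sigmoid(0.5), and the block stays parameter-free. The
  widely-circulated implementation shortcut (channel-wide statistics for
  all neurons) differs from this by $O(1/M)$ and is *not* an exact
  minimiser, which is why it was not adopted.
* **FEAM parameter accounting.** The published per-block size increments
  are numerically consistent with the channel gates alone (r = 4, biases
  on) and leave no room for the spectral grids, suggesting the reference
  implementation did not register them as parameters. Here the grids are
  genuine learnable parameters -- gradients flow to $\alpha$ and $\beta$,
  verified by finite differences -- and are counted. Consequence: FEAM x k
  totals still increase strictly in k, but the *increments* grow again
  beyond two blocks (the grids quadruple per shallower skip while the
  gates shrink 4x), unlike the printed sequence. The full model counts
  32.807 M vs the published 32.756 M (+0.16%).
* **Frequency-domain conventions.** Full complex spectrum (not a
  Hermitian half-spectrum) with unitary normalisation; the real part is
  taken after the inverse transform to restore realness explicitly.
  Frequency bins are in native FFT order with DC at index (1,1); weight
  grids are defined in that ordering and no fftshift is applied anywhere.
* **Bilinear projection** of the weight grids uses the align-corners
  convention, making projection the exact identity at the stored size and
  constant-preserving (both unit-tested).
* **Haar conventions.** Orthonormal $1/\sqrt2$ filters (so energy
  conservation is exact, not approximate); subband order A, horizontal,
  vertical, diagonal, where "horizontal detail" is the high-pass response
  along the width axis; even spatial dimensions are required rather than
  padded (all working resolutions are divisible by 16).
* **EMA normalisation** uses one group per channel (per-channel instance
  normalisation) with affine parameters -- the affine 2c parameters are
  required to reproduce the published +EMA increment exactly.
* **Zero-division rule** for metrics: a class absent from both prediction
  and reference contributes a vacuously perfect 1 to the macro averages
  (`absent = "perfect"`); `absent = "skip"` drops it instead. Accuracy is
  pooled (trace over total), which matches the magnitude relationships of
  the published results (accuracy far above mPA).
* **Checkpoint format**: RDS with the full configuration embedded, so a
  checkpoint reconstructs its exact model.

## The synthetic scene generator

Real field datasets are large, external downloads; every test in this
package instead runs on synthetic scenes (`synthScene()`) that emulate the
difficulty axes the field imagery is described by: a green leaf base with
sinusoidal vein striping at random orientation, a directional illumination
gradient, optional half-plane cast shadow, Gaussian speckle, and between
one and four aphid clusters rendered as unions of overlapping random
ellipses at a deliberately small intensity offset (low contrast), with
per-seed variation in density and placement. The mask is the exact
ellipse union, and the generating ellipse parameters are exposed so tests
can validate the rasterised area against an independent Monte-Carlo
geometric oracle.

What the generator does *not* reproduce: real leaf geometry and
out-of-plane curvature, specular highlights, true aphid texture and
occlusion boundaries, JPEG artefacts, and the long-tailed cluster-size
distribution of real infestations. Passing tests therefore demonstrate
that the architecture, gradients, metrics and training loop are correct
and that the model can fit data with the described statistical structure;
they say nothing about segmentation accuracy on real field imagery, which
requires the external datasets and GPU-scale training (the published
68.76% / 81.22% mIoU figures are shipped only as reference values in
`publishedBenchmarks()`).

## Numerical and scale choices

Convolution arithmetic is single-precision (sgemm); everything else is
double. Eval-mode inference is bitwise deterministic. Finite-difference
tests of gradients that cross the compiled convolutions use step sizes
and tolerances appropriate for float32 (relative ~1%); purely
double-precision paths (SimAM, FEAM, EMA algebra, loss) are checked to
1e-4 or tighter.

Test problem sizes are chosen for a single-CPU workflow: unit tests run
blocks at 4--16 pixel resolutions where oracles are cheap; the ablation
grid runs one forward pass per variant at the full 480x480 working
resolution; the overfit sanity run trains the full 32.8 M-parameter model
on eight 64x64 scenes for up to 200 Adam steps (batch 1, lr 1e-3 -- a
constant 1e-4 also converges but needs more steps than a sanity check
warrants), stopping as soon as training mIoU exceeds the required 0.9
(with the pinned seed this happens around step 120, at mIoU ~0.92). At 64x64 the deepest skips are 8x8 and
16x16, so that configuration uses proportionally scaled FEAM grids
([4,8], [8,16]); parameter-count checks always use the nominal 480-scale
grids.

## Known limitations

* CPU-only; single-threaded BLAS throughput bounds training speed, so the
  package is a faithful, testable implementation and a small-scale
  training tool, not a production trainer for the full datasets.
* Input spatial dimensions must be divisible by 16; no implicit padding.
* Two classes; multi-class pest taxonomies are out of scope.
* JPEG images are not read (no JPEG reader in the dependency set); PNG
  and TIFF are supported.
* The published headline accuracies and FPS figures are not recomputed:
  the former need external data and GPU training (and an unpublished
  loss/learning-rate), the latter are hardware-specific.
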