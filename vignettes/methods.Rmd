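---
title: "Adversarial de-aliasing of undersampled MRI: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial de-aliasing of undersampled MRI: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
acquisition and reconstruction model, the network and loss design, the
parameters that matter, what the synthetic data do and do not emulate,
and the numerical decisions taken where the design was genuinely open.

## The reconstruction problem

An MR scanner samples the spatial-frequency (k-space) representation of
the image line by line; scan time scales with the number of phase-encode
lines acquired. Undersampling k-space by a factor of 3–10 shortens the
scan proportionally, but the zero-filled inverse transform of the
undersampled data is corrupted by aliasing. `csgan` treats de-aliasing as
a supervised image-to-image problem with an adversarial refinement term:
a generator `G` maps the zero-filled image `z` toward the fully sampled
image `x`, and a discriminator scores how plausible the reconstruction
looks relative to real images.

## Acquisition simulation

**Fourier convention.** `forwardTransform` is the unitary 2D DFT with the
DC component at `(floor(H/2)+1, floor(W/2)+1)`. Unitarity matters twice:
the round trip is exact to machine precision, and Parseval's identity
makes the frequency-domain loss equal the pixel loss for real images, so
the published loss weights keep their meaning. `inverseTransform` returns
the magnitude image — the networks see single-channel magnitude data; a
two-channel complex mode is out of scope.

**Masks.** `makeMask` draws Gaussian variable-density patterns: whole
phase-encode lines (`gaussian1d`, rows of the grid) or individual points
(`gaussian2d`). Selection probability is proportional to a Gaussian
density centered on k-space center with standard deviation 0.15 × the
grid extent, and a low-frequency block — 4% of lines, or an 8×8 square —
is always retained and counted inside the budget. These two constants are
not published for the reference masks; they were chosen once to match the
visual concentration of typical variable-density masks and are exposed as
arguments (`densitySd`, `centerFraction`, `centerBlock`). The retained
count is exact (`round(rate × lines)`), which is what makes the nominal
10×/5×/3.3× acceleration factors hold exactly on grids where the rate
divides the line count.

## Synthetic phantoms

`makePhantom` composites `nEllipses` uniform-intensity ellipses
back-to-front — the first a head-sized outline, later ones interior
structures — then adds a low-pass-filtered Gaussian texture inside the
head region (`textureAmplitude`, default 0.15 of the dynamic range,
smoothing length ~1/24 of the image side). The defaults (64×64, 8
ellipses) emulate what matters for this method: piecewise-smooth anatomy
with sharp boundaries, whose undersampled reconstructions show the
characteristic streaking, plus fine texture that exercises detail
recovery. What the phantoms do **not** emulate: true anatomical
correlations across images, coil sensitivities and complex-valued noise,
intensity inhomogeneity, and the sheer diversity of a clinical training
corpus. Passing tests therefore demonstrate that the pipeline trains and
de-aliases under controlled conditions, not that it reaches clinical
reconstruction quality.

`augmentImage` implements the standard augmentation family — left-right
flip, rotation up to ±20°, shifts up to 10%, zoom 0.9–1.1, brightness
jitter, and a Simard-style elastic deformation (displacement = α ×
Gaussian-smoothed unit noise, α = 765 px, σ = 25.5 px, bilinear
resampling, reflect borders). `addAwgn` adds image-domain white Gaussian
noise scaled so the realized SNR equals the target exactly; whether test
noise should live in k-space instead is not determined by the reference
protocol, and image-domain addition is the reading adopted here.

## Networks

**Generator.** Down-sampling block (3 stride-2 convolutions, channels
base → 2× → 4×), 7 residual blocks at 4× base (conv–BN–PReLU–conv–BN with
an inner skip), up-sampling block (3 stride-2 transposed convolutions
mirroring the channel plan). Kernel size 3 throughout. The channel plan,
kernel size and strides are not published; this is the standard layout of
the de-aliasing GAN family the architecture belongs to.

Three design choices deserve explanation because the published
description leaves them open and they decide trainability:

1. **Attention placement.** The self-attention module consumes "the
   output feature map of the last residual block", i.e. it sits at the
   entrance of the up-sampling block, where the resolution is lowest and
   the N×N attention map cheapest. `attentionLayerIndex` moves it after
   any of the transposed convolutions instead. The module follows the
   score/softmax/projection equations literally, stores the map
   query-major (each row sums to 1), subtracts the per-query maximum
   before exponentiation (required in finite arithmetic, harmless by
   softmax shift invariance), and blends through `γ`, initialized 0 — so
   a fresh module is the pixel-exact identity and attention strength is
   learned, not imposed.

2. **Normalization.** Spectral normalization is applied to every weight
   of both networks, as specified. But a 20-convolution generator with
   *only* spectral normalization is strongly contractive — each layer's
   typical gain is well below its spectral norm — and at desk scale it
   simply does not train. Two standard ingredients restore conditioning:
   batch normalization after every generator convolution except the final
   read-out (universal in this architecture family), and a learnable
   scalar gain per generator weight, used as `gain · W/σ(W)` and
   initialized to the He-init weight's spectral norm, so the network
   starts exactly as its unnormalized counterpart while the weight
   *direction* stays spectrally smoothed. The discriminator deliberately
   gets neither: pure spectral normalization keeps it 1-Lipschitz per
   layer, which is the stabilization mechanism the method relies on —
   adding a gain there lets the critic blow up its scores and saturate
   the adversarial loss within an epoch (observed, and fatal at short
   schedules).

3. **Output stage.** Residual learning: `G(z) = clip(z + g·c(z), −1, 1)`
   with the final read-out layer initialized two orders of magnitude
   small and the blend `g` learnable (initialized 1). A fresh generator
   is therefore the identity on its input up to a ~1% perturbation, which
   is what "skip connections avoid poor early-training performance" means
   operationally. The bounded output map is a hard clip rather than tanh
   so that the identity is exact on in-range inputs.

**Discriminator.** 11 convolutions, strides alternating 1/2, widths
doubling at each stride-2 layer capped at 8× base, leaky-ReLU slope 0.2,
then a dense layer to one raw score per image. The raw score is exposed
deliberately: the relativistic losses apply their sigmoid to score
*differences*, so a sigmoid inside the network would be inconsistent with
the loss definition; the drawn sigmoid in the reference figure is
interpreted as belonging to the loss.

**Spectral normalization numerics.** One power iteration per training
step with a persistent `u` vector is standard and cheap. The `u` vectors
are initialized from a seeded standard normal and then burnt in with 50
power iterations at build time; without the burn-in the early σ estimates
are biased low and the effective weights start inflated — irrelevant over
tens of thousands of steps, visible over hundreds.

## Losses

All squared-error content losses use the `½ × mean` convention, so the
published weights (pixel 15, frequency 0.1, perceptual 0.0025,
adversarial 1) balance terms independently of image size. The
relativistic average losses are evaluated in log-sigmoid form
(`log σ(t) = −log1p(exp(−t))` branch-split on the sign of `t`), finite
for |scores| up to at least 1e4. Batch expectations are within-minibatch
means over the half-real/half-fake batch, scored with shared normalized
weights in a single forward pass.

The perceptual term is defined against a *fixed deterministic feature
extractor*. The reference choice, a pretrained 16-layer classifier, is an
external binary artifact; the packaged default is a seeded frozen 3-layer
strided random convolutional map behind the same contract (deterministic,
non-trainable, plug-replaceable). Random convolutional features preserve
local structure differences well enough to act as a structural prior;
they are not a substitute for learned semantics, and the weight 0.0025
keeps the term a gentle regularizer either way.

## Optimization

Adam with β₁ = 0.5, β₂ = 0.999 and gradient centralization: every weight
gradient has its output-unit-slice mean subtracted before the update
(biases and scalars pass through). Schedule: one discriminator step then
one generator step per batch — the minimal reading of "learn
simultaneously". Validation NMSE is computed every epoch and the best
checkpoint kept, ties to the earlier epoch.

**Desk-scale preset** (`deskScaleConfig`): 200 training / 50 validation /
50 test phantoms at 64×64, 10% 1D Gaussian mask, generator base 16 /
discriminator base 8 channels, batch 4, 5 epochs. That is a ~250-step
schedule against a reference schedule near 30 000 steps, and three
adaptations follow from it, each with a measured rationale:

- generator learning rate 1e-3 (10× the reference 1e-4): at 1e-4 the
  parameters cannot move far enough in 250 steps to leave the identity;
- discriminator learning rate 1e-4 (half the reference 2e-4, i.e. the
  generator:discriminator pacing is inverted): a critic updated at 2e-3
  or even 2e-4-equivalent pace wins within the first epoch at this scale,
  and a won critic feeds the generator saturated, noisy gradients that
  drown the content losses. Keeping the critic at the reference pace
  while the generator is accelerated preserves the intent — both learn,
  neither dominates — rather than the literal ratio;
- no augmentation in the preset: with 200 unique random phantoms every
  training image is already novel, and the augmented distribution
  (rotated borders, elastic warps, brightness shifts) differs from the
  clean evaluation distribution; at 250 steps that mismatch costs more
  than the regularization buys (measured: ~0.6 dB with augmentation vs
  ~3.5 dB without, test PSNR gain over zero-filled). At reference scale
  augmentation is useful; the operation stays first-class and tested.

The problem sizes in the preset (and in the test suite, which uses
32–64 pixel images and 2–200 image datasets) were chosen so a full
training run takes a couple of minutes on one CPU core.

## Numerical and degenerate-input decisions

- PSNR of identical images is reported as a declared cap (default
  100 dB) rather than infinity; the published PSNR definition is
  implemented as `10 log₁₀(255²/MSE)` — the only reading consistent with
  reported dB magnitudes.
- SSIM uses the global single-window form with the universal stabilizers
  `C1 = (0.01·255)²`, `C2 = (0.03·255)²` and population moments; a
  sliding-window variant is available behind `windowed = TRUE` but is not
  the default.
- NMSE is `‖x − y‖²/‖x‖²`; an all-zero reference is an error, as is an
  all-zero image handed to the SNR-targeted noise generator.
- Masks whose always-retained center block exceeds the sampling budget
  raise an infeasible-rate error instead of silently overshooting the
  budget.
- All stochastic operations are pure functions of an explicit integer
  seed; dataset splits derive per-image seeds from the master seed with
  fixed offsets, making splits disjoint and bit-reproducible.
- Batch normalization uses batch statistics during training and running
  averages (momentum 0.9) at inference, so inference is deterministic and
  batch-size independent.

## Known limitations

- Desk-scale training shows the method *works* (it beats the zero-filled
  baseline by several dB on held-out phantoms) but says nothing about
  reference-scale reconstruction quality on clinical data; no attempt is
  made to reproduce published PSNR/SSIM tables, which required a
  15 816-slice corpus and GPU-scale training.
- Magnitude-only pipeline: no complex k-space noise, no multi-coil
  simulation, no hard data-consistency projection (k-space consistency is
  enforced only through the frequency loss, as in the reference design).
- The adversarial term at desk scale is a stabilized bystander more than
  a driver: with 250 steps the content losses do the de-aliasing, and the
  critic mostly regularizes. Directional claims about attention or
  spectral-normalization ablations are explicitly not asserted at this
  scale; the ablation switches (`useAttention`, `useSpectralNorm`) exist
  so such comparisons can be run at any scale.
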