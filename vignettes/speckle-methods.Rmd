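---
title: "Physics-guided speckle synthesis and mask-conditioned GANs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-guided speckle synthesis and mask-conditioned GANs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosynth)
```

## The model

Speckle is the granular interference pattern of coherent imaging: when many
scatterers with independent random phases fall inside one resolution cell,
their contributions interfere and the recorded amplitude fluctuates from
pixel to pixel.  Under the Fourier-optics view of a simple imaging system, a
square aperture of edge length $d$ in the frequency plane turns an object
$I(x,y)$ carrying i.i.d. random phases $\varphi(x,y)$ into the speckled
image

$$ I_{sp} \;=\; \bigl|\,\mathcal F^{-1}\!\left\{\,\mathcal F\{ I\,e^{j\varphi}\}\cdot \mathrm{rect}_d \,\right\}\bigr| , $$

equivalently a circular convolution of $I e^{j\varphi}$ with the inverse
DFT of the window (a discrete sinc kernel).  The window edge length $d$
controls the passband and therefore the **mean speckle grain size**:
smaller windows produce larger grains.  `apply_speckle()` implements the
FFT route; `speckle_conv_oracle()` evaluates the convolution by explicit
summation with explicit DFT matrices and exists solely so the two routes
can be cross-checked (they agree to $10^{-6}$ relative tolerance on all
tested inputs up to $64\times 64$; this is enforced in the test suite).

**Assumptions.** Phases are i.i.d. $\mathrm{Uniform}[0, 2\pi)$ — the
standard fully-developed-speckle regime.  The window is square rather than
circular (cost parity with the reference design; visually
indistinguishable speckle).  The FFT convention pairs an unnormalized
forward transform with a $1/N$ inverse; the magnitude output is invariant
to this pairing.

### Learnable window size

The hard rectangle is not differentiable in $d$, so the window is built as
the outer product of two 1-D logistic ramps
$\sigma\!\bigl((d/2 - |u|)/s\bigr)$ with softness $s$; $s = 0$ recovers the
exact 0/1 rectangle used by the oracle tests.  The gradient of the mean
speckled intensity with respect to $d$ is computed analytically
(`speckle_d_gradient()`): with $Z = \mathcal F^{-1}\{W(d)\cdot \mathcal
F\{Ie^{j\varphi}\}\}$,

$$ \frac{\partial\,\mathrm{mean}|Z|}{\partial d}
   = \mathrm{mean}\,\Re\!\left[ \frac{\bar Z}{|Z|}\,\mathcal
   F^{-1}\!\left\{ \tfrac{\partial W}{\partial d}\,\mathcal F\{I
   e^{j\varphi}\} \right\}\right]. $$

The test suite checks this against central finite differences at relative
tolerance $10^{-3}$ (softness 0.5, $h = 10^{-3}$).

### Polar warping

Catheter-based (centric) views show speckle grains that curve around the
transducer.  `cartesian_to_polar()` / `polar_to_cartesian()` resample
bilinearly between the Cartesian grid and a (radius × angle) grid; both
warps are realized as sparse matrices, so their transposes are the exact
backward operators and the warp can sit inside the network.  Defaults:
centre $((H-1)/2,(W-1)/2)$, $n_{radii} = H$, $n_{angles} = W$,
$r_{max} = \min(H,W)/2$, out-of-disc pixels 0.  Round-tripping a smooth
image loses interpolation detail near the centre and rim; measured PSNR
inside $0.9\,r_{max}$ exceeds 30 dB at $64\times64$, which is the
tolerance frozen in the tests.

Whether the original network warps inside the speckle layer or operates in
polar space throughout is not determinable from the source material; the
generator exposes `polar_in_network` (default off) and the phantom
renderer always uses the polar pipeline (speckle in the polar domain, then
polar→Cartesian).

## The GAN

The generator maps a 128-dim standard Gaussian seed through a linear layer
to a $4\times4$ grid, then repeats [nearest-neighbour ×2 upsampling +
residual block] until the target size.  Each residual block is conv3×3 →
SPADE → ReLU → conv3×3 → SPADE with an additive skip (1×1 projection on
channel change).  SPADE standardizes each channel with batch statistics
and modulates with $\gamma, \beta$ maps produced from the one-hot,
nearest-neighbour-resized segmentation mask by a shared 3×3 convolution
(64 output channels at full scale) + ReLU and two head convolutions.  The
$\gamma$-head bias initializes at 1 so blocks start near plain
standardization ($\gamma$ multiplies directly, matching the stated
formula, not $1+\gamma$).

The **speckle bank** follows the penultimate block, where feature maps have
reached the output size and 8 channels: every input map is speckled at
$S = 4$ window sizes (learnable $d$, initialized evenly over 28–48 px),
giving 32 output maps; channel-attention coefficients (global sum pooling
→ two linear layers, ReLU/sigmoid) weight each (channel, size)
combination.  Phases are drawn fresh per forward pass unless seeded — so
a mode-collapsed generator could only collapse the *morphology*, never
the speckle pattern, which is resampled physically.  A final residual
block, 3×3 convolution and sigmoid produce the image in $[0,1]$ (output
squashing is a design choice; the source is silent).

The discriminator concatenates the image with the one-hot mask (the
conditioning route is unspecified in the source; concatenation is the
simplest standard choice), then applies stride-2 spectral-normalized
residual blocks, global average pooling and a linear + sigmoid head.
Spectral normalization uses one power iteration per training step with a
persistent `u`; $\sigma$ is treated as a constant during backprop.  In
eval mode the estimate starts from a fixed vector and performs no state
update, making repeated forwards bitwise identical.

Losses are the non-saturating pair
$L_D = -\mathbb E[\log D(x|y)] - \mathbb E[\log(1 - D(G(z|y)))]$ and
$L_G = -\mathbb E[\log D(G(z|y))]$, probabilities clamped to
$[10^{-7}, 1-10^{-7}]$ before the logarithm.  Optimization is Adam with
$\beta_1 = 0.5$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$; the learning
rate steps from `lr_init` through the geometric midpoint to `lr_final` at
two milestone epochs.  Augmentation applies one random rotation plus
horizontal/vertical flips identically to image (bilinear) and mask
(nearest neighbour, labels preserved, rotated-in corners get the
background label).

### Smoke-scale training and what it establishes

Full-scale training (256 px, hundreds of epochs, hundreds of images) is a
GPU-class workload and out of scope.  `smoke_gan_config()` is the CPU
configuration used by the tests: 64 px, channel schedule 32-16-8-8, SPADE
hidden width 8, batch 4, 8 phantom pairs.  Two deliberate choices, fixed
after pilot runs and worth stating plainly:

* **10 discriminator-only warmup steps** precede alternating training.
  Without them, "generator loss at step 1" measures a randomly
  initialized discriminator whose sign of bias is a coin flip, and the
  200-step trend test degenerates to noise around the $\ln 2$
  equilibrium.  Warmup makes step 1 reflect a discriminator that already
  rejects untrained fakes.
* **Discriminator learning-rate scale 0.1** (two-timescale updates), so
  the generator can demonstrably gain ground within 200 steps.

A green 200-step run therefore establishes that the losses are wired
correctly, gradients flow end to end (including through the speckle bank
into the window sizes $d$), checkpoints and FID logging work, and the
generator weakly learns — not that images at this scale look like
ultrasound.

## Synthetic data

`sample_artery_mask()` builds the lumen boundary as a randomly rotated
ellipse with a low-order Fourier radial disturbance
$r(\theta) = r_e(\theta)\,(1 + \sum_{k\le4} a_k \cos(k\theta + \phi_k))$,
$\sum_k |a_k| \le 0.15$, and the vessel-wall band from a second, larger
disturbed ellipse clipped to stay at least 2 px outside the lumen; pixels
are labelled by their centre point.  Defaults (lumen radius 10–21% of the
image side, wall 5–12%, centre jitter 5%, eccentricity up to 0.45) were
chosen once as plausible vessel cross-section geometry; the construction
is star-shaped around the centre, so enclosure and connectivity hold by
construction and are re-asserted over 100 seeds in the tests.

`render_phantom()` composites per-class textures: a constant image at the
class base intensity (0.10 / 0.55 / 0.75 for lumen / wall / adventitia) is
speckled in the polar domain at a per-class window size (44 / 28 / 16 px —
blood speckle finest), renormalized to the class mean (the window passes
only a $d^2/N^2$ power fraction, so raw magnitudes scale with $d$), warped
to Cartesian, noised (σ = 0.02) and rescaled to $[0,1]$.  What this
emulates: per-tissue brightness and grain-size contrasts, the circular
field of view, radially curved grains.  What it does not: calcified
plaque, bifurcations, side branches, shadowing artifacts, depth-dependent
attenuation.  A green test on phantoms therefore validates mechanics and
statistics of the pipeline, not clinical realism.

## Metrics

* **Frechet distance** between Gaussian fits of embedded features
  (`fid`): $\|\mu_1-\mu_2\|^2 + \mathrm{Tr}(C_1 + C_2 - 2(C_1C_2)^{1/2})$,
  matrix square root via eigendecomposition of the symmetrized product
  $C_1^{1/2}C_2C_1^{1/2}$, eigenvalues clipped at 0, jitter
  $10^{-6}I$ on decomposition failure.  The default embedder is a
  fixed-seed random strided-conv projection to 64 features ("desk
  embedder") — deterministic and download-free; absolute values are
  embedder-specific and only comparisons sharing an embedder mean
  anything.  Any object with `feature_dim` and `embed()` can be plugged
  in instead.
* **Jensen–Shannon divergence** of per-class gray-value histograms:
  natural log (range $[0, \ln 2]$), 256 bins on $[0,1]$, additive
  $10^{-12}$ smoothing.
* **SSIM**: 11×11 Gaussian window σ = 1.5, $K_1 = 0.01$, $K_2 = 0.03$,
  data range 1, valid-window mean.
* **Dice** with the empty-vs-empty convention 1.0; **modified Hausdorff
  distance** in the max-of-directed-means (Dubuisson–Jain) form, fed by
  4-neighbour boundary extraction (`contour_points`).

## Numerical choices

Batch-norm and SPADE variance guards $\varepsilon = 10^{-5}$; magnitude
guard $10^{-12}$ in the speckle backward; probability clamp $10^{-7}$;
window sizes clamped to $[1, \min(H,W)]$ after every optimizer step;
degenerate all-zero images pass through the speckle transform as zeros.
All stochastic operations consume the R RNG and are bit-reproducible
under a fixed seed; seeded helpers save and restore the global RNG state
so they are pure.

## Known limitations

Pure-R training is orders of magnitude slower than a GPU framework; the
smoke scale demonstrates dynamics, not image fidelity.  The desk embedder
is not an Inception network, so Frechet distances are not comparable to
published FID numbers.  The phantom generator's realism gaps are listed
above.  Eval-mode batch normalization still uses batch statistics (no
running averages), which is adequate for the deterministic generation
contracts but would bias single-image inference in a deployed setting.
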