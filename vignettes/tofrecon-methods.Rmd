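---
title: "Methods: simulation, reconstruction and evaluation in tofrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, reconstruction and evaluation in tofrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tofrecon)
```

This vignette is the package's own account of its models and the design
decisions behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Why simulate raw k-space

Unrolled reconstruction networks need complex-valued multi-coil k-space for
training, but public TOF-MRA archives contain magnitude images only. The
package therefore synthesises everything the forward model needs — phase,
coil sensitivities, receive-field bias, partial Fourier, undersampling —
on top of any magnitude volume, so that a network can be pre-trained on
abundant magnitude data and then fine-tuned on one or two genuinely measured
slabs ("few-shot").

### 1.1 Phase model

`simulate_phase()` computes

    phi(r) = arg( |x(r)| + F^{-1}[ sum_{j=1..Nphs} W(k; sigma_Gj) n_j(k) ] )

with `n_j` complex white Gaussian noise (each quadrature of standard
deviation `sigma_nj`) and `W` a zero-centred Gaussian weight in k-space.
The magnitude image contributes its conjugate-symmetric k-space, so the
simulated phase inherits anatomical structure; the Gaussian-weighted noise
components add the slowly varying background phase of field inhomogeneity
plus finer noise, and break the conjugate symmetry of k-space — the property
that makes partial-Fourier reconstruction non-trivial and that the test
suite checks directly.

*Parameter conventions.* `sigma_nj` is expressed relative to `max|x|` and
`sigma_Gj` relative to the axis length. The defaults (`Nphs = 3`,
`sigma_n ~ U(0.5, 5)`, `sigma_G ~ U(0.02, 0.3)`) keep the noise amplitude
above the magnitude signal so the phase is not biased toward zero; they are
package defaults pinned by regression tests, not published values (the
published ranges live in a supplement that prints only its caption in the
available text). With `n_components = 0` the phase is exactly zero on the
support — the documented degenerate limit.

### 1.2 Coil model

`simulate_coil_maps()` builds, per coil,

    S_i(r) = d_SS ( G_i(r) + F^{-1}[ sum_{k=1..Ncsm} W(k; sigma_Gk) n_k(k) ] )

where `G_i` is an anisotropic 3D Gaussian centred on a voxel drawn uniformly
from the head-mask boundary (Otsu threshold, 4 binary erosions, 9 dilations,
6-connected structuring element) and rotated about the z-axis by a uniform
angle in `[0, pi)`; independent modulated noise is added per coil; `d_SS`
normalises the stack to unit sum-of-squares at every voxel. The SoS
constraint is what makes `sens_reduce(sens_expand(m)) = m` exact and lets
the test suite verify the whole simulation algebraically (RSS of the
simulated k-space must reproduce the magnitude to 1e-5).

Defaults: `Ncsm = 2`, spatial widths `sigma_{x,y,z} ~ U(0.15, 0.5)` of the
axis length, noise `sigma_nk ~ U(0.05, 0.3)` relative to the unit Gaussian
peak — the coil shape should dominate its noise, unlike the phase model.

### 1.3 Bias field, partial Fourier, Poisson-disc masks

* **Bias field**: voxelwise multiplication by `exp(P(r))`, `P` a random
  polynomial of total degree <= 3 with coefficients `U(-0.3, 0.3)` over
  coordinates normalised to `[-1, 1]` (matching the usual random-bias-field
  augmentation convention with coefficient 0.3, order 3). The tests refit
  `log` of the applied field with a degree-3 least-squares polynomial.
* **Partial Fourier**: "PF = 26%" is read as the *omitted* fraction —
  `round(0.26 * 288) = 75` readout samples (half-up) are zeroed at one
  contiguous end, i.e. 74% acquired, approximately a 6/8 partial echo. The
  paper does not define the convention; this reading is flagged as an open
  question there and pinned here by tests.
* **Poisson-disc masks**: variable density is implemented as a minimum-
  distance radius growing linearly with k-space radius,
  `r(k) = r0 (1 + alpha |k| / |k|_max)`, `alpha = 2`; `r0` is calibrated by
  bisection (fixed candidate permutation per seed, so generation is
  deterministic) until the sampled fraction including the forced 12 x 6
  calibration block matches `1/R` within 2% where the grid allows. Two
  accepted samples never violate `|p - q| >= min(r(p), r(q))`; the tests
  verify this exhaustively. The calibration block counts toward the nominal
  acceleration, by post-hoc density calibration.

### 1.4 The synthetic phantom

`generate_tof_phantom()` emulates what matters for this pipeline: a bounded
head (ellipsoid, exact zeros outside), moderate-intensity tissue with smooth
low-frequency texture, and a few bright, thin, connected tubes (cubic-spline
centerlines through uniform control points, Gaussian cross-sections of
radius 1-2.5 voxels) occupying a few percent of the volume, at thin-slab
geometry (64 x 64 x 24 by default). It does **not** emulate: realistic brain
anatomy or tissue classes, flow-related signal variation along vessels,
motion, gradient nonlinearity, or measurement noise beyond the phase/coil
noise models. A green phantom test therefore establishes that the *pipeline
machinery* (operators, masks, training loop, metrics) is correct and that
learning occurs — it does not establish clinical image quality, which the
original work assessed on measured data unavailable here.

## 2. The reconstruction network

The model is the end-to-end variational network scheme: a sensitivity U-Net
estimates coil maps from the calibration region of the measured k-space,
then `n_cascades` unrolled blocks each compute

    k_{t+1} = DC( k_t - F S CNN( S^H F^{-1} k_t ) )

with a refinement U-Net (`CNN`) acting on the coil-combined complex image
packed as two real channels.

* **Data consistency** is *hard* by default: every acquired sample
  (phase-encode mask AND acquired partial-Fourier region) is reset to the
  measured value after every cascade and once more at the end, so the
  asymmetric PF band is left entirely to the network (no Hermitian
  fill-in / homodyne step). A soft mode with a learned step `eta` per
  cascade is provided for parity with the classical formulation; whether
  the original model combined soft weights with PF pinning is ambiguous,
  and hard pinning is the reading that matches "remained identical to the
  acquired signals".
* **Anisotropic pooling**: the 3D U-Nets pool four times in-plane but only
  twice along the slice axis, with slice pooling at the *first two* encoder
  levels (strides 2,2,2 / 2,2,2 / 2,2,1 / 2,2,1) — a 24-slice slab reaches
  the bottleneck with 6 slices. The level ordering is not printed in the
  source description; pooling early was chosen so deeper (wider) levels keep
  slice resolution. With the standard widths (12 cascades, refiners of base
  width 18, sensitivity net of width 8) this convention reproduces both
  published parameter counts exactly — 29.9 M for the 2D baseline and
  84.6 M for the 3D variant — which is the main external check available
  for the architecture.
* **Padding**: extents not divisible by the pooling product are reflection-
  padded on the U-Net input and cropped back, with the exact adjoint used in
  backpropagation.
* **Implementation**: no deep-learning runtime exists in the target
  environment, so convolutions (im2col + BLAS), transposed convolutions
  (kernel = stride), instance normalisation, leaky ReLU, average pooling,
  the unrolled complex-valued forward model and its full backward pass, and
  Adam are implemented in base R. Gradient correctness is enforced by
  finite-difference tests through the entire unrolled network in both DC
  modes, including the sensitivity-normalisation path.

## 3. Training protocol

`pretrain()` follows the published recipe: Adam, learning rate 3e-4, up to
50 epochs per acceleration factor, L1 + SSIM loss (unit weights — the
source writes the loss without weights), validation-based early stopping
(patience 5, a package default). Each time an acquisition is loaded a fresh
Poisson-disc mask is drawn, seeded by `(seed, item, epoch)` so reruns are
bit-identical while masks still vary across epochs. Each item is normalised
so its zero-filled RSS maximum is 1 (recorded in checkpoints); the source is
silent on normalisation, and small-batch training is unstable without it.
`finetune()` is the same loop warm-started from a checkpoint with all
weights trainable ("followed the same protocol" is read as full-network
fine-tuning); its epoch-0 history row is the unmodified checkpoint's
validation loss, and the returned best checkpoint can never be worse than
that on the validation items.

The refinement U-Nets do not renormalise their input internally (the
per-item k-space normalisation plays that role); this differs from
implementations that wrap each U-Net in an input-normalisation shell, and
has no effect on parameter counts.

## 4. Evaluation stack

* **PSNR** uses peak = max(reference) — the source does not state its
  convention; this one is pinned in documentation and tests.
* **SSIM** (3D and on MIPs) uses a uniform 7-wide window, K1 = 0.01,
  K2 = 0.03, dynamic range = max(reference), symmetric boundary handling.
  The loss uses the same definition, with an analytic gradient verified
  against finite differences.
* **VM-SSIM** averages the local 2D SSIM map between axial MIPs over a
  vessel mask derived from the *reference only*.
* **Vessel masks**: multiscale Hessian vesselness (scales 1-3 px, bright
  tubular structures) unioned with the hyperintense Otsu class inside the
  head region, then components under 10 px removed. The derivation differs
  deliberately from a fixed 97th-percentile vesselness threshold: on
  thin-slab MIPs the projected vessel density varies too much for a fixed
  percentile (phantom validation showed ~40% centerline coverage for a pure
  ridge filter, because ridge filters miss vessel crossings and thick-vessel
  plateaus), while the adaptive union covers >= 98% of phantom centerline
  pixels at <= 2% background false positives. A MIP whose in-head intensity
  histogram has no hyperintense class (bright/dark contrast below 1.5) is
  declared vessel-free and raises an error rather than producing an
  arbitrary mask. Consequently VM-SSIM values are comparable within this
  package but not guaranteed numerically identical to values produced by
  other vessel-mask recipes.

## 5. Numerical conventions

* Fourier transforms are centred (DC at `floor(n/2)+1`) and unitary in both
  directions, so Parseval identities and operator adjointness hold exactly
  and are tested at 1e-6.
* The CS baseline solves `min_m 0.5 ||M F S m - y||^2 + lambda ||Psi m||_1`
  with FISTA (60 iterations, restart on objective increase, unit step — the
  forward operator has unit norm under SoS coils), `Psi` an orthogonal
  Daubechies-4 periodic DWT (3 levels, capped by divisibility), and
  `lambda = 0.005` relative to the zero-filled intensity maximum. The
  source names only "L1 wavelet-regularised CS"; solver and `lambda` are
  package choices pinned by regression tests, so quantitative parity with
  the published CS rows is not claimed.
* Slab splitting rounds the overlap to the nearest integer slice, half-up:
  20% of a 24-slice slab resolves to the 5-slice overlap that makes five
  slabs tile exactly 100 slices. Recombination is overlap-trimmed
  concatenation (the first slab keeps its overlap slices); how measured
  multi-slab data should be intensity-normalised at slab boundaries is
  genuinely open and out of scope.
* Every stochastic component derives its seed as
  `derive_seed(global_seed, tag, index)`; no function leaves the global RNG
  state altered.

## 6. Known limitations

* The headline in vivo comparisons of the original work are not reproducible
  here: the measured multi-slab raw data are not shareable, so acceptance
  rests on the self-contained architecture and procedure numbers plus the
  property suite.
* At desk scale the qualitative ordering "network >= CS" does not emerge
  from 200 smoke pre-training steps on eight synthetic phantoms: the
  L1-wavelet baseline with exact coil maps is very strong on a piecewise-
  smooth phantom (it is essentially the phantom's generative prior), while
  the published ordering reflects ~50 epochs over ~1700 simulated slabs of
  real anatomy. The smoke-trained network does beat zero-filling (by more
  than 1 dB at R = 4 on held-out phantoms), which is the learning signal a
  desk-scale test can honestly certify; the corresponding acceptance
  assertion against CS is expected to stay red and is documented as such
  rather than weakened.
* Training is batch-1, CPU-only and hence slow beyond toy scales; the
  package is a faithful, testable reference implementation, not a
  performance-oriented trainer.
* No physics-based (flow/off-resonance) phase model, no motion or gradient-
  nonlinearity simulation, no DICOM input, no prospective-scan registration.
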