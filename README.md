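# tofrecon

Few-shot deep-learning reconstruction of highly accelerated 3D
time-of-flight MR angiography (TOF-MRA), as an R package.

## The problem

3D TOF-MRA depicts the intracranial arteries without contrast agent, but a
fully sampled multi-slab acquisition takes upwards of 12 minutes.
Undersampling k-space shortens the scan; reconstructing diagnostic-quality
angiograms from 4-8x undersampled multi-coil data then requires a strong
prior. Unrolled variational networks learn that prior, but raw multi-coil
TOF k-space for training is scarce: magnitude-only archives are plentiful,
raw complex data are not.

This package implements the complete few-shot recipe around that constraint:

1. **Raw k-space simulation** (`simulate_acquisition()` and friends):
   magnitude volumes are given a realistic phase
   `phi(r) = arg(|x(r)| + F^{-1}[ sum_j W(k; sigma_Gj) n_j(k) ])`
   (Gaussian-weighted complex noise corrupting the conjugate-symmetric
   k-space of the magnitude image), coil sensitivity maps
   `S_i(r) = d_SS ( G_i(r) + F^{-1}[ sum_k W(k; sigma_Gk) n_k(k) ] )`
   (boundary-centred anisotropic 3D Gaussians plus modulated noise,
   sum-of-squares normalised), a random polynomial bias field, one-sided
   readout partial Fourier, and variable-density Poisson-disc undersampling
   in the ky-kz plane with a fully sampled 12 x 6 calibration block.
2. **A 3D unrolled end-to-end variational network** (`build_model()`,
   `reconstruct()`): cascades of coil-combine -> refinement U-Net ->
   coil-expand -> data consistency, with a sensitivity-estimation U-Net,
   3D kernels, four pooling levels in-plane but only two along the thin
   slice axis, and *hard* data consistency that keeps every acquired sample
   (including the asymmetric partial-Fourier boundary) identical to the
   measurement. The 2D baseline configuration has 29.9 M parameters, the 3D
   variant 84.6 M. Forward pass, backpropagation and Adam are implemented in
   base R — no deep-learning runtime is required.
3. **Baselines and metrics**: zero-filling and L1-wavelet FISTA compressed
   sensing (`zero_fill_recon()`, `cs_l1wavelet_recon()`); PSNR, 3D SSIM,
   NMSE and vessel-masked SSIM on axial maximum-intensity projections
   (`metrics_record()`), with vessel masks derived from the reference only.
4. **Few-shot training** (`pretrain()`, `finetune()`): Adam at learning rate
   3e-4, L1 + SSIM loss, a fresh Poisson-disc mask each time an acquisition
   is loaded, validation-based early stopping, warm-started fine-tuning.
5. **A synthetic TOF phantom** (`generate_tof_phantom()`): ellipsoidal
   textured head with bright spline-centerline vessels, so the entire
   pipeline runs and is tested without any external data.

## Worked example

```r
library(tofrecon)

# synthetic TOF volume and a simulated 4-coil acquisition, R = 4 with a
# 26% readout partial Fourier
ph  <- generate_tof_phantom(phantom_config(shape = c(64, 64, 24), seed = 1))
acq <- simulate_acquisition(ph, n_coils = 4, R = 4, pf_fraction = 0.26,
                            calib = c(12, 6), seed = 1)

ref <- Mod(acq$truth_image)            # bias-modulated ground truth
zf  <- zero_fill_recon(acq$kspace)     # RSS zero-filling
cs  <- cs_l1wavelet_recon(acq$kspace, acq$mask, acq$truth_coils)

vm <- vessel_mask(mip_axial(ref))
print(metrics_record(zf, ref, vm))
print(metrics_record(cs, ref, vm))
```

which prints (R 4.3.3, this package's seeds):

```
PSNR 20.20 dB | SSIM 0.3430 | NMSE 0.34553 | VM-SSIM 0.3789
PSNR 27.52 dB | SSIM 0.8153 | NMSE 0.06406 | VM-SSIM 0.8253
```

Compressed sensing recovers ~7.3 dB over zero-filling on this phantom, and
the vessel-masked SSIM (the metric that tracks vascular fidelity) improves
from 0.38 to 0.83. The network path (`demo` below) adds the learned prior.

An end-to-end toy pipeline — simulate phantoms, smoke-train the 3D network,
reconstruct a held-out phantom, evaluate — is one call:

```r
run("demo", overrides = list(seed = 7, out_dir = "demo_out"))
```

and writes `demo_out/metrics.json`, the reconstruction and checkpoint, plus
a resolved-config snapshot and artifact manifest. A command-line front end
with the same commands (`simulate`, `mask`, `train_pretrain`,
`train_finetune`, `recon`, `evaluate`, `demo`) is installed at
`inst/cli/tofrecon`.

## Layout

| path | contents |
|---|---|
| `R/phantom_io.R` | phantom generator, slab split/recombine, NIfTI I/O |
| `R/ksim.R` | phase/coil/bias simulation, PF + Poisson-disc masks, HDF5 |
| `R/mri_ops.R` | centred unitary FFTs, coil operators, SVD compression, wavelets, CS |
| `R/nn.R`, `R/varnet.R` | layer framework with backprop; the unrolled network |
| `R/metrics.R` | PSNR / SSIM / NMSE / MIP / vessel masks / VM-SSIM |
| `R/training.R` | L1+SSIM loss and gradient, Adam, pretrain/finetune |
| `R/cli.R` | YAML-configured pipeline commands |
| `vignettes/tofrecon-methods.Rmd` | the methods vignette |

See the methods vignette for the model assumptions, parameter conventions,
what the phantom does and does not emulate, and known limitations.
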