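# k-space simulation: head mask morphology, phase model, coil maps, bias
# field, partial Fourier, Poisson-disc masks, undersampling, HDF5 round trip.

test_that("head mask reproduces erosion/dilation against a closed-form oracle", {
  # solid bright cube, side 20, centred in a 40^3 zero field
  vol <- array(0, c(40, 40, 40))
  vol[11:30, 11:30, 11:30] <- 1
  hm <- compute_head_mask(magnitude_volume(vol))
  # oracle: erode 4 -> cube 15:26; dilate 9 with the 6-connected cross is the
  # L1 (Manhattan) distance-9 neighbourhood of that cube, clipped at borders
  ax <- seq_len(40)
  dist1 <- function(p, lo, hi) pmax(lo - p, p - hi, 0)
  dx <- dist1(ax, 15, 26)
  l1 <- outer(outer(dx, dx, `+`), dx, `+`)
  expect_identical(hm$mask, l1 <= 9)

  # all-zero volume: no Otsu threshold
  expect_error(compute_head_mask(magnitude_volume(array(0, c(16, 16, 16)))),
               class = "tofrecon_no_threshold")
  # every boundary voxel has at least one background 6-neighbour
  nb <- hm$boundary
  bad <- 0
  for (i in seq_len(nrow(nb))) {
    p <- nb[i, ]
    has_bg <- FALSE
    for (ax3 in 1:3) for (s in c(-1L, 1L)) {
      q <- p; q[ax3] <- q[ax3] + s
      if (all(q >= 1) && all(q <= 40) && !hm$mask[q[1], q[2], q[3]])
        has_bg <- TRUE
    }
    if (!has_bg) bad <- bad + 1
  }
  expect_equal(bad, 0)
})

test_that("phase simulation follows the modulated-noise model", {
  ph <- fx_phantom_small()
  # zero components: arg of a positive real image is exactly zero on support
  phase0 <- simulate_phase(ph, phase_sim_config(n_components = 0))
  expect_true(all(phase0[ph$data > 0] == 0))

  # codomain and determinism
  cfg <- phase_sim_config(seed = 5)
  p1 <- simulate_phase(ph, cfg)
  expect_true(all(p1 > -pi & p1 <= pi))
  expect_identical(p1, simulate_phase(ph, cfg))

  # with noise amplitudes far above the signal, the phase at a fixed voxel is
  # circularly unbiased across seeds and the histogram is non-degenerate
  vox <- c(16, 16, 8)
  phis <- vapply(1:50, function(s) {
    simulate_phase(ph, phase_sim_config(sigma_noise_range = c(50, 60),
                                        seed = s))[vox[1], vox[2], vox[3]]
  }, 0)
  m <- mean(exp(1i * phis))
  rbar <- Mod(m)
  circ_se <- sqrt((1 - rbar^2) / (50 * max(rbar^2, 1e-6))) # delta method
  expect_lt(abs(Arg(m)), 3 * circ_se + 1e-9)
  expect_gt(stats::sd(phis), 0.5)
})

test_that("coil maps are SoS-normalised, centred on the boundary, seeded", {
  ph <- fx_phantom_small()
  hm <- compute_head_mask(ph)
  cfg <- coil_sim_config(n_coils = 6, seed = 2)
  cm <- simulate_coil_maps(ph, hm, cfg)
  sos <- colSums(Mod(cm$maps)^2, dims = 1)
  expect_lt(max(abs(sos - 1)), 1e-5)
  expect_equal(dim(cm$maps)[1], 6)
  expect_identical(cm$maps, simulate_coil_maps(ph, hm, cfg)$maps)

  # 32 coils requested -> 32 maps
  cm32 <- simulate_coil_maps(ph, hm, coil_sim_config(n_coils = 32, seed = 1))
  expect_equal(dim(cm32$maps)[1], 32)

  # noise-free maps peak near their sampled centres (within 2 sigma voxels)
  cfg0 <- coil_sim_config(n_coils = 4, n_components = 0, seed = 9)
  cm0 <- simulate_coil_maps(ph, hm, cfg0)
  centers <- attr(cm0, "centers")
  d <- dim(ph$data)
  sig_vox <- 0.5 * max(d) # upper end of the sigma_xyz default range
  for (i in 1:4) {
    am <- which(Mod(cm0$maps[i, , , ]) ==
                  max(Mod(cm0$maps[i, , , ])), arr.ind = TRUE)[1, ]
    expect_lt(sqrt(sum((am - centers[i, ])^2)), 2 * sig_vox)
  }

  # degenerate boundary
  expect_error(head_mask(array(FALSE, c(8, 8, 8))),
               class = "tofrecon_degenerate_mask")
})

test_that("bias field is a positive exp(degree-3 polynomial)", {
  ph <- fx_phantom_small()
  # coefficient 0 -> identity
  b0 <- apply_bias_field(ph, coefficient = 0, seed = 3)
  expect_equal(b0$data, ph$data)
  b <- apply_bias_field(ph, coefficient = 0.3, order = 3, seed = 3)
  field <- b$meta$bias_field
  expect_true(all(field > 0))
  # least-squares refit oracle: log(field) is degree-3 polynomial
  d <- dim(ph$data)
  gx <- seq(-1, 1, length.out = d[1]); gy <- seq(-1, 1, length.out = d[2])
  gz <- seq(-1, 1, length.out = d[3])
  g <- expand.grid(x = gx, y = gy, z = gz)
  basis <- NULL
  for (a in 0:3) for (bb in 0:(3 - a)) for (cc in 0:(3 - a - bb))
    basis <- cbind(basis, g$x^a * g$y^bb * g$z^cc)
  fit <- stats::lm.fit(basis, as.vector(log(field)))
  expect_lt(sqrt(sum(fit$residuals^2) / sum(log(field)^2)), 1e-6)
})

test_that("composed multi-coil k-space obeys the algebraic identities", {
  acq <- fx_acq()
  ph <- fx_phantom_small()
  # RSS of the inverse transform recovers the (bias-field-modulated)
  # magnitude exactly, because the coil maps are SoS-normalised
  ref_mag <- Mod(acq$truth_image)
  rss <- zero_fill_recon(acq$kspace)
  expect_lt(max(abs(rss - ref_mag)) / max(ref_mag), 1e-5)
  # Parseval across coils
  expect_lt(abs(sum(Mod(acq$kspace)^2) - sum(Mod(acq$truth_image)^2)) /
              sum(Mod(acq$truth_image)^2), 1e-10)
  # coil-combined phase recovery on the support
  comb <- sens_reduce(acq$kspace, acq$truth_coils)
  supp <- ph$data > 0.1 * max(ph$data)
  expect_lt(max(abs(Arg(comb)[supp] - acq$truth_phase[supp])), 1e-4)
  # shape mismatch
  expect_error(compose_multicoil_kspace(ph, acq$truth_phase[1:8, 1:8, 1:8],
                                        acq$truth_coils),
               class = "tofrecon_shape_error")
})

test_that("k-space of a real image is Hermitian and phase noise breaks it", {
  ph <- fx_phantom_small()
  d <- dim(ph$data)
  # single uniform coil, zero phase
  k <- fft3c(ph$data * exp(1i * 0))
  # centred convention: k[c+v] == Conj(k[c-v]) away from Nyquist planes
  herm_err <- function(k) {
    d <- dim(k)
    ctr <- floor(d / 2) + 1
    ix <- 2:(d[1] - 0); iy <- 2:(d[2] - 0); iz <- 2:(d[3] - 0)
    kk <- k[ix, iy, iz]
    kr <- k[rev(ix), rev(iy), rev(iz)]
    max(Mod(kk - Conj(kr)))
  }
  expect_lt(herm_err(k) / max(Mod(k)), 1e-5)
  phase <- simulate_phase(ph, phase_sim_config(seed = 4))
  k2 <- fft3c(ph$data * exp(1i * phase))
  expect_gt(herm_err(k2) / max(Mod(k2)), 1e-2)
})

test_that("partial-Fourier mask omits one contiguous end", {
  expect_identical(make_pf_mask(64, 0), rep(1L, 64))
  pf <- make_pf_mask(288, 0.26)
  expect_equal(sum(pf == 0), 75) # round(0.26 * 288) half-up
  expect_equal(sum(pf == 1), 213)
  # contiguity: once ones begin they never revert
  expect_true(all(diff(pf) >= 0))
  expect_error(make_pf_mask(64, 0.5), class = "tofrecon_invalid_pf")
})

test_that("Poisson-disc masks are calibrated, seeded and radius-valid", {
  # R = 1: all ones
  m1 <- make_poisson_mask(16, 8, 1, calib = c(4, 2))
  expect_true(all(m1$pe_mask == 1))

  # calibration block fully sampled: exactly 12 x 6 = 72 forced samples
  mk <- make_poisson_mask(64, 24, 8, calib = c(12, 6), seed = 1)
  cr <- tofrecon:::calib_ranges(64, 24, c(12, 6))
  expect_equal(sum(mk$pe_mask[cr$y, cr$z]), 72)
  expect_identical(mk$pe_mask,
                   make_poisson_mask(64, 24, 8, calib = c(12, 6),
                                     seed = 1)$pe_mask)

  # acceleration within 10% of target across 20 seeds for R in {4, 8}
  for (R in c(4, 8)) {
    fr <- vapply(1:20, function(s)
      mean(make_poisson_mask(64, 24, R, seed = s)$pe_mask), 0)
    expect_true(all(abs(fr - 1 / R) / (1 / R) < 0.10))
  }

  # exhaustive pairwise check of the local radius rule (non-calibration)
  mk4 <- make_poisson_mask(64, 24, 4, calib = c(12, 6), seed = 3)
  r0 <- attr(mk4, "r0"); alpha <- attr(mk4, "alpha")
  pts <- which(mk4$pe_mask == 1, arr.ind = TRUE)
  in_cal <- pts[, 1] %in% cr$y & pts[, 2] %in% cr$z
  pts <- pts[!in_cal, , drop = FALSE]
  ctr <- c(floor(64 / 2) + 1, floor(24 / 2) + 1)
  dmax <- max(sqrt((which(mk4$pe_mask > -1, arr.ind = TRUE)[, 1] - ctr[1])^2 +
                     (which(mk4$pe_mask > -1, arr.ind = TRUE)[, 2] - ctr[2])^2))
  rad <- r0 * (1 + alpha * sqrt((pts[, 1] - ctr[1])^2 +
                                  (pts[, 2] - ctr[2])^2) / dmax)
  viol <- 0L
  for (i in seq_len(nrow(pts) - 1)) {
    j <- (i + 1):nrow(pts)
    dd <- sqrt((pts[j, 1] - pts[i, 1])^2 + (pts[j, 2] - pts[i, 2])^2)
    viol <- viol + sum(dd < pmin(rad[i], rad[j]))
  }
  expect_equal(viol, 0L)

  # infeasible R (calibration alone exceeds the budget)
  expect_error(make_poisson_mask(16, 8, 64, calib = c(12, 6)),
               class = "tofrecon_infeasible")
})

test_that("undersampling zeroes excluded samples and keeps the rest bitwise", {
  acq <- fx_acq()
  d <- dim(acq$kspace)
  mk <- fx_masked(acq, R = 4, seed = 7, pf = 0.26)
  m3 <- tofrecon:::mask_3d(mk$mask)
  full <- aperm(array(m3, c(d[-1], d[1])), c(4, 1, 2, 3))
  expect_identical(mk$acq$kspace[full == 1], acq$kspace[full == 1])
  expect_true(all(mk$acq$kspace[full == 0] == 0))

  # all-ones mask is the identity
  ones <- sampling_mask(matrix(1L, d[3], d[4]), rep(1L, d[2]), c(8, 4), 1)
  expect_identical(undersample(acq, ones)$kspace, acq$kspace)

  # retained energy fraction across seeds on white-noise k-space
  set.seed(1)
  noise_acq <- simulated_acquisition(rcarr(c(2, 16, 16, 8)),
                                     ones_mask <- sampling_mask(
                                       matrix(1L, 16, 8), rep(1L, 16),
                                       c(4, 2), 1))
  fr <- vapply(1:20, function(s) {
    pe <- make_poisson_mask(16, 8, 4, calib = c(4, 2), seed = s)
    u <- undersample(noise_acq, sampling_mask(pe$pe_mask, rep(1L, 16),
                                              c(4, 2), 4))
    sum(Mod(u$kspace)^2) / sum(Mod(noise_acq$kspace)^2)
  }, 0)
  samp <- vapply(1:20, function(s)
    mean(make_poisson_mask(16, 8, 4, calib = c(4, 2), seed = s)$pe_mask), 0)
  expect_true(all(fr <= 1))
  # white noise: retained energy tracks the sampled fraction
  expect_true(all(abs(fr - samp) < 0.1))

  # dimension mismatch
  bad <- sampling_mask(matrix(1L, 3, 3), rep(1L, d[2]), c(1, 1), 1)
  expect_error(undersample(acq, bad), class = "tofrecon_shape_error")
})

test_that("acquisitions round-trip through HDF5", {
  acq <- fx_masked(fx_acq(), R = 4, seed = 2, pf = 0.26)$acq
  path <- tempfile(fileext = ".h5")
  save_acquisition(acq, path)
  rd <- load_acquisition(path)
  expect_equal(rd$kspace, acq$kspace)
  expect_identical(rd$mask$pe_mask, acq$mask$pe_mask)
  expect_identical(rd$mask$pf_mask, acq$mask$pf_mask)
  expect_equal(rd$mask$target_R, acq$mask$target_R)
  expect_equal(rd$truth_image, acq$truth_image)
  expect_equal(rd$truth_coils$maps, acq$truth_coils$maps)
  unlink(path)
})
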