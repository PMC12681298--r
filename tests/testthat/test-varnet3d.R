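# Variational network: architecture/parameter counts, sensitivity
# estimation, data consistency, reconstruction contracts, gradient flow,
# and the smoke-learning invariant.

# analytic parameter-count oracle: layer-by-layer arithmetic, independent of
# the builder's data structures
oracle_params <- function(cascades, chans, sens_chans, L, slice_levels,
                          three_d, soft_dc = FALSE) {
  kt <- if (three_d) 27 else 9
  convblock <- function(ci, co) kt * (ci * co + co * co)
  tconv_kt <- function(l) { # decoder position l = 1..L (from bottleneck)
    if (!three_d) return(4)
    # encoder levels 1..slice_levels pool z; decoder mirrors in reverse
    enc_level <- L - l + 1
    if (enc_level <= slice_levels) 8 else 4
  }
  unet <- function(ch) {
    total <- convblock(2, ch)
    c_cur <- ch
    for (l in seq_len(L)[-1]) { total <- total + convblock(c_cur, 2 * c_cur)
                                c_cur <- 2 * c_cur }
    total <- total + convblock(c_cur, 2 * c_cur) # bottleneck
    for (l in 1:L) {
      total <- total + tconv_kt(l) * (2 * c_cur) * c_cur # transpose conv
      total <- total + convblock(2 * c_cur, c_cur)       # after skip concat
      if (l < L) c_cur <- c_cur / 2
    }
    total + c_cur * 2 + 2 # final 1x1 conv with bias
  }
  cascades * (unet(chans) + as.integer(soft_dc)) + unet(sens_chans)
}

test_that("parameter counts reproduce the published architecture sizes", {
  m2d <- build_model(varnet_config(dimensionality = "2D"),
                     init_weights = FALSE)
  expect_equal(round(count_parameters(m2d) / 1e6, 1), 29.9)
  m3d <- build_model(varnet_config(dimensionality = "3D"),
                     init_weights = FALSE)
  expect_equal(round(count_parameters(m3d) / 1e6, 1), 84.6)
})

test_that("parameter count is a pure function of the configuration", {
  cases <- list(
    list(cfg = varnet_config(1, 2, 2, 1, 1, "3D"),
         or = oracle_params(1, 2, 2, 1, 1, TRUE)),
    list(cfg = varnet_config(2, 4, 3, 2, 1, "3D"),
         or = oracle_params(2, 4, 3, 2, 1, TRUE)),
    list(cfg = varnet_config(3, 6, 4, 3, 2, "3D"),
         or = oracle_params(3, 6, 4, 3, 2, TRUE)),
    list(cfg = varnet_config(2, 8, 4, 4, 2, "2D"),
         or = oracle_params(2, 8, 4, 4, 0, FALSE)),
    list(cfg = varnet_config(12, 18, 8, 4, 2, "2D", dc_mode = "soft"),
         or = oracle_params(12, 18, 8, 4, 0, FALSE, soft_dc = TRUE)))
  for (cs in cases) {
    m <- build_model(cs$cfg, init_weights = FALSE)
    expect_equal(count_parameters(m), cs$or)
  }
  # built twice -> identical counts; invalid pooling rejected
  expect_error(varnet_config(pool_levels_inplane = 2, pool_levels_slice = 3),
               class = "tofrecon_invalid_config")
})

test_that("sensitivity estimation uses only the calibration region", {
  acq <- fx_masked(fx_acq(), R = 4, seed = 8, pf = 0.25)
  model <- build_model(fx_toy_cfg(), seed = 5)
  S <- estimate_sensitivities(model, acq$acq$kspace, acq$mask)
  sos <- colSums(Mod(S$maps)^2, dims = 1)
  expect_lt(max(abs(sos - 1)), 1e-5)
  expect_equal(dim(S$maps)[1], dim(acq$acq$kspace)[1])

  # perturbing non-calibration samples leaves the output bit-identical
  k2 <- acq$acq$kspace
  acs <- tofrecon:::acs_mask_3d(acq$mask, dim(k2)[2])
  out <- which(acs == 0)
  k2[1, , , ][out] <- k2[1, , , ][out] + (0.5 + 0.25i)
  S2 <- estimate_sensitivities(model, k2, acq$mask)
  expect_identical(S$maps, S2$maps)

  # mask without calibration block -> calibration error
  nocal <- sampling_mask(acq$mask$pe_mask, acq$mask$pf_mask, c(0, 0), 4)
  expect_error(estimate_sensitivities(model, acq$acq$kspace, nocal),
               class = "tofrecon_calibration")
})

test_that("hard data consistency pins acquired samples and is idempotent", {
  set.seed(20)
  d <- c(2, 16, 16, 8)
  cur <- rcarr(d)
  pe <- make_poisson_mask(16, 8, 4, calib = c(4, 2), seed = 2)$pe_mask
  msk <- sampling_mask(pe, make_pf_mask(16, 0.26), c(4, 2), 4)
  m3 <- tofrecon:::mask_3d(msk)
  ref <- rcarr(d)
  for (i in 1:2) ref[i, , , ] <- array(ref[i, , , ], d[-1]) * m3
  st <- cascade_state(cur, ref, msk)
  h <- dc_step(st, "hard")
  full <- aperm(array(m3, c(d[-1], d[1])), c(4, 1, 2, 3))
  # acquired samples identical to the measurement
  expect_identical(h$current_kspace[full == 1], ref[full == 1])
  # unsampled locations (including the omitted PF band) untouched, bitwise
  expect_identical(h$current_kspace[full == 0], cur[full == 0])
  # idempotence
  h2 <- dc_step(h, "hard")
  expect_identical(h2$current_kspace, h$current_kspace)
  # soft mode with eta = 1 equals hard pinning on the sampled set
  s1 <- dc_step(cascade_state(cur, ref, msk, eta = 1), "soft")
  expect_equal(s1$current_kspace[full == 1], ref[full == 1])
})

test_that("reconstruct() satisfies its output contracts", {
  acq <- fx_masked(fx_acq(), R = 4, seed = 9, pf = 0.25)
  model <- build_model(fx_toy_cfg(), seed = 6)
  out <- reconstruct(model, acq$acq$kspace, acq$mask)
  expect_equal(dim(out), dim(acq$acq$kspace)[-1])
  expect_true(all(is.finite(out)) && all(out >= 0))
  # determinism in evaluation
  expect_identical(out, reconstruct(model, acq$acq$kspace, acq$mask))

  # re-projected k-space equals the measurement on the sampled set
  S <- estimate_sensitivities(model, acq$acq$kspace, acq$mask)
  r <- tofrecon:::varnet_apply(model, acq$acq$kspace, acq$mask,
                               with_tape = TRUE)
  m3 <- tofrecon:::mask_3d(acq$mask)
  d <- dim(acq$acq$kspace)
  full <- aperm(array(m3, c(d[-1], d[1])), c(4, 1, 2, 3))
  expect_identical(r$tape$k_fin[full == 1], acq$acq$kspace[full == 1])

  # padding path: odd extents are reflection-padded internally
  k_odd <- acq$acq$kspace[, 1:30, 1:30, 1:15, drop = FALSE]
  msk_odd <- sampling_mask(acq$mask$pe_mask[1:30, 1:15],
                           acq$mask$pf_mask[1:30], c(8, 4), 4)
  out_odd <- reconstruct(model, k_odd, msk_odd)
  expect_equal(dim(out_odd), c(30L, 30L, 15L))
  expect_true(all(is.finite(out_odd)))
})

test_that("zeroed refiners degenerate to sens-combined zero-filling", {
  acq <- fx_masked(fx_acq(), R = 4, seed = 10)
  model <- build_model(fx_toy_cfg(), seed = 7)
  for (cs in model$cascades) {
    for (p in tofrecon:::collect_param_envs(cs$unet)) {
      p$W[] <- 0
      if (!is.null(p$b)) p$b[] <- 0
    }
  }
  out <- reconstruct(model, acq$acq$kspace, acq$mask)
  S <- estimate_sensitivities(model, acq$acq$kspace, acq$mask)
  zf <- Mod(sens_reduce(acq$acq$kspace, S))
  expect_equal(out, zf, tolerance = 1e-12)
})

test_that("gradients flow to every trainable tensor", {
  set.seed(30)
  d <- c(2, 16, 16, 8)
  k <- rcarr(d)
  pe <- make_poisson_mask(16, 8, 2, calib = c(4, 2), seed = 3)$pe_mask
  msk <- sampling_mask(pe, make_pf_mask(16, 0.2), c(4, 2), 2)
  m3 <- tofrecon:::mask_3d(msk)
  for (i in 1:2) k[i, , , ] <- array(k[i, , , ], d[-1]) * m3
  # hard DC (the default): every trainable tensor receives gradient
  cfg <- varnet_config(n_cascades = 2, chans = 4, sens_chans = 3,
                       pool_levels_inplane = 2, pool_levels_slice = 1,
                       dc_mode = "hard")
  model <- build_model(cfg, seed = 8)
  envs <- tofrecon:::varnet_param_envs(model)
  tofrecon:::zero_grads(envs)
  r <- tofrecon:::varnet_apply(model, k, msk, with_tape = TRUE)
  tofrecon:::varnet_backward(model, r$tape, array(1, d[-1]))
  dead <- vapply(envs, function(p) is.null(p$gW) || all(p$gW == 0), TRUE)
  expect_false(any(dead))

  # soft DC: every tensor except the structurally degenerate first- and
  # last-cascade eta steps. Cascade 1's DC term M(k - y) is identically zero
  # because its input IS the measurement (true of the classical soft-DC
  # formulation as well), and the terminal hard-DC projection zeroes the
  # sampled-set gradient reaching the last cascade's eta.
  cfg3 <- varnet_config(n_cascades = 3, chans = 4, sens_chans = 3,
                        pool_levels_inplane = 2, pool_levels_slice = 1,
                        dc_mode = "soft")
  model3 <- build_model(cfg3, seed = 8)
  envs3 <- tofrecon:::varnet_param_envs(model3)
  tofrecon:::zero_grads(envs3)
  r3 <- tofrecon:::varnet_apply(model3, k, msk, with_tape = TRUE)
  tofrecon:::varnet_backward(model3, r3$tape, array(1, d[-1]))
  etas <- which(vapply(envs3, function(p) identical(p$wshape, 1L), TRUE))
  dead3 <- which(vapply(envs3, function(p)
    is.null(p$gW) || all(p$gW == 0), TRUE))
  expect_setequal(dead3, etas[c(1, length(etas))])
})

test_that("200 smoke steps at R=4 beat zero-filling by >= 1 dB held out", {
  ck <- fx_smoke_checkpoint(4)
  # training loss decreased over the run (and already by epoch 5, the
  # documented 5-epoch smoke-run contract at this scale)
  h <- ck$history
  expect_lt(h$train_loss[h$epoch == 5], h$train_loss[h$epoch == 1])
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  hold <- fx_holdout()
  tc <- train_config(R = 4, calib = c(8, 4), seed = 77)
  msk <- tofrecon:::draw_item_mask(hold, tc, "test", 1L, 1L)
  it <- tofrecon:::prepare_item(hold, msk)
  net <- reconstruct(checkpoint_model(ck), it$k, it$mask) * it$scale
  zf <- zero_fill_recon(undersample(hold, msk)$kspace)
  ref <- Mod(hold$truth_image)
  expect_gte(psnr(net, ref) - psnr(zf, ref), 1)
})
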