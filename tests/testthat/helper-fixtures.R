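# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from seeds: no stored data files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# default 64 x 64 x 24 phantom (the documented regression phantom)
fx_phantom <- function() memo("phantom64", function() {
  generate_tof_phantom(phantom_config())
})

# small thin-slab phantom for operator tests
fx_phantom_small <- function(seed = 1L) {
  memo(paste0("phantom32-", seed), function() {
    generate_tof_phantom(phantom_config(shape = c(32, 32, 16), n_vessels = 6,
                                        vessel_radius_range = c(1, 2),
                                        seed = seed))
  })
}

# fully sampled 4-coil acquisition of the small phantom
fx_acq <- function(seed = 1L) {
  memo(paste0("acq-", seed), function() {
    simulate_acquisition(fx_phantom_small(seed), n_coils = 4, seed = seed,
                         calib = c(8, 4))
  })
}

# toy training item: 32 x 32 x 16 phantom, 4 coils (distinct phantoms per
# seed). Used by the smoke-training and acceptance tests.
fx_train_item <- function(seed) {
  memo(paste0("item-", seed), function() {
    ph <- generate_tof_phantom(phantom_config(shape = c(32, 32, 16),
                                              n_vessels = 6,
                                              vessel_radius_range = c(1, 2),
                                              seed = seed))
    simulate_acquisition(ph, n_coils = 4, seed = seed, calib = c(8, 4))
  })
}

# toy architecture used for smoke training
fx_toy_cfg <- function() {
  varnet_config(n_cascades = 2, chans = 8, sens_chans = 4,
                pool_levels_inplane = 2, pool_levels_slice = 1)
}

# relative L2 error for complex arrays
rel_err_c <- function(a, b) sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))

# random complex array helper
rcarr <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(complex(real = stats::rnorm(prod(d)),
                imaginary = stats::rnorm(prod(d))), d)
}

# undersample an acquisition with a seeded Poisson + PF mask
fx_masked <- function(acq, R, seed, pf = 0, calib = c(8, 4)) {
  d <- dim(acq$kspace)
  pe <- make_poisson_mask(d[3], d[4], R, calib, seed = seed)
  msk <- sampling_mask(pe$pe_mask, make_pf_mask(d[2], pf), calib, R)
  list(acq = undersample(acq, msk), mask = msk)
}

# memoised 200-step smoke pre-training at a given R (the expensive fixture
# shared by the learning-invariant and acceptance-ordering tests)
fx_smoke_checkpoint <- function(R) {
  memo(paste0("smoke-ck-", R), function() {
    items <- lapply(1:9, fx_train_item) # 8 train + 1 validation
    model <- build_model(fx_toy_cfg(), seed = 3)
    tc <- train_config(epochs = 25, lr = 3e-4, R = R, calib = c(8, 4),
                       early_stop_patience = 50, seed = 11)
    pretrain(model, items, tc)
  })
}

# held-out phantom acquisition never seen in training
fx_holdout <- function() fx_train_item(100)
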