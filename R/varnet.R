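# Unrolled end-to-end variational network for 3D multi-coil reconstruction.
#
# Architecture: one sensitivity-estimation U-Net (applied per coil to the
# calibration-region image, then sum-of-squares normalised) and `n_cascades`
# unrolled blocks, each performing coil-combine -> refinement U-Net ->
# coil-expand -> data consistency. Data consistency is "hard" by default:
# every acquired k-space sample (phase-encode mask AND the acquired
# partial-Fourier region) is pinned to the measured value, so the asymmetric
# PF band is left entirely to the network. A soft mode with a learned step
# eta is available for parity with the classical end-to-end formulation.
#
# The 3D variant uses 3x3x3 kernels with four pooling levels along the
# in-plane axes but only two along the thin slice axis (strides 2,2,2 /
# 2,2,2 / 2,2,1 / 2,2,1 from the top), keeping enough slices at the
# bottleneck for thin-slab inputs. The 2D variant is the same network with
# unit z kernels and strides.

#' Variational network configuration
#'
#' Defaults reproduce the published end-to-end variational network baseline:
#' 12 cascades, refinement U-Nets of base width 18 with 4 pooling levels,
#' sensitivity U-Net of base width 8 (29.9 M parameters in 2D, 84.6 M for
#' the 3D variant with 4/4/2 pooling).
#'
#' @param n_cascades unrolled cascade count.
#' @param chans base channel width of the cascade refinement U-Nets.
#' @param sens_chans base channel width of the sensitivity U-Net.
#' @param pool_levels_inplane pooling levels along x and y.
#' @param pool_levels_slice pooling levels along z (3D only; must not exceed
#'   `pool_levels_inplane`). Slice pooling is applied at the FIRST
#'   `pool_levels_slice` encoder levels.
#' @param dimensionality `"2D"` or `"3D"`.
#' @param dc_mode `"hard"` (exact pinning of acquired samples) or `"soft"`
#'   (learned step `eta`).
#' @return object of class `varnet_config`.
#' @export
varnet_config <- function(n_cascades = 12, chans = 18, sens_chans = 8,
                          pool_levels_inplane = 4, pool_levels_slice = 2,
                          dimensionality = c("3D", "2D"),
                          dc_mode = c("hard", "soft")) {
  dimensionality <- match.arg(dimensionality)
  dc_mode <- match.arg(dc_mode)
  assert_that(pool_levels_slice <= pool_levels_inplane,
              "pool_levels_slice must be <= pool_levels_inplane",
              "tofrecon_invalid_config")
  assert_that(n_cascades >= 1 && chans >= 1 && sens_chans >= 1,
              "invalid widths", "tofrecon_invalid_config")
  structure(list(n_cascades = as.integer(n_cascades),
                 chans = as.integer(chans),
                 sens_chans = as.integer(sens_chans),
                 pool_levels_inplane = as.integer(pool_levels_inplane),
                 pool_levels_slice = as.integer(pool_levels_slice),
                 dimensionality = dimensionality, dc_mode = dc_mode),
            class = "varnet_config")
}

varnet_strides <- function(cfg) {
  L <- cfg$pool_levels_inplane
  lapply(seq_len(L), function(l) {
    if (cfg$dimensionality == "2D") c(2L, 2L, 1L)
    else c(2L, 2L, if (l <= cfg$pool_levels_slice) 2L else 1L)
  })
}

varnet_ksize <- function(cfg) {
  if (cfg$dimensionality == "2D") c(3L, 3L, 1L) else c(3L, 3L, 3L)
}

#' Build a variational network model
#'
#' @param cfg a [varnet_config()].
#' @param init_weights allocate and initialise weights (fan-in uniform);
#'   `FALSE` builds the architecture skeleton only (enough for
#'   [count_parameters()]).
#' @param seed integer seed for weight initialisation.
#' @return object of class `varnet_model`.
#' @export
build_model <- function(cfg, init_weights = TRUE, seed = 1L) {
  stopifnot(inherits(cfg, "varnet_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "init"))
  strides <- varnet_strides(cfg)
  ks <- varnet_ksize(cfg)
  sens_unet <- nn_unet(2, 2, cfg$sens_chans, strides, ks, init_weights)
  cascades <- lapply(seq_len(cfg$n_cascades), function(i) {
    eta <- NULL
    if (cfg$dc_mode == "soft") {
      eta <- new.env(parent = emptyenv())
      eta$wshape <- 1L; eta$bshape <- NULL
      if (init_weights) eta$W <- array(1, 1L)
      eta$gW <- NULL; eta$gb <- NULL
    }
    list(unet = nn_unet(2, 2, cfg$chans, strides, ks, init_weights),
         eta = eta)
  })
  structure(list(cfg = cfg, sens_unet = sens_unet, cascades = cascades,
                 init_seed = as.integer(seed)),
            class = "varnet_model")
}

varnet_param_envs <- function(model) {
  envs <- collect_param_envs(model$sens_unet)
  for (cs in model$cascades) {
    envs <- c(envs, collect_param_envs(cs$unet))
    if (!is.null(cs$eta)) envs <- c(envs, list(cs$eta))
  }
  envs
}

#' Count trainable parameters
#'
#' A pure function of the architecture configuration: the sum of all weight
#' and bias tensor sizes (and the learned data-consistency steps in soft
#' mode).
#'
#' @param model a `varnet_model` from [build_model()].
#' @return integer-valued double.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "varnet_model"))
  sum(vapply(varnet_param_envs(model), n_params_env, 0))
}

#' @export
print.varnet_model <- function(x, ...) {
  cat(sprintf("<varnet_model %s: %d cascades, chans %d, sens %d, %.1fM params, dc=%s>\n",
              x$cfg$dimensionality, x$cfg$n_cascades, x$cfg$chans,
              x$cfg$sens_chans, count_parameters(x) / 1e6, x$cfg$dc_mode))
  invisible(x)
}

# ---- weight (de)serialisation ------------------------------------------------

get_weights <- function(model) {
  lapply(varnet_param_envs(model), function(p)
    list(W = p$W, b = if (!is.null(p$bshape)) p$b else NULL))
}

set_weights <- function(model, weights) {
  envs <- varnet_param_envs(model)
  assert_that(length(envs) == length(weights),
              "weight list does not match architecture",
              "tofrecon_config_error")
  for (i in seq_along(envs)) {
    assert_that(identical(dim(weights[[i]]$W), dim(envs[[i]]$W)) ||
                  all(dim(weights[[i]]$W) == envs[[i]]$wshape),
                "weight shape mismatch", "tofrecon_config_error")
    envs[[i]]$W <- weights[[i]]$W
    if (!is.null(envs[[i]]$bshape)) envs[[i]]$b <- weights[[i]]$b
  }
  invisible(model)
}

# ---- reflection padding to pooling divisibility --------------------------------

# per-axis gather matrix mapping length-n input to length-N reflection-padded
pad_matrix <- function(n, N, lo) {
  P <- matrix(0, N, n)
  for (p in seq_len(N)) {
    q <- p - lo
    while (q < 1 || q > n) {
      if (q < 1) q <- 2 - q
      if (q > n) q <- 2 * n - q
    }
    P[p, q] <- 1
  }
  P
}

apply_axis_mat <- function(x, axis, M) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- M %*% matrix(xp, nrow = d[axis])
  nd <- d[perm]; nd[1] <- nrow(M)
  aperm(array(m, nd), order(perm))
}

pad_to_divisible <- function(x, div) {
  d <- dim(x)[1:3]
  target <- ceiling(d / div) * div
  mats <- vector("list", 3)
  for (a in 1:3) {
    if (target[a] > d[a]) {
      pad <- target[a] - d[a]
      lo <- pad %/% 2
      mats[[a]] <- pad_matrix(d[a], target[a], lo)
      x <- apply_axis_mat(x, a, mats[[a]])
    }
  }
  list(y = x, mats = mats, orig = d)
}

unpad_crop <- function(y, info) {
  d <- dim(y)
  idx <- lapply(1:3, function(a) {
    if (is.null(info$mats[[a]])) seq_len(info$orig[a])
    else {
      pad <- d[a] - info$orig[a]
      lo <- pad %/% 2
      lo + seq_len(info$orig[a])
    }
  })
  y[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
}

# adjoint of (pad -> unet -> crop): embed gradient, then fold padding
pad_embed_adjoint <- function(dy, info, padded_dim) {
  out <- array(0, padded_dim)
  d <- padded_dim[1:3]
  idx <- lapply(1:3, function(a) {
    if (is.null(info$mats[[a]])) seq_len(info$orig[a])
    else ((d[a] - info$orig[a]) %/% 2) + seq_len(info$orig[a])
  })
  out[idx[[1]], idx[[2]], idx[[3]], ] <- dy
  out
}

pad_fold_adjoint <- function(dx, info) {
  for (a in 3:1) {
    if (!is.null(info$mats[[a]])) dx <- apply_axis_mat(dx, a, t(info$mats[[a]]))
  }
  dx
}

# apply a U-Net to a complex image with pad/crop; returns value + cache
unet_apply <- function(unet, m_complex, div) {
  x <- pack_complex(m_complex)
  info <- pad_to_divisible(x, div)
  r <- nn_forward(unet, info$y)
  padded_dim <- dim(r$y)
  ycrop <- unpad_crop(r$y, info)
  list(y = unpack_complex(ycrop),
       cache = list(info = info, unet_cache = r$cache,
                    padded_dim = padded_dim))
}

unet_apply_backward <- function(unet, cache, g_complex) {
  dy <- pack_complex(g_complex)
  dfull <- pad_embed_adjoint(dy, cache$info, cache$padded_dim)
  dx <- nn_backward(unet, cache$unet_cache, dfull)
  dx <- pad_fold_adjoint(dx, cache$info)
  unpack_complex(dx)
}

pack_complex <- function(m) {
  d <- dim(m)
  array(c(Re(m), Im(m)), c(d, 2L))
}

unpack_complex <- function(x) {
  d <- dim(x)
  n <- prod(d[1:3])
  array(complex(real = x[seq_len(n)], imaginary = x[n + seq_len(n)]), d[1:3])
}

pool_divisor <- function(cfg) {
  st <- varnet_strides(cfg)
  Reduce(`*`, st, accumulate = FALSE)
}

# ---- sensitivity estimation ----------------------------------------------------

acs_mask_3d <- function(mask, nx) {
  ce <- mask$calib_extent
  if (length(ce) < 2 || any(ce <= 0))
    abort("sampling mask has no calibration block", "tofrecon_calibration")
  pe <- mask$pe_mask * 0L
  cr <- calib_ranges(nrow(pe), ncol(pe), ce)
  pe[cr$y, cr$z] <- 1L
  pf <- mask$pf_mask
  if (length(pf) == 1L) pf <- rep(1L, nx)
  mask_3d(sampling_mask(pe, pf, ce, mask$target_R))
}

#' Estimate coil sensitivity maps with the sensitivity U-Net
#'
#' Zeroes all k-space outside the fully sampled calibration block (restricted
#' to the acquired partial-Fourier region), inverse-transforms each coil,
#' refines each low-resolution coil image with the sensitivity U-Net, and
#' sum-of-squares-normalises the stack. The output depends only on
#' calibration-region samples.
#'
#' @param model a `varnet_model`.
#' @param kspace complex `(n_coils, nx, ny, nz)` masked k-space.
#' @param mask a [sampling_mask()] with a nonzero `calib_extent`.
#' @return a [coil_sensitivities()].
#' @export
estimate_sensitivities <- function(model, kspace, mask) {
  sens_forward(model, kspace, mask)$S
}

sens_forward <- function(model, kspace, mask) {
  d <- dim(kspace)
  acs <- acs_mask_3d(mask, d[2])
  div <- pool_divisor(model$cfg)
  nc <- d[1]
  u <- array(complex(real = 0), d)
  caches <- vector("list", nc)
  for (i in seq_len(nc)) {
    img <- ifft3c(array(kspace[i, , , ], d[-1]) * acs)
    r <- unet_apply(model$sens_unet, img, div)
    u[i, , , ] <- r$y
    caches[[i]] <- r$cache
  }
  sos <- sqrt(pmax(colSums(Mod(u)^2, dims = 1), 1e-30))
  S <- u
  for (i in seq_len(nc)) S[i, , , ] <- array(u[i, , , ], d[-1]) / sos
  list(S = coil_sensitivities(S, check = FALSE), u = u, r = sos,
       caches = caches)
}

sens_backward <- function(model, sf, gS) {
  d <- dim(sf$u)
  nc <- d[1]
  # A(r) = sum_i Re(conj(gS_i) * u_i) per voxel
  A <- array(0, d[-1])
  for (i in seq_len(nc)) {
    A <- A + Re(Conj(array(gS[i, , , ], d[-1])) * array(sf$u[i, , , ], d[-1]))
  }
  r <- sf$r
  for (i in seq_len(nc)) {
    gu <- array(gS[i, , , ], d[-1]) / r -
      array(sf$u[i, , , ], d[-1]) * A / r^3
    unet_apply_backward(model$sens_unet, sf$caches[[i]], gu)
  }
  invisible(NULL)
}

# ---- data consistency -----------------------------------------------------------

#' Cascade state for data consistency
#'
#' @param current_kspace complex `(n_coils, nx, ny, nz)` iterate.
#' @param reference_kspace measured k-space (zero off-mask).
#' @param mask a [sampling_mask()].
#' @param eta soft-DC step (used when `mode = "soft"`).
#' @return object of class `cascade_state`.
#' @export
cascade_state <- function(current_kspace, reference_kspace, mask, eta = 1) {
  assert_that(identical(dim(current_kspace), dim(reference_kspace)),
              "k-space shapes differ", "tofrecon_shape_error")
  structure(list(current_kspace = current_kspace,
                 reference_kspace = reference_kspace, mask = mask,
                 eta = eta),
            class = "cascade_state")
}

#' Data-consistency step
#'
#' Hard mode replaces the iterate at every acquired location (phase-encode
#' mask AND acquired partial-Fourier region) by the measured value — the
#' asymmetric PF band and unsampled points pass through unchanged — and is
#' idempotent. Soft mode computes
#' `current - eta * M * (current - reference)`.
#'
#' @param state a [cascade_state()].
#' @param mode `"hard"` or `"soft"`.
#' @return the updated [cascade_state()].
#' @export
dc_step <- function(state, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  d <- dim(state$current_kspace)
  mask <- state$mask
  if (length(mask$pf_mask) == 1L) mask$pf_mask <- rep(1L, d[2])
  m3 <- mask_3d(mask)
  k <- state$current_kspace
  for (i in seq_len(d[1])) {
    ki <- array(k[i, , , ], d[-1])
    ri <- array(state$reference_kspace[i, , , ], d[-1])
    k[i, , , ] <- if (mode == "hard") {
      ki * (1 - m3) + ri * m3
    } else {
      ki - state$eta * m3 * (ki - ri)
    }
  }
  cascade_state(k, state$reference_kspace, state$mask, state$eta)
}

# ---- full unrolled forward / backward -------------------------------------------

varnet_apply <- function(model, kspace, mask, with_tape = FALSE) {
  cfg <- model$cfg
  d <- dim(kspace)
  if (length(mask$pf_mask) == 1L)
    mask <- sampling_mask(mask$pe_mask, rep(1L, d[2]), mask$calib_extent,
                          mask$target_R)
  m3 <- mask_3d(mask)
  div <- pool_divisor(cfg)

  sf <- sens_forward(model, kspace, mask)
  S <- sf$S
  y <- kspace
  k <- kspace
  tapes <- vector("list", cfg$n_cascades)
  for (t in seq_len(cfg$n_cascades)) {
    m <- sens_reduce(k, S)
    ur <- unet_apply(model$cascades[[t]]$unet, m, div)
    r_ks <- sens_expand(ur$y, S)
    k_in <- k
    if (cfg$dc_mode == "hard") {
      k <- k_in - r_ks
      for (i in seq_len(d[1])) {
        ki <- array(k[i, , , ], d[-1]); yi <- array(y[i, , , ], d[-1])
        k[i, , , ] <- ki * (1 - m3) + yi * m3
      }
    } else {
      eta <- model$cascades[[t]]$eta$W[1]
      for (i in seq_len(d[1])) {
        ki <- array(k_in[i, , , ], d[-1]); yi <- array(y[i, , , ], d[-1])
        ri <- array(r_ks[i, , , ], d[-1])
        k[i, , , ] <- ki - eta * m3 * (ki - yi) - ri
      }
    }
    if (with_tape) tapes[[t]] <- list(k_in = k_in, u_img = ur$y,
                                      unet_cache = ur$cache)
  }
  # final hard DC, then coil combine
  k_fin <- k
  for (i in seq_len(d[1])) {
    ki <- array(k_fin[i, , , ], d[-1]); yi <- array(y[i, , , ], d[-1])
    k_fin[i, , , ] <- ki * (1 - m3) + yi * m3
  }
  m_fin <- sens_reduce(k_fin, S)
  out <- Mod(m_fin)
  if (!with_tape) return(list(out = out))
  list(out = out,
       tape = list(sf = sf, S = S, tapes = tapes, k_fin = k_fin,
                   m_fin = m_fin, m3 = m3, y = y, mask = mask, d = d))
}

# adjoint pieces; gradients g are dL/dRe + i dL/dIm
reduce_backward <- function(g_m, k, S, gS) {
  d <- dim(k)
  g_k <- array(complex(real = 0), d)
  for (i in seq_len(d[1])) {
    Si <- array(S$maps[i, , , ], d[-1])
    ti <- ifft3c(array(k[i, , , ], d[-1]))
    g_k[i, , , ] <- fft3c(Si * g_m)
    gS[i, , , ] <- array(gS[i, , , ], d[-1]) + ti * Conj(g_m)
  }
  list(g_k = g_k, gS = gS)
}

expand_backward <- function(g_r, u_img, S, gS) {
  d <- dim(g_r)
  g_u <- array(complex(real = 0), d[-1])
  for (i in seq_len(d[1])) {
    Si <- array(S$maps[i, , , ], d[-1])
    vi <- ifft3c(array(g_r[i, , , ], d[-1]))
    g_u <- g_u + Conj(Si) * vi
    gS[i, , , ] <- array(gS[i, , , ], d[-1]) + Conj(u_img) * vi
  }
  list(g_u = g_u, gS = gS)
}

varnet_backward <- function(model, tape, g_out) {
  cfg <- model$cfg
  d <- tape$d
  m3 <- tape$m3
  S <- tape$S
  div <- pool_divisor(cfg)
  gS <- array(complex(real = 0), d)

  mag <- pmax(Mod(tape$m_fin), 1e-30)
  g_m <- g_out * tape$m_fin / mag
  rb <- reduce_backward(g_m, tape$k_fin, S, gS)
  gS <- rb$gS
  g_k <- rb$g_k
  for (i in seq_len(d[1])) { # final hard DC: acquired samples carry no grad
    g_k[i, , , ] <- array(g_k[i, , , ], d[-1]) * (1 - m3)
  }

  for (t in rev(seq_len(cfg$n_cascades))) {
    tp <- tape$tapes[[t]]
    if (cfg$dc_mode == "hard") {
      # k_out = (k_in - r) off-mask + y on-mask; g already masked from caller?
      g_u <- g_k
      for (i in seq_len(d[1])) {
        g_u[i, , , ] <- array(g_k[i, , , ], d[-1]) * (1 - m3)
      }
      g_kin <- g_u
      g_r <- -g_u
    } else {
      eta <- model$cascades[[t]]$eta$W[1]
      g_kin <- g_k
      g_eta <- 0
      for (i in seq_len(d[1])) {
        gi <- array(g_k[i, , , ], d[-1])
        g_kin[i, , , ] <- gi * (1 - eta * m3)
        diff <- m3 * (array(tp$k_in[i, , , ], d[-1]) -
                        array(tape$y[i, , , ], d[-1]))
        g_eta <- g_eta - sum(Re(Conj(gi) * diff))
      }
      e <- model$cascades[[t]]$eta
      e$gW <- if (is.null(e$gW)) g_eta else e$gW + g_eta
      g_r <- -g_k
    }
    eb <- expand_backward(g_r, tp$u_img, S, gS)
    gS <- eb$gS
    g_m <- unet_apply_backward(model$cascades[[t]]$unet, tp$unet_cache,
                               eb$g_u)
    rb <- reduce_backward(g_m, tp$k_in, S, gS)
    gS <- rb$gS
    g_k <- g_kin + rb$g_k
  }
  sens_backward(model, tape$sf, gS)
  invisible(NULL)
}

#' Reconstruct a magnitude volume with the variational network
#'
#' Estimates sensitivities from the calibration region, runs the unrolled
#' cascades with data consistency, applies a final hard DC projection and
#' coil-combines. Deterministic in evaluation for fixed weights. Spatial
#' extents that are not divisible by the pooling product are handled by
#' internal reflection padding.
#'
#' @param model a `varnet_model` with weights.
#' @param masked_kspace complex `(n_coils, nx, ny, nz)` measured k-space.
#' @param mask the [sampling_mask()] used for acquisition.
#' @return real non-negative `(nx, ny, nz)` magnitude array.
#' @export
reconstruct <- function(model, masked_kspace, mask) {
  stopifnot(inherits(model, "varnet_model"))
  assert_that(!is.null(varnet_param_envs(model)[[1]]$W),
              "model was built without weights", "tofrecon_config_error")
  varnet_apply(model, masked_kspace, mask)$out
}
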