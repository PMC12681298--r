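# Linear MRI operators, coil compression, and the classical reconstruction
# baselines (zero-filling and L1-wavelet compressed sensing).

#' Coil expand / reduce operators
#'
#' `sens_expand()` maps a complex image `m` to per-coil k-space
#' `F{S_i * m}`; `sens_reduce()` maps multi-coil k-space back to an image via
#' `sum_i conj(S_i) * F^{-1}{k_i}`. With sum-of-squares-normalised maps the
#' pair satisfies `reduce(expand(m)) == m`, and the two operators are exact
#' adjoints of each other.
#'
#' @param image complex `(nx, ny, nz)` array.
#' @param kspace complex `(n_coils, nx, ny, nz)` array.
#' @param coils a [coil_sensitivities()].
#' @return `sens_expand`: complex `(n_coils, nx, ny, nz)`; `sens_reduce`:
#'   complex `(nx, ny, nz)`.
#' @export
sens_expand <- function(image, coils) {
  maps <- coils$maps
  d <- dim(maps)
  assert_that(identical(dim(image), d[-1]) ||
                identical(as.integer(dim(image)), as.integer(d[-1])),
              "image / coil map shape mismatch", "tofrecon_shape_error")
  out <- array(complex(real = 0), d)
  for (i in seq_len(d[1])) {
    out[i, , , ] <- fft3c(array(maps[i, , , ], d[-1]) * image)
  }
  out
}

#' @rdname sens_expand
#' @export
sens_reduce <- function(kspace, coils) {
  maps <- coils$maps
  d <- dim(kspace)
  assert_that(identical(as.integer(dim(maps)), as.integer(d)),
              "k-space / coil map shape mismatch", "tofrecon_shape_error")
  acc <- array(complex(real = 0), d[-1])
  for (i in seq_len(d[1])) {
    acc <- acc + Conj(array(maps[i, , , ], d[-1])) *
      ifft3c(array(kspace[i, , , ], d[-1]))
  }
  acc
}

#' Root-sum-of-squares coil combination
#'
#' @param coil_images complex `(n_coils, nx, ny, nz)` array of coil images.
#' @return real `(nx, ny, nz)` array.
#' @export
rss_combine <- function(coil_images) {
  sqrt(colSums(Mod(coil_images)^2, dims = 1))
}

#' SVD-based coil compression
#'
#' Projects the coil dimension onto the top `n_virtual` left singular vectors
#' of the samples-by-coils data matrix (computed via the coil-by-coil Gram
#' matrix), reducing computational burden while retaining most of the signal
#' energy.
#'
#' @param kspace complex `(n_coils, ...)` array.
#' @param n_virtual number of virtual coils to keep (default 8).
#' @return compressed k-space array with `n_virtual` leading channels;
#'   attribute `energy_retained` gives the retained eigen-energy fraction.
#' @export
coil_compress_svd <- function(kspace, n_virtual = 8) {
  d <- dim(kspace)
  nc <- d[1]
  assert_that(n_virtual <= nc, "n_virtual must be <= n_coils",
              "tofrecon_invalid_config")
  A <- matrix(kspace, nrow = nc) # coils x samples
  G <- A %*% Conj(t(A))          # Hermitian Gram matrix, coils x coils
  eig <- eigen(G, symmetric = TRUE)
  U <- eig$vectors[, seq_len(n_virtual), drop = FALSE]
  comp <- Conj(t(U)) %*% A
  out <- array(comp, c(n_virtual, d[-1]))
  ev <- pmax(Re(eig$values), 0)
  attr(out, "energy_retained") <- sum(ev[seq_len(n_virtual)]) / sum(ev)
  out
}

#' Symmetric centre crop of k-space in the in-plane axes
#'
#' Crops the two in-plane spatial axes (the first two after the coil axis)
#' around the array centre; the slice and coil axes are untouched. The DC
#' sample (centred convention) is preserved.
#'
#' @param kspace complex `(n_coils, nx, ny, nz)` array.
#' @param target integer length-2 in-plane target size.
#' @return cropped k-space array.
#' @export
crop_center_kspace <- function(kspace, target = c(256, 256)) {
  d <- dim(kspace)
  assert_that(target[1] <= d[2] && target[2] <= d[3],
              "crop target larger than input", "tofrecon_invalid_config")
  rx <- crop_range(d[2], target[1])
  ry <- crop_range(d[3], target[2])
  kspace[, rx, ry, , drop = FALSE]
}

# centred crop index range preserving the DC sample at floor(n/2)+1
crop_range <- function(n, m) {
  c0 <- floor(n / 2) + 1
  start <- c0 - floor(m / 2)
  start:(start + m - 1)
}

#' Zero-filling reconstruction
#'
#' Inverse-transforms the (masked) k-space per coil and combines with
#' root-sum-of-squares, or with the conjugate of the coil maps when they are
#' supplied. No inpainting of missing samples is attempted.
#'
#' @param kspace complex `(n_coils, nx, ny, nz)` masked k-space.
#' @param coils optional [coil_sensitivities()]; if NULL, RSS combination.
#' @return real non-negative `(nx, ny, nz)` magnitude array.
#' @export
zero_fill_recon <- function(kspace, coils = NULL) {
  if (is.null(coils)) {
    rss_combine(fftc_coils(kspace, inverse = TRUE))
  } else {
    Mod(sens_reduce(kspace, coils))
  }
}

#' Decouple the readout axis by inverse Fourier transform
#'
#' Utility for 2D (slice-by-slice) baselines: applies the centred unitary
#' inverse transform along the readout axis only, turning 3D k-space into a
#' stack of 2D ky-kz k-space planes indexed by readout position.
#'
#' @param kspace complex `(n_coils, nx, ny, nz)` array.
#' @return same-shaped array, hybrid (x, ky, kz) space.
#' @export
readout_decouple <- function(kspace) {
  d <- dim(kspace)
  nx <- d[2]
  # centred unitary 1D inverse FFT along axis 2
  k <- aperm(kspace, c(2, 1, 3, 4))
  m <- matrix(k, nrow = nx)
  m <- ifftshift_rows(m, nx)
  m <- stats::mvfft(m, inverse = TRUE) / sqrt(nx)
  m <- fftshift_rows(m, nx)
  aperm(array(m, c(nx, d[1], d[3], d[4])), c(2, 1, 3, 4))
}

fftshift_rows <- function(m, n) m[((seq_len(n) - 1 - floor(n / 2)) %% n) + 1, ,
                                  drop = FALSE]
ifftshift_rows <- function(m, n) m[((seq_len(n) - 1 + floor(n / 2)) %% n) + 1, ,
                                   drop = FALSE]

# ---- orthogonal wavelet transform (Daubechies-4, periodic) ------------------

DB4_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
DB4_G <- rev(DB4_H) * c(1, -1, 1, -1)

# one-level analysis along the first axis of a matrix (columns = signals)
dwt_axis <- function(m, n) {
  half <- n / 2
  idx <- function(off) ((2 * (seq_len(half) - 1) + off) %% n) + 1
  lo <- DB4_H[1] * m[idx(0), , drop = FALSE]
  hi <- DB4_G[1] * m[idx(0), , drop = FALSE]
  for (t in 2:4) {
    rows <- idx(t - 1)
    lo <- lo + DB4_H[t] * m[rows, , drop = FALSE]
    hi <- hi + DB4_G[t] * m[rows, , drop = FALSE]
  }
  rbind(lo, hi)
}

idwt_axis <- function(m, n) {
  half <- n / 2
  lo <- m[seq_len(half), , drop = FALSE]
  hi <- m[half + seq_len(half), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  if (is.complex(m)) out <- matrix(complex(real = 0), n, ncol(m))
  for (t in 1:4) {
    rows <- ((2 * (seq_len(half) - 1) + (t - 1)) %% n) + 1
    out[rows, ] <- out[rows, ] + DB4_H[t] * lo + DB4_G[t] * hi
  }
  out
}

apply_axis <- function(x, axis, fun) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  m <- fun(m, d[axis])
  xp <- array(m, d[perm])
  aperm(xp, order(perm))
}

#' Orthogonal 3D discrete wavelet transform (Daubechies-4, periodic)
#'
#' Multi-level separable DWT applied to the low-pass corner at each level.
#' The transform is orthonormal: it preserves the L2 norm and
#' `idwt3(dwt3(x)) == x` to machine precision. All dims must be divisible by
#' `2^levels`.
#'
#' @param x numeric or complex 3D array.
#' @param levels decomposition depth.
#' @return coefficient array of the same shape.
#' @export
dwt3 <- function(x, levels = 3) {
  d <- dim(x)
  assert_that(all(d %% 2^levels == 0),
              "dims must be divisible by 2^levels", "tofrecon_invalid_config")
  cur <- d
  for (l in seq_len(levels)) {
    sub <- x[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3]), drop = FALSE]
    for (ax in 1:3) sub <- apply_axis(sub, ax, dwt_axis)
    x[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3])] <- sub
    cur <- cur / 2
  }
  x
}

#' @rdname dwt3
#' @export
idwt3 <- function(x, levels = 3) {
  d <- dim(x)
  cur <- d / 2^(levels - 1)
  for (l in seq_len(levels)) {
    sub <- x[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3]), drop = FALSE]
    for (ax in 1:3) sub <- apply_axis(sub, ax, idwt_axis)
    x[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3])] <- sub
    cur <- cur * 2
  }
  x
}

# ---- L1-wavelet compressed sensing (FISTA) ----------------------------------

#' Compressed-sensing solver configuration
#'
#' @param lambda regularisation weight, RELATIVE to the maximum magnitude of
#'   the zero-filled coil-combined image (scaled internally).
#' @param n_iters FISTA iterations.
#' @param levels wavelet decomposition levels (capped by divisibility).
#' @param step gradient step size; the forward operator has unit spectral
#'   norm with SoS-normalised coils, so 1 is safe.
#' @return object of class `cs_config`.
#' @export
cs_config <- function(lambda = 0.005, n_iters = 60, levels = 3, step = 1) {
  assert_that(lambda >= 0 && n_iters >= 1 && step > 0,
              "invalid CS config", "tofrecon_invalid_config")
  structure(list(lambda = lambda, n_iters = as.integer(n_iters),
                 levels = as.integer(levels), step = step),
            class = "cs_config")
}

soft_threshold <- function(z, t) {
  m <- Mod(z)
  scale <- pmax(m - t, 0) / pmax(m, 1e-30)
  z * scale
}

#' L1-wavelet regularised compressed-sensing reconstruction
#'
#' Solves `min_m 0.5 ||M F S m - y||^2 + lambda ||Psi m||_1` with FISTA
#' (accelerated proximal gradient, restart on objective increase), where
#' `Psi` is the orthogonal Daubechies-4 DWT applied to the complex image.
#' Returns the magnitude of the final iterate.
#'
#' @param kspace complex `(n_coils, nx, ny, nz)` masked k-space.
#' @param mask a [sampling_mask()].
#' @param coils a [coil_sensitivities()] (SoS-normalised).
#' @param cfg a [cs_config()].
#' @return real magnitude array; attribute `objective` holds the per-iteration
#'   objective trace.
#' @export
cs_l1wavelet_recon <- function(kspace, mask, coils, cfg = cs_config()) {
  d <- dim(kspace)
  shape <- d[-1]
  if (length(mask$pf_mask) == 1L)
    mask <- sampling_mask(mask$pe_mask, rep(1L, shape[1]),
                          mask$calib_extent, mask$target_R)
  m3 <- mask_3d(mask)
  levels <- min(cfg$levels, max_dwt_levels(shape))

  mask_coils <- function(k) {
    for (i in seq_len(d[1])) k[i, , , ] <- array(k[i, , , ], shape) * m3
    k
  }
  y <- mask_coils(kspace)
  A <- function(m) mask_coils(sens_expand(m, coils))
  At <- function(k) sens_reduce(mask_coils(k), coils)

  m0 <- At(y)
  lam <- cfg$lambda * max(Mod(m0))
  obj <- function(m) {
    r <- A(m) - y
    0.5 * sum(Mod(r)^2) + lam * sum(Mod(dwt3(m, levels)))
  }

  m <- m0; z <- m0; t_acc <- 1
  trace <- numeric(cfg$n_iters)
  prev_obj <- Inf; n_bad <- 0L
  for (it in seq_len(cfg$n_iters)) {
    grad <- At(A(z) - y)
    w <- dwt3(z - cfg$step * grad, levels)
    m_new <- idwt3(soft_threshold(w, cfg$step * lam), levels)
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    z <- m_new + ((t_acc - 1) / t_new) * (m_new - m)
    cur <- obj(m_new)
    trace[it] <- cur
    if (cur > prev_obj) { # restart acceleration on objective increase
      z <- m_new; t_new <- 1
      n_bad <- n_bad + 1L
      if (n_bad >= 5L)
        abort("CS objective increased 5 consecutive restarts: step too large",
              "tofrecon_step_size")
    } else n_bad <- 0L
    prev_obj <- cur
    m <- m_new; t_acc <- t_new
  }
  out <- Mod(m)
  attr(out, "objective") <- trace
  out
}

max_dwt_levels <- function(shape) {
  lv <- 0L
  while (all(shape %% 2 == 0) && min(shape) / 2 >= 4) {
    lv <- lv + 1L
    shape <- shape / 2
  }
  max(lv, 1L)
}
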