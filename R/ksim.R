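# Raw k-space simulation: turn a magnitude volume into a realistic
# complex-valued multi-coil undersampled acquisition.
#
# Phase model: the conjugate-symmetric k-space of the magnitude image is
# corrupted by several Gaussian-weighted complex white-noise components and
# the phase of the resulting image is kept; the noise amplitudes are chosen
# to exceed the magnitude signal so the phase is not biased toward zero.
# Coil model: per-coil anisotropic 3D Gaussians centred on head-boundary
# voxels (randomly rotated about z) plus modulated complex noise, normalised
# across coils to unit sum-of-squares.

# ---- head mask -------------------------------------------------------------

# shift a logical 3D array by one voxel along `axis` (+1/-1), zero-filled
shift1 <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] - 1); idx_src[[axis]] <- 2:d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

neighbor_stack <- function(m) {
  list(shift1(m, 1, 1), shift1(m, 1, -1),
       shift1(m, 2, 1), shift1(m, 2, -1),
       shift1(m, 3, 1), shift1(m, 3, -1))
}

#' Binary erosion / dilation with the 6-connected structuring element
#'
#' One iteration erodes (or dilates) by the 3D cross (face-connectivity)
#' structuring element; voxels outside the array are treated as background.
#'
#' @param mask logical 3D array.
#' @param iterations integer >= 0.
#' @return logical 3D array.
#' @export
binary_erode <- function(mask, iterations = 1) {
  for (i in seq_len(iterations)) {
    nb <- neighbor_stack(mask)
    mask <- mask & nb[[1]] & nb[[2]] & nb[[3]] & nb[[4]] & nb[[5]] & nb[[6]]
  }
  mask
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, iterations = 1) {
  for (i in seq_len(iterations)) {
    nb <- neighbor_stack(mask)
    mask <- mask | nb[[1]] | nb[[2]] | nb[[3]] | nb[[4]] | nb[[5]] | nb[[6]]
  }
  mask
}

#' Otsu threshold of a numeric array
#'
#' Maximises the between-class variance over a 256-bin histogram.
#'
#' @param x numeric array; must not be constant.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2])
    abort("constant volume: no Otsu threshold exists", "tofrecon_no_threshold")
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = nb)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w <- cumsum(h); mu <- cumsum(h * mids)
  tot_w <- w[nb]; tot_mu <- mu[nb]
  w0 <- w[-nb]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (tot_mu * w0[valid] - mu[-nb][valid] * tot_w)^2 /
    (w0[valid] * w1[valid])
  br[which.max(bcv) + 1L]
}

#' Extract the head mask of a magnitude volume
#'
#' Otsu thresholding, then binary erosion (4 iterations) and binary dilation
#' (9 iterations) with the 6-connected structuring element, mirroring common
#' brain-extraction preprocessing; finally the surface voxels of the mask are
#' collected as candidate coil-centre locations.
#'
#' @param volume a [magnitude_volume()] (or plain 3D array).
#' @param erode_iter,dilate_iter morphology iteration counts.
#' @return object of class `head_mask`: `mask` (logical 3D array) and
#'   `boundary` (integer matrix, one voxel coordinate per row).
#' @export
compute_head_mask <- function(volume, erode_iter = 4, dilate_iter = 9) {
  x <- if (inherits(volume, "magnitude_volume")) volume$data else volume
  thr <- otsu_threshold(x)
  m <- x > thr
  m <- binary_erode(m, erode_iter)
  if (!any(m))
    abort("mask empty after erosion: degenerate head mask",
          "tofrecon_degenerate_mask")
  m <- binary_dilate(m, dilate_iter)
  head_mask(m)
}

#' Construct a head mask from a logical array
#'
#' Boundary voxels are mask voxels with at least one in-bounds background
#' 6-neighbour.
#'
#' @param mask logical 3D array.
#' @return `head_mask` object.
#' @export
head_mask <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask))
    abort("empty head mask", "tofrecon_degenerate_mask")
  interior <- binary_erode(mask, 1)
  # erosion treats out-of-bounds as background; a voxel at the array edge is
  # NOT interior under that convention, but it has no in-bounds background
  # neighbour unless an in-bounds neighbour is background, so recompute:
  nb <- neighbor_stack(!mask)
  has_bg_nb <- nb[[1]] | nb[[2]] | nb[[3]] | nb[[4]] | nb[[5]] | nb[[6]]
  boundary <- which(mask & has_bg_nb, arr.ind = TRUE)
  structure(list(mask = mask, boundary = boundary), class = "head_mask")
}

# ---- phase simulation ------------------------------------------------------

#' Configuration for phase simulation
#'
#' `n_components` Gaussian-weighted complex white-noise fields are added to
#' the (conjugate-symmetric) k-space of the magnitude image; the phase of the
#' corrupted image is the simulated phase. Noise standard deviations are
#' expressed relative to `max(|x|)`, Gaussian-weight widths relative to the
#' axis length. Defaults keep the noise amplitude above the magnitude signal
#' (so the phase is not biased toward zero) and are package defaults pinned
#' by regression tests, not published values.
#'
#' @param n_components integer >= 0, number of noise components.
#' @param sigma_noise_range length-2, uniform range for the per-component
#'   noise SD as a multiple of `max(|x|)`.
#' @param sigma_gauss_range length-2, uniform range for the Gaussian weight
#'   SD as a fraction of axis length.
#' @param seed integer.
#' @return object of class `phase_sim_config`.
#' @export
phase_sim_config <- function(n_components = 3,
                             sigma_noise_range = c(0.5, 5),
                             sigma_gauss_range = c(0.02, 0.3),
                             seed = 1L) {
  assert_that(n_components >= 0, "n_components must be >= 0",
              "tofrecon_invalid_config")
  assert_that(all(sigma_noise_range > 0) && all(sigma_gauss_range > 0) &&
                all(sigma_gauss_range <= 1),
              "sigma ranges must be positive (gauss range in (0, 1])",
              "tofrecon_invalid_config")
  structure(list(n_components = as.integer(n_components),
                 sigma_noise_range = sigma_noise_range,
                 sigma_gauss_range = sigma_gauss_range,
                 seed = as.integer(seed)),
            class = "phase_sim_config")
}

# sum of n_components Gaussian-weighted complex white noise fields, built in
# centred k-space; returns the IMAGE-domain complex field
modulated_noise_field <- function(shape, n_components, sigma_noise_range,
                                  sigma_gauss_range, amplitude) {
  acc <- array(complex(real = 0), shape)
  n <- prod(shape)
  for (j in seq_len(n_components)) {
    s_n <- stats::runif(1, sigma_noise_range[1], sigma_noise_range[2]) *
      amplitude
    s_g <- stats::runif(1, sigma_gauss_range[1], sigma_gauss_range[2])
    nj <- array(complex(real = stats::rnorm(n, sd = s_n),
                        imaginary = stats::rnorm(n, sd = s_n)), shape)
    acc <- acc + gaussian_kweight(shape, s_g) * nj
  }
  ifft3c(acc)
}

#' Simulate a phase volume from a magnitude image
#'
#' The simulated phase is `arg(|x(r)| + F^{-1}[sum_j W(k; sigma_Gj) n_j(k)])`
#' with complex white Gaussian noise `n_j` and zero-centred Gaussian k-space
#' weights `W`; per-component SDs are drawn from the config ranges.
#' Deterministic given `cfg$seed`. With `n_components = 0` the phase is
#' exactly zero wherever `|x| > 0`.
#'
#' @param volume a [magnitude_volume()].
#' @param cfg a [phase_sim_config()].
#' @return real 3D array of phases in `(-pi, pi]`.
#' @export
simulate_phase <- function(volume, cfg = phase_sim_config()) {
  stopifnot(inherits(volume, "magnitude_volume"),
            inherits(cfg, "phase_sim_config"))
  x <- volume$data
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "phase"))
  noise <- modulated_noise_field(dim(x), cfg$n_components,
                                 cfg$sigma_noise_range, cfg$sigma_gauss_range,
                                 amplitude = max(x))
  Arg(x + noise)
}

# ---- coil sensitivity maps -------------------------------------------------

#' Configuration for coil sensitivity map simulation
#'
#' Each coil map is an anisotropic 3D Gaussian centred on a random
#' head-boundary voxel and randomly rotated about the z-axis, plus
#' `n_components` modulated complex-noise fields (independent per coil); the
#' stack is normalised to unit sum-of-squares across coils at every voxel.
#'
#' @param n_coils number of receiver coils (32 emulates a standard head
#'   array).
#' @param n_components modulated noise components per coil.
#' @param sigma_noise_range noise SD range, relative to the unit Gaussian
#'   peak.
#' @param sigma_gauss_range k-space Gaussian weight SD range (fraction of
#'   axis length).
#' @param sigma_xyz_range per-axis spatial Gaussian SD range (fraction of
#'   axis length).
#' @param seed integer.
#' @return object of class `coil_sim_config`.
#' @export
coil_sim_config <- function(n_coils = 32,
                            n_components = 2,
                            sigma_noise_range = c(0.05, 0.3),
                            sigma_gauss_range = c(0.02, 0.3),
                            sigma_xyz_range = c(0.15, 0.5),
                            seed = 1L) {
  assert_that(n_coils >= 1, "n_coils must be >= 1", "tofrecon_invalid_config")
  assert_that(n_components >= 0 && all(sigma_noise_range > 0) &&
                all(sigma_gauss_range > 0) && all(sigma_xyz_range > 0),
              "invalid coil sim ranges", "tofrecon_invalid_config")
  structure(list(n_coils = as.integer(n_coils),
                 n_components = as.integer(n_components),
                 sigma_noise_range = sigma_noise_range,
                 sigma_gauss_range = sigma_gauss_range,
                 sigma_xyz_range = sigma_xyz_range,
                 seed = as.integer(seed)),
            class = "coil_sim_config")
}

#' Coil sensitivity container
#'
#' @param maps complex 4D array `(n_coils, nx, ny, nz)`, expected to satisfy
#'   `sum_i |S_i(r)|^2 == 1` at every voxel (tolerance 1e-5).
#' @param check validate the sum-of-squares invariant.
#' @return object of class `coil_sensitivities`.
#' @export
coil_sensitivities <- function(maps, check = TRUE) {
  stopifnot(is.complex(maps), length(dim(maps)) == 4L)
  if (check) {
    sos <- colSums(Mod(maps)^2, dims = 1)
    assert_that(max(abs(sos - 1)) < 1e-5,
                "coil maps are not sum-of-squares normalised")
  }
  structure(list(maps = maps), class = "coil_sensitivities")
}

#' Simulate coil sensitivity maps
#'
#' For each coil, a centre is drawn uniformly from the head-mask boundary, an
#' anisotropic Gaussian with per-axis SDs drawn from
#' `cfg$sigma_xyz_range` (fraction of axis length) is rotated by a uniform
#' angle in `[0, pi)` about the z-axis, and modulated complex noise is added;
#' the final stack is sum-of-squares normalised. Deterministic given
#' `cfg$seed`.
#'
#' @param volume a [magnitude_volume()] (defines the grid).
#' @param head a [head_mask()].
#' @param cfg a [coil_sim_config()].
#' @return a [coil_sensitivities()]; attribute `centers` holds the sampled
#'   coil centres (voxel coordinates, one row per coil).
#' @export
simulate_coil_maps <- function(volume, head, cfg = coil_sim_config()) {
  stopifnot(inherits(volume, "magnitude_volume"), inherits(head, "head_mask"),
            inherits(cfg, "coil_sim_config"))
  if (nrow(head$boundary) == 0)
    abort("head mask has an empty boundary", "tofrecon_degenerate_mask")
  shape <- dim(volume$data)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "coils"))

  g <- coord_grids(shape) # normalized [-1, 1]; SDs as fractions of axis
  maps <- array(complex(real = 0), c(cfg$n_coils, shape))
  centers <- matrix(0L, cfg$n_coils, 3)
  for (i in seq_len(cfg$n_coils)) {
    ci <- head$boundary[sample.int(nrow(head$boundary), 1), ]
    centers[i, ] <- ci
    s <- stats::runif(3, cfg$sigma_xyz_range[1], cfg$sigma_xyz_range[2]) * 2
    theta <- stats::runif(1, 0, pi)
    cn <- 2 * (ci - 1) / pmax(shape - 1, 1) - 1 # centre in normalized coords
    dx <- g$x - cn[1]; dy <- g$y - cn[2]; dz <- g$z - cn[3]
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    G <- exp(-(u^2 / (2 * s[1]^2) + v^2 / (2 * s[2]^2) + dz^2 / (2 * s[3]^2)))
    noise <- modulated_noise_field(shape, cfg$n_components,
                                   cfg$sigma_noise_range,
                                   cfg$sigma_gauss_range, amplitude = 1)
    maps[i, , , ] <- G + noise
  }
  sos <- sqrt(pmax(colSums(Mod(maps)^2, dims = 1), 1e-300))
  for (i in seq_len(cfg$n_coils)) {
    maps[i, , , ] <- array(maps[i, , , ], shape) / sos
  }
  out <- coil_sensitivities(maps)
  attr(out, "centers") <- centers
  attr(out, "sigma_frac") <- NULL
  out
}

# ---- bias field ------------------------------------------------------------

#' Apply a random multiplicative polynomial bias field
#'
#' The volume is multiplied voxelwise by `exp(P(r))` where `P` is a random
#' polynomial of total degree `<= order` over coordinates normalised to
#' `[-1, 1]`, with coefficients uniform in `[-coefficient, coefficient]`.
#' This emulates receive-field inhomogeneity; the field is strictly positive.
#'
#' @param volume a [magnitude_volume()].
#' @param coefficient coefficient range half-width (default 0.3).
#' @param order maximal total polynomial degree (default 3).
#' @param seed integer.
#' @return a [magnitude_volume()]; `meta$bias_field` stores the applied
#'   multiplicative field.
#' @export
apply_bias_field <- function(volume, coefficient = 0.3, order = 3, seed = 1L) {
  stopifnot(inherits(volume, "magnitude_volume"))
  assert_that(coefficient >= 0 && order >= 0, "invalid bias-field parameters",
              "tofrecon_invalid_config")
  shape <- dim(volume$data)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "bias"))
  g <- coord_grids(shape)
  P <- array(0, shape)
  for (a in 0:order) for (b in 0:(order - a)) for (cc in 0:(order - a - b)) {
    coef <- stats::runif(1, -coefficient, coefficient)
    P <- P + coef * g$x^a * g$y^b * g$z^cc
  }
  field <- exp(P)
  magnitude_volume(volume$data * field, spacing = volume$spacing,
                   meta = c(volume$meta, list(bias_field = field)))
}

# ---- sampling masks --------------------------------------------------------

#' Sampling mask container
#'
#' Holds the 2D phase-encode (ky-kz) mask, the 1D readout partial-Fourier
#' mask, the calibration extent and the nominal acceleration.
#'
#' @param pe_mask binary `(ny, nz)` matrix.
#' @param pf_mask binary length-`nx` vector.
#' @param calib_extent integer length-2 `(cy, cz)`.
#' @param target_R nominal acceleration factor.
#' @return object of class `sampling_mask`.
#' @export
sampling_mask <- function(pe_mask, pf_mask, calib_extent = c(0L, 0L),
                          target_R = 1) {
  stopifnot(is.matrix(pe_mask), is.numeric(pf_mask) || is.integer(pf_mask))
  structure(list(pe_mask = (pe_mask != 0) * 1L,
                 pf_mask = (pf_mask != 0) * 1L,
                 calib_extent = as.integer(calib_extent),
                 target_R = target_R),
            class = "sampling_mask")
}

# full 3D sampling pattern (nx, ny, nz) from readout PF x phase-encode mask
mask_3d <- function(mask) {
  nx <- length(mask$pf_mask)
  pe <- mask$pe_mask
  array(outer(mask$pf_mask, as.vector(pe)), c(nx, dim(pe)))
}

# index ranges of the centred calibration block
calib_ranges <- function(ny, nz, calib) {
  cy <- calib[1]; cz <- calib[2]
  y0 <- floor(ny / 2) + 1 - floor(cy / 2)
  z0 <- floor(nz / 2) + 1 - floor(cz / 2)
  list(y = y0:(y0 + cy - 1), z = z0:(z0 + cz - 1))
}

#' One-sided readout partial-Fourier mask
#'
#' Omits `round(pf_fraction * n_readout)` contiguous samples (half-up
#' rounding) from the beginning of the readout axis; the symmetric centre and
#' the full opposite side are retained. `pf_fraction` is the OMITTED
#' fraction: PF = 26% means 74% of readout samples are acquired.
#'
#' @param n_readout readout axis length.
#' @param pf_fraction omitted fraction in `[0, 0.5)`.
#' @return integer 0/1 vector of length `n_readout`.
#' @export
make_pf_mask <- function(n_readout, pf_fraction) {
  assert_that(pf_fraction >= 0 && pf_fraction < 0.5,
              "pf_fraction must be in [0, 0.5)", "tofrecon_invalid_pf")
  n_zero <- round_half_up(pf_fraction * n_readout)
  c(rep(0L, n_zero), rep(1L, n_readout - n_zero))
}

#' Variable-density Poisson-disc phase-encode mask
#'
#' Draws a Poisson-disc sample set on the ky-kz grid whose local
#' minimum-distance radius grows linearly with distance from the k-space
#' centre, `r(k) = r0 * (1 + alpha * |k| / |k|_max)`, so sampling density
#' decreases radially. `r0` is calibrated by bisection so the achieved
#' sampled fraction (including the forced, fully sampled centred calibration
#' block) matches `1/R` within 2% where feasible. Two samples `p, q` conflict
#' when `|p - q| < min(r(p), r(q))`; the calibration block is exempt.
#' Deterministic given `seed`.
#'
#' @param ny,nz phase-encode grid size.
#' @param R nominal acceleration factor (>= 1).
#' @param calib integer length-2 calibration block size (default `c(12, 6)`).
#' @param seed integer.
#' @param alpha radial density slope.
#' @return a [sampling_mask()] with an all-ones `pf_mask`; attributes `r0`
#'   and `alpha` expose the calibrated radius law.
#' @export
make_poisson_mask <- function(ny, nz, R, calib = c(12, 6), seed = 1L,
                              alpha = 2) {
  assert_that(R >= 1, "R must be >= 1", "tofrecon_invalid_config")
  assert_that(calib[1] <= ny && calib[2] <= nz,
              "calibration block does not fit the grid",
              "tofrecon_invalid_config")
  if (R == 1) {
    return(sampling_mask(matrix(1L, ny, nz), rep(1L, 1), calib, 1))
  }
  target <- 1 / R
  n_calib <- prod(calib)
  if (target < n_calib / (ny * nz))
    abort(sprintf("R = %g infeasible: calibration block alone samples 1/%.1f",
                  R, ny * nz / n_calib), "tofrecon_infeasible")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "poisson"))
  pts <- as.matrix(expand.grid(y = seq_len(ny), z = seq_len(nz)))
  ctr <- c(floor(ny / 2) + 1, floor(nz / 2) + 1)
  dist_ctr <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  dmax <- max(dist_ctr)
  order_perm <- sample.int(nrow(pts)) # fixed across bisection evaluations
  cr <- calib_ranges(ny, nz, calib)
  in_calib <- pts[, 1] %in% cr$y & pts[, 2] %in% cr$z

  throw <- function(r0) {
    rad <- r0 * (1 + alpha * dist_ctr / dmax)
    acc_y <- acc_z <- numeric(0); acc_r <- numeric(0)
    sel <- logical(nrow(pts))
    for (idx in order_perm) {
      if (in_calib[idx]) next
      ri <- rad[idx]
      if (length(acc_y)) {
        d2 <- (acc_y - pts[idx, 1])^2 + (acc_z - pts[idx, 2])^2
        if (any(d2 < pmin(ri, acc_r)^2)) next
      }
      acc_y <- c(acc_y, pts[idx, 1]); acc_z <- c(acc_z, pts[idx, 2])
      acc_r <- c(acc_r, ri)
      sel[idx] <- TRUE
    }
    sel
  }
  frac <- function(sel) (sum(sel | in_calib)) / (ny * nz)

  lo <- 0.5; hi <- max(ny, nz)
  best <- NULL; best_err <- Inf
  for (it in 1:18) {
    mid <- (lo + hi) / 2
    sel <- throw(mid)
    f <- frac(sel)
    err <- abs(f - target) / target
    if (err < best_err) {
      best <- list(sel = sel, r0 = mid); best_err <- err
    }
    if (err < 0.02) break
    if (f > target) lo <- mid else hi <- mid
  }
  pe <- matrix(0L, ny, nz)
  pe[pts[best$sel | in_calib, , drop = FALSE]] <- 1L
  out <- sampling_mask(pe, rep(1L, 1), calib, R)
  attr(out, "r0") <- best$r0
  attr(out, "alpha") <- alpha
  out
}

# ---- acquisition assembly --------------------------------------------------

#' Simulated acquisition container
#'
#' @param kspace complex `(n_coils, nx, ny, nz)` array.
#' @param mask a [sampling_mask()].
#' @param truth_image complex `(nx, ny, nz)` ground-truth image.
#' @param truth_coils a [coil_sensitivities()] or NULL.
#' @param truth_phase real `(nx, ny, nz)` phase in `(-pi, pi]` or NULL.
#' @param meta provenance list.
#' @return object of class `simulated_acquisition`.
#' @export
simulated_acquisition <- function(kspace, mask, truth_image = NULL,
                                  truth_coils = NULL, truth_phase = NULL,
                                  meta = list()) {
  stopifnot(is.complex(kspace), length(dim(kspace)) == 4L)
  structure(list(kspace = kspace, mask = mask, truth_image = truth_image,
                 truth_coils = truth_coils, truth_phase = truth_phase,
                 meta = meta),
            class = "simulated_acquisition")
}

#' Combine magnitude, phase and coil maps into fully sampled k-space
#'
#' The ground-truth complex image is `|x| * exp(i * phase)`; each coil's
#' k-space is the centred unitary 3D Fourier transform of the coil-weighted
#' image. Because the coil maps are sum-of-squares normalised, the
#' root-sum-of-squares of the inverse transform recovers `|x|` exactly.
#'
#' @param volume a [magnitude_volume()].
#' @param phase real 3D phase array (radians).
#' @param coils a [coil_sensitivities()].
#' @return a [simulated_acquisition()] with an all-ones mask.
#' @export
compose_multicoil_kspace <- function(volume, phase, coils) {
  stopifnot(inherits(volume, "magnitude_volume"),
            inherits(coils, "coil_sensitivities"))
  shape <- dim(volume$data)
  assert_that(identical(dim(phase), as.integer(shape)) ||
                identical(dim(phase), shape),
              "phase shape mismatch", "tofrecon_shape_error")
  assert_that(identical(dim(coils$maps)[-1], as.integer(shape)) ||
                identical(dim(coils$maps)[-1], shape),
              "coil map shape mismatch", "tofrecon_shape_error")
  truth <- volume$data * exp(1i * phase)
  n_coils <- dim(coils$maps)[1]
  k <- array(complex(real = 0), c(n_coils, shape))
  for (i in seq_len(n_coils)) {
    k[i, , , ] <- fft3c(array(coils$maps[i, , , ], shape) * truth)
  }
  full_mask <- sampling_mask(matrix(1L, shape[2], shape[3]),
                             rep(1L, shape[1]), c(0L, 0L), 1)
  simulated_acquisition(k, full_mask, truth_image = truth,
                        truth_coils = coils, truth_phase = phase,
                        meta = volume$meta)
}

#' Apply a sampling mask to an acquisition
#'
#' Zeroes k-space samples excluded by `pe_mask (x) pf_mask`; retained samples
#' are bit-identical to the input.
#'
#' @param acq a [simulated_acquisition()].
#' @param mask a [sampling_mask()]; its `pf_mask` may have length 1 (treated
#'   as no PF) or `nx`.
#' @return the undersampled [simulated_acquisition()] carrying `mask`.
#' @export
undersample <- function(acq, mask) {
  stopifnot(inherits(acq, "simulated_acquisition"),
            inherits(mask, "sampling_mask"))
  d <- dim(acq$kspace)
  if (length(mask$pf_mask) == 1L) mask$pf_mask <- rep(1L, d[2])
  assert_that(length(mask$pf_mask) == d[2] &&
                all(dim(mask$pe_mask) == d[3:4]),
              "mask dimensions do not match k-space", "tofrecon_shape_error")
  m3 <- mask_3d(mask)
  k <- acq$kspace
  for (i in seq_len(d[1])) {
    k[i, , , ] <- array(k[i, , , ], d[-1]) * m3
  }
  simulated_acquisition(k, mask, truth_image = acq$truth_image,
                        truth_coils = acq$truth_coils,
                        truth_phase = acq$truth_phase, meta = acq$meta)
}

#' Full simulation pipeline: magnitude volume to undersampled acquisition
#'
#' Runs bias field, head-mask extraction, phase simulation, coil-map
#' simulation, k-space composition and (optionally) partial-Fourier +
#' Poisson-disc undersampling, all seeded from one integer.
#'
#' @param volume a [magnitude_volume()].
#' @param n_coils number of simulated coils.
#' @param R acceleration factor (1 = fully sampled).
#' @param pf_fraction omitted readout fraction (0 = no partial Fourier).
#' @param calib calibration block `(cy, cz)`.
#' @param seed integer master seed for this acquisition.
#' @param bias apply a random bias field first.
#' @param phase_cfg,coil_cfg optional config overrides (their seeds are
#'   re-derived from `seed`).
#' @return a [simulated_acquisition()].
#' @export
simulate_acquisition <- function(volume, n_coils = 8, R = 1,
                                 pf_fraction = 0, calib = c(12, 6),
                                 seed = 1L, bias = TRUE,
                                 phase_cfg = NULL, coil_cfg = NULL) {
  if (is.null(phase_cfg))
    phase_cfg <- phase_sim_config(seed = derive_seed(seed, "phase_cfg"))
  if (is.null(coil_cfg))
    coil_cfg <- coil_sim_config(n_coils = n_coils,
                                seed = derive_seed(seed, "coil_cfg"))
  vol <- if (bias) apply_bias_field(volume, seed = derive_seed(seed, "bias"))
         else volume
  head <- compute_head_mask(vol)
  phase <- simulate_phase(vol, phase_cfg)
  coils <- simulate_coil_maps(vol, head, coil_cfg)
  acq <- compose_multicoil_kspace(vol, phase, coils)
  d <- dim(vol$data)
  if (R > 1 || pf_fraction > 0) {
    pe <- if (R > 1) {
      make_poisson_mask(d[2], d[3], R, calib,
                        seed = derive_seed(seed, "mask"))
    } else {
      sampling_mask(matrix(1L, d[2], d[3]), rep(1L, 1), calib, 1)
    }
    msk <- sampling_mask(pe$pe_mask, make_pf_mask(d[1], pf_fraction),
                         calib_extent = pe$calib_extent, target_R = R)
    acq <- undersample(acq, msk)
  }
  acq$meta$seed <- seed
  acq
}

# ---- HDF5 I/O --------------------------------------------------------------

#' Save / load a simulated acquisition as HDF5
#'
#' Layout: float64 dataset pairs `kspace_re`/`kspace_im` (coil, kx, ky, kz),
#' `pe_mask` (ny, nz), `pf_mask` (nx), optional `sens_re`/`sens_im`,
#' `truth_re`/`truth_im`, `truth_phase`; root attributes `target_R` and
#' `calib_extent`. HDF5 has no native complex type, hence the re/im pairs.
#'
#' @param acq a [simulated_acquisition()].
#' @param path output `.h5` path.
#' @return `path` invisibly (`save`); a [simulated_acquisition()] (`load`).
#' @export
save_acquisition <- function(acq, path) {
  stopifnot(inherits(acq, "simulated_acquisition"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(acq$kspace), path, "kspace_re")
  rhdf5::h5write(Im(acq$kspace), path, "kspace_im")
  d <- dim(acq$kspace)
  pf <- acq$mask$pf_mask
  if (length(pf) == 1L) pf <- rep(1L, d[2])
  rhdf5::h5write(acq$mask$pe_mask, path, "pe_mask")
  rhdf5::h5write(pf, path, "pf_mask")
  if (!is.null(acq$truth_coils)) {
    rhdf5::h5write(Re(acq$truth_coils$maps), path, "sens_re")
    rhdf5::h5write(Im(acq$truth_coils$maps), path, "sens_im")
  }
  if (!is.null(acq$truth_image)) {
    rhdf5::h5write(Re(acq$truth_image), path, "truth_re")
    rhdf5::h5write(Im(acq$truth_image), path, "truth_im")
  }
  if (!is.null(acq$truth_phase))
    rhdf5::h5write(acq$truth_phase, path, "truth_phase")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.double(acq$mask$target_R), fid, "target_R")
  rhdf5::h5writeAttribute(as.integer(acq$mask$calib_extent), fid,
                          "calib_extent")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname save_acquisition
#' @export
load_acquisition <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path),
                                "tofrecon_io_error")
  re <- rhdf5::h5read(path, "kspace_re")
  im <- rhdf5::h5read(path, "kspace_im")
  k <- array(complex(real = re, imaginary = im), dim(re))
  pe <- as.matrix(rhdf5::h5read(path, "pe_mask"))
  pf <- as.vector(rhdf5::h5read(path, "pf_mask"))
  at <- rhdf5::h5readAttributes(path, "/")
  msk <- sampling_mask(pe, pf,
                       calib_extent = if (!is.null(at$calib_extent))
                         as.integer(at$calib_extent) else c(0L, 0L),
                       target_R = if (!is.null(at$target_R))
                         as.numeric(at$target_R) else 1)
  names_in_file <- rhdf5::h5ls(path)$name
  coils <- NULL
  if ("sens_re" %in% names_in_file) {
    sre <- rhdf5::h5read(path, "sens_re")
    sim <- rhdf5::h5read(path, "sens_im")
    coils <- coil_sensitivities(array(complex(real = sre, imaginary = sim),
                                      dim(sre)), check = FALSE)
  }
  truth <- NULL
  if ("truth_re" %in% names_in_file) {
    tre <- rhdf5::h5read(path, "truth_re")
    tim <- rhdf5::h5read(path, "truth_im")
    truth <- array(complex(real = tre, imaginary = tim), dim(tre))
  }
  phase <- if ("truth_phase" %in% names_in_file)
    rhdf5::h5read(path, "truth_phase") else NULL
  simulated_acquisition(k, msk, truth_image = truth, truth_coils = coils,
                        truth_phase = phase, meta = list(source = path))
}
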