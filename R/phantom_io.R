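# Magnitude volumes, synthetic TOF-like phantom, slab splitting.
#
# Axis convention: the two longer in-plane axes come first (x = readout,
# y = phase encode), the short slice axis is LAST. Thin-slab volumes
# therefore have dim = c(nx, ny, nz) with nx, ny >= nz.

#' Construct a magnitude volume
#'
#' A `magnitude_volume` is a real, non-negative 3D array (the modulus image
#' `|x(r)|` that drives the whole simulation pipeline) together with its
#' voxel spacing in mm and free-form provenance tags.
#'
#' @param data non-negative finite 3D numeric array, slice axis last.
#' @param spacing numeric length-3, mm per axis.
#' @param meta named list of provenance tags.
#' @return object of class `magnitude_volume` with fields `data`, `spacing`,
#'   `meta`.
#' @export
magnitude_volume <- function(data, spacing = c(1, 1, 1), meta = list()) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "data must be a 3D array", "tofrecon_dim_error")
  assert_that(all(is.finite(data)), "data must be finite")
  assert_that(all(data >= 0), "magnitude data must be non-negative")
  assert_that(length(spacing) == 3L && all(spacing > 0),
              "spacing must be 3 positive numbers")
  d <- dim(data)
  assert_that(d[1] >= d[3] && d[2] >= d[3],
              "slice axis (last) must be the shortest: nx, ny >= nz")
  structure(list(data = data, spacing = as.numeric(spacing), meta = meta),
            class = "magnitude_volume")
}

#' @export
print.magnitude_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<magnitude_volume %d x %d x %d, spacing %s mm, max %.4g>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              max(x$data)))
  invisible(x)
}

#' Configuration for the synthetic TOF-MRA phantom
#'
#' The phantom emulates the appearance of a time-of-flight angiography
#' magnitude volume: an ellipsoidal "head" of moderate-intensity tissue with
#' smooth low-frequency texture, containing a handful of bright, thin,
#' connected tubular vessels, and exact zeros outside the head. Defaults give
#' a 64 x 64 x 24 thin-slab volume in which bright (vessel) voxels occupy a
#' few percent of the volume, matching the sparsity of real TOF angiograms.
#'
#' @param shape integer length-3, volume dimensions (slice axis last).
#' @param n_vessels number of tubular vessels.
#' @param vessel_radius_range voxels, min/max Gaussian cross-section radius.
#' @param vessel_intensity peak vessel intensity (a.u.).
#' @param tissue_intensity background tissue intensity (a.u.); must be less
#'   than `vessel_intensity`.
#' @param head_axes ellipsoid semi-axes in voxels (default 0.42 * shape).
#' @param texture_scale amplitude of the smooth tissue texture, relative to
#'   `tissue_intensity`.
#' @param seed integer; the phantom is a pure function of the full config
#'   including this seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64, 24),
                           n_vessels = 8,
                           vessel_radius_range = c(1.0, 2.5),
                           vessel_intensity = 1.0,
                           tissue_intensity = 0.3,
                           head_axes = NULL,
                           texture_scale = 0.15,
                           seed = 1L) {
  if (is.null(head_axes)) head_axes <- 0.42 * shape
  assert_that(length(shape) == 3L && all(shape >= 16),
              "each phantom axis must be >= 16", "tofrecon_invalid_config")
  assert_that(vessel_intensity > tissue_intensity && tissue_intensity > 0,
              "need vessel_intensity > tissue_intensity > 0",
              "tofrecon_invalid_config")
  assert_that(all(vessel_radius_range >= 1),
              "vessel radii must be >= 1 voxel", "tofrecon_invalid_config")
  assert_that(max(vessel_radius_range) * 6 < min(shape),
              "shape too small for requested vessel radius",
              "tofrecon_invalid_config")
  structure(list(shape = as.integer(shape), n_vessels = as.integer(n_vessels),
                 vessel_radius_range = vessel_radius_range,
                 vessel_intensity = vessel_intensity,
                 tissue_intensity = tissue_intensity,
                 head_axes = head_axes, texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# normalized coordinate grids in [-1, 1] per axis, as three 3D arrays
coord_grids <- function(shape) {
  gx <- if (shape[1] > 1) seq(-1, 1, length.out = shape[1]) else 0
  gy <- if (shape[2] > 1) seq(-1, 1, length.out = shape[2]) else 0
  gz <- if (shape[3] > 1) seq(-1, 1, length.out = shape[3]) else 0
  list(x = array(rep(gx, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(gy, each = shape[1]), times = shape[3]), shape),
       z = array(rep(gz, each = shape[1] * shape[2]), shape))
}

# smooth positive texture field: k-space Gaussian-weighted white noise
smooth_texture <- function(shape, corr_frac = 0.15) {
  n <- prod(shape)
  noise <- array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
                 shape)
  w <- gaussian_kweight(shape, corr_frac)
  tex <- Re(ifft3c(fft3c(noise) * w))
  tex / max(abs(tex), 1e-12)
}

# zero-centred Gaussian weight in k-space (DC at array centre);
# sigma_frac is the SD as a fraction of each axis length
gaussian_kweight <- function(shape, sigma_frac) {
  g <- coord_grids(shape) # [-1, 1]; sigma in the same units is 2*sigma_frac
  s <- 2 * sigma_frac
  exp(-(g$x^2 + g$y^2 + g$z^2) / (2 * s^2))
}

#' Generate a synthetic TOF-like angiography phantom
#'
#' Deterministic given the config (including its seed): an ellipsoidal head
#' of textured tissue containing `n_vessels` smooth tubes (cubic-spline
#' centerlines through random control points inside the head, Gaussian
#' cross-sections of per-vessel radius) rendered at `vessel_intensity`.
#' Voxels outside the head ellipsoid are exactly zero.
#'
#' @param config a [phantom_config()].
#' @return a [magnitude_volume()]; `meta$centerlines` holds the voxel
#'   coordinates of each rendered centerline (used by vessel-mask tests).
#' @export
generate_tof_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "phantom"))

  g <- coord_grids(shape)
  ax <- config$head_axes / (shape / 2) # semi-axes in normalized units
  head <- (g$x / ax[1])^2 + (g$y / ax[2])^2 + (g$z / ax[3])^2 <= 1

  tex <- smooth_texture(shape)
  tissue <- config$tissue_intensity *
    pmax(1 + config$texture_scale * tex, 0.2)

  vess <- array(0, shape)
  centerlines <- vector("list", config$n_vessels)
  ctr <- shape / 2
  semi <- config$head_axes * 0.85
  for (v in seq_len(config$n_vessels)) {
    radius <- stats::runif(1, config$vessel_radius_range[1],
                           config$vessel_radius_range[2])
    n_ctrl <- sample(4:6, 1)
    # control points uniform inside the shrunken head ellipsoid
    pts <- matrix(0, n_ctrl, 3)
    for (j in seq_len(n_ctrl)) {
      repeat {
        p <- stats::runif(3, -1, 1)
        if (sum(p^2) <= 1) break
      }
      pts[j, ] <- ctr + p * semi
    }
    tt <- seq_len(n_ctrl)
    ts <- seq(1, n_ctrl, by = 0.02)
    cl <- cbind(stats::spline(tt, pts[, 1], xout = ts)$y,
                stats::spline(tt, pts[, 2], xout = ts)$y,
                stats::spline(tt, pts[, 3], xout = ts)$y)
    centerlines[[v]] <- cl
    vess <- render_tube(vess, cl, radius)
  }

  vol <- pmax(tissue, config$vessel_intensity * vess)
  vol[!head] <- 0
  magnitude_volume(vol, spacing = c(0.8, 0.8, 0.8),
                   meta = list(kind = "synthetic_tof_phantom",
                               config = config, centerlines = centerlines))
}

# accumulate max of Gaussian cross-section profiles along a centerline
render_tube <- function(vol, cl, radius) {
  shape <- dim(vol)
  r_ext <- ceiling(2.5 * radius)
  for (i in seq_len(nrow(cl))) {
    p <- cl[i, ]
    lo <- pmax(floor(p - r_ext), 1)
    hi <- pmin(ceiling(p + r_ext), shape)
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx2 <- (xs - p[1])^2; dy2 <- (ys - p[2])^2; dz2 <- (zs - p[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    prof <- exp(-d2 / (2 * (radius / 1.5)^2))
    cur <- vol[xs, ys, zs]
    vol[xs, ys, zs] <- pmax(cur, prof)
  }
  vol
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Split a volume into uniform overlapping slabs along the slice axis
#'
#' Multi-slab TOF acquisitions cover the head with thin overlapping slabs.
#' Given a requested slab count and approximate overlap fraction, the slab
#' length `L` and integer overlap `o = round(overlap_fraction * L)` (half-up)
#' are found by exhaustive search so that
#' `n_slabs * L - (n_slabs - 1) * o == nz` exactly. A 100-slice volume with
#' `n_slabs = 5`, `overlap_fraction = 0.2` yields 24-slice slabs with a
#' 5-slice overlap.
#'
#' @param volume a [magnitude_volume()].
#' @param n_slabs integer >= 1.
#' @param overlap_fraction in `[0, 1)`, approximate fractional overlap.
#' @return object of class `slab_stack`: fields `slabs` (list of
#'   `magnitude_volume`, inferior to superior), `overlap_slices`,
#'   `slab_length`, `source_extent`.
#' @export
split_slabs <- function(volume, n_slabs, overlap_fraction = 0.2) {
  stopifnot(inherits(volume, "magnitude_volume"))
  assert_that(n_slabs >= 1, "n_slabs must be >= 1")
  assert_that(overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must be in [0, 1)")
  nz <- dim(volume$data)[3]
  sol <- slab_solution(nz, n_slabs, overlap_fraction)
  if (is.null(sol)) {
    feas <- feasible_slice_counts(nz, n_slabs, overlap_fraction)
    abort(sprintf(paste0("no integer slab split of %d slices into %d slabs ",
                         "at overlap %.2f; nearest feasible slice counts: %s"),
                  nz, n_slabs, overlap_fraction,
                  paste(feas, collapse = ", ")),
          "tofrecon_infeasible_split")
  }
  L <- sol$L
  ov <- if (n_slabs == 1) 0L else sol$ov # overlap is meaningless for 1 slab
  step <- L - ov
  slabs <- lapply(seq_len(n_slabs), function(i) {
    z0 <- (i - 1) * step + 1
    magnitude_volume(volume$data[, , z0:(z0 + L - 1), drop = FALSE],
                     spacing = volume$spacing,
                     meta = c(volume$meta, list(slab_index = i)))
  })
  structure(list(slabs = slabs, overlap_slices = ov, slab_length = L,
                 source_extent = nz),
            class = "slab_stack")
}

# search L in 1..nz for n*L - (n-1)*round_half_up(f*L) == nz; among exact
# solutions prefer the one whose realized overlap fraction is closest to f
slab_solution <- function(nz, n, f) {
  best <- NULL
  for (L in seq_len(nz)) {
    ov <- round_half_up(f * L)
    if (ov >= L && n > 1) next
    if (n * L - (n - 1) * ov == nz) {
      dev <- if (L > 0) abs(ov / L - f) else Inf
      if (is.null(best) || dev < best$dev) best <- list(L = L, ov = ov, dev = dev)
    }
  }
  best
}

feasible_slice_counts <- function(nz, n, f) {
  cand <- integer(0)
  for (L in seq_len(nz + n)) {
    ov <- round_half_up(f * L)
    if (ov >= L && n > 1) next
    cand <- c(cand, n * L - (n - 1) * ov)
  }
  cand <- sort(unique(cand))
  lower <- rev(cand[cand < nz]); upper <- cand[cand > nz]
  c(utils::head(lower, 1), utils::head(upper, 1))
}

#' Recombine a slab stack by overlap-trimmed concatenation
#'
#' The first slab is kept whole; every subsequent slab contributes its slices
#' beyond the overlap region, so `combine_slabs(split_slabs(v, ...))`
#' reproduces `v` exactly.
#'
#' @param stack a `slab_stack` from [split_slabs()].
#' @return a [magnitude_volume()].
#' @export
combine_slabs <- function(stack) {
  stopifnot(inherits(stack, "slab_stack"))
  ov <- stack$overlap_slices
  pieces <- lapply(seq_along(stack$slabs), function(i) {
    d <- stack$slabs[[i]]$data
    if (i == 1) d else d[, , (ov + 1):dim(d)[3], drop = FALSE]
  })
  first <- stack$slabs[[1]]
  dd <- dim(first$data)
  total <- sum(vapply(pieces, function(p) dim(p)[3], 0L))
  out <- array(0, c(dd[1], dd[2], total))
  z <- 1L
  for (p in pieces) {
    nzp <- dim(p)[3]
    out[, , z:(z + nzp - 1)] <- p
    z <- z + nzp
  }
  magnitude_volume(out, spacing = first$spacing, meta = first$meta)
}
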