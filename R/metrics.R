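# Evaluation metrics: PSNR, 3D SSIM, NMSE, axial MIP, vessel-mask
# derivation (multiscale Hessian vesselness on the reference MIP), and
# vessel-masked SSIM.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` computed over the entire 3D volume, with
#' `peak = max(reference)` (the peak convention is the reference maximum,
#' pinned here and in the tests). Identical volumes give `Inf`.
#'
#' @param recon,reference same-shaped non-negative arrays.
#' @return scalar dB value (`Inf` when `recon == reference`).
#' @export
psnr <- function(recon, reference) {
  check_pair(recon, reference)
  mse <- mean((recon - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(reference)^2 / mse)
}

#' Normalised mean square error
#'
#' `||recon - reference||^2 / ||reference||^2`.
#'
#' @inheritParams psnr
#' @return scalar >= 0.
#' @export
nmse <- function(recon, reference) {
  check_pair(recon, reference)
  sum((recon - reference)^2) / sum(reference^2)
}

check_pair <- function(recon, reference) {
  assert_that(identical(dim(recon), dim(reference)),
              "volumes have different shapes", "tofrecon_shape_error")
  assert_that(any(reference != 0), "all-zero reference: metric undefined",
              "tofrecon_undefined_metric")
  invisible(TRUE)
}

# ---- uniform box filtering with symmetric boundaries -------------------------

# dense per-axis filter matrix: length-n signal -> length-n local means over a
# centred window of width w with symmetric (edge-mirrored) padding
box_matrix <- function(n, w = 7L) {
  p <- w %/% 2
  assert_that(w <= n, "window larger than volume axis", "tofrecon_window")
  idx <- c(rev(seq_len(p)), seq_len(n), n + 1 - seq_len(p))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- idx[i:(i + w - 1)]
    for (s in src) B[i, s] <- B[i, s] + 1 / w
  }
  B
}

# separable box mean over all axes of a 2D or 3D array
box_mean <- function(x, w = 7L, adjoint = FALSE) {
  d <- dim(x)
  for (a in seq_along(d)) {
    B <- box_matrix(d[a], w)
    if (adjoint) B <- t(B)
    x <- apply_axis_mat_nd(x, a, B)
  }
  x
}

apply_axis_mat_nd <- function(x, axis, M) {
  d <- dim(x)
  if (length(d) == 2) {
    return(if (axis == 1) M %*% x else x %*% t(M))
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- M %*% matrix(xp, nrow = d[axis])
  aperm(array(m, d[perm]), order(perm))
}

# SSIM ingredients shared by the metric, the map, and the loss gradient
ssim_parts <- function(x, y, w, K1, K2, L) {
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mx <- box_mean(x, w); my <- box_mean(y, w)
  sxx <- box_mean(x * x, w) - mx^2
  syy <- box_mean(y * y, w) - my^2
  sxy <- box_mean(x * y, w) - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * sxy + C2
  B1 <- mx^2 + my^2 + C1; B2 <- sxx + syy + C2
  list(S = (A1 * A2) / (B1 * B2), mx = mx, my = my, sxx = sxx, syy = syy,
       sxy = sxy, A1 = A1, A2 = A2, B1 = B1, B2 = B2, C1 = C1, C2 = C2)
}

#' Structural similarity index for 3D volumes
#'
#' Mean local SSIM with a uniform 7x7x7 window, constants `K1 = 0.01`,
#' `K2 = 0.03`, dynamic range `max(reference)`, and symmetric boundary
#' handling. Symmetric in its arguments up to the dynamic-range convention;
#' identical volumes give exactly 1.
#'
#' @inheritParams psnr
#' @param window odd window width (applied along every axis).
#' @param K1,K2 stability constants.
#' @param dynamic_range luminance range `L`; default `max(reference)`.
#' @return scalar in `[-1, 1]`.
#' @export
ssim3d <- function(recon, reference, window = 7L, K1 = 0.01, K2 = 0.03,
                   dynamic_range = NULL) {
  check_pair(recon, reference)
  if (is.null(dynamic_range)) dynamic_range <- max(reference)
  parts <- ssim_parts(recon, reference, window, K1, K2, dynamic_range)
  mean(parts$S)
}

# local SSIM map between two 2D images (used by VM-SSIM)
ssim_map_2d <- function(a, b, window = 7L, K1 = 0.01, K2 = 0.03,
                        dynamic_range = max(b)) {
  ssim_parts(a, b, window, K1, K2, dynamic_range)$S
}

#' Axial maximum intensity projection
#'
#' Per-pixel maximum along the slice (last) axis — the standard angiographic
#' display for TOF-MRA.
#'
#' @param volume 3D array or [magnitude_volume()].
#' @return 2D matrix `(nx, ny)`.
#' @export
mip_axial <- function(volume) {
  x <- if (inherits(volume, "magnitude_volume")) volume$data else volume
  assert_that(length(dim(x)) == 3L, "MIP needs a 3D volume",
              "tofrecon_dim_error")
  apply(x, c(1, 2), max)
}

# ---- vessel mask -----------------------------------------------------------

# dense Gaussian smoothing matrix (symmetric boundaries)
gauss_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- idx[i:(i + 2 * r)]
    for (j in seq_along(src)) G[i, src[j]] <- G[i, src[j]] + k[j]
  }
  G
}

gauss_smooth_2d <- function(img, sigma) {
  img <- gauss_matrix(nrow(img), sigma) %*% img
  img %*% t(gauss_matrix(ncol(img), sigma))
}

# central-difference Hessian of a 2D image (replicated edges)
hessian_2d <- function(img) {
  sx <- function(m, d) { # shift rows by d with edge replication
    n <- nrow(m); i <- pmin(pmax(seq_len(n) + d, 1), n); m[i, , drop = FALSE]
  }
  sy <- function(m, d) {
    n <- ncol(m); i <- pmin(pmax(seq_len(n) + d, 1), n); m[, i, drop = FALSE]
  }
  list(xx = sx(img, 1) - 2 * img + sx(img, -1),
       yy = sy(img, 1) - 2 * img + sy(img, -1),
       xy = (sy(sx(img, 1), 1) - sy(sx(img, 1), -1) -
               sy(sx(img, -1), 1) + sy(sx(img, -1), -1)) / 4)
}

# multiscale Frangi-type vesselness for bright 2D tubular structures
vesselness_2d <- function(img, scales = c(1, 2, 3), beta = 0.5, c_str = 0.2) {
  img <- img / max(img)
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- gauss_smooth_2d(img, s)
    H <- hessian_2d(sm)
    # scale-normalised Hessian
    hxx <- s^2 * H$xx; hyy <- s^2 * H$yy; hxy <- s^2 * H$xy
    tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    h <- (hxx + hyy) / 2
    mu1 <- h + tmp; mu2 <- h - tmp # mu1 >= mu2
    # order by modulus: lam2 = larger |.|
    swap <- abs(mu1) > abs(mu2)
    lam1 <- ifelse(swap, mu2, mu1)
    lam2 <- ifelse(swap, mu1, mu2)
    Rb2 <- (lam1 / pmin(lam2, -1e-12))^2
    S2 <- lam1^2 + lam2^2
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c_str^2)))
    v[lam2 >= 0] <- 0 # bright vessels: strongest curvature negative
    best <- pmax(best, v)
  }
  best
}

# 4-connected component labelling (iterative flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    seed <- todo[1]
    frontier <- seed
    lab[seed] <- cur
    nr <- nrow(mask)
    while (length(frontier)) {
      nb <- c(frontier - 1L, frontier + 1L, frontier - nr, frontier + nr)
      # block row wrap-around
      up_bad <- (frontier - 1L)[(frontier - 1L) %% nr == 0L]
      dn_bad <- (frontier + 1L)[frontier %% nr == 0L]
      nb <- setdiff(nb, c(up_bad, dn_bad))
      nb <- nb[nb >= 1L & nb <= length(mask)]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- unique(nb)
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Derive a vessel mask from a reference MIP
#'
#' Multiscale Hessian vesselness (scales 1-3 px, bright tubular structures)
#' is computed on the reference MIP and thresholded within the head region
#' (pixels above 10% of the MIP maximum). The default threshold is Otsu's
#' threshold of the vesselness values inside the head — adaptive to vessel
#' density, which varies widely between thin-slab projections — intersected
#' with an absolute vesselness floor; a fixed `percentile` can be supplied
#' instead. Components smaller than `min_size` pixels are removed. Derived
#' ONLY from the reference — never from a reconstruction.
#'
#' @param reference_mip 2D non-constant reference MIP.
#' @param percentile optional vesselness percentile within the head region;
#'   `NULL` (default) uses Otsu's threshold of the in-head vesselness.
#' @param min_size minimal connected-component size (pixels).
#' @param floor absolute vesselness floor (normalised image units).
#' @return object of class `vessel_mask`: `mask` (logical matrix) plus the
#'   derivation parameters.
#' @export
vessel_mask <- function(reference_mip, percentile = NULL, min_size = 10,
                        floor = 0.05) {
  assert_that(is.matrix(reference_mip), "reference MIP must be 2D")
  if (max(reference_mip) == min(reference_mip))
    abort("constant MIP: no vessel mask derivable", "tofrecon_empty_mask")
  head_reg <- reference_mip > 0.1 * max(reference_mip)
  # TOF vessels are hyperintense in the MIP: the Otsu bright class inside the
  # head must form a genuine high-contrast class, otherwise the MIP contains
  # no vessels (an all-tissue projection fails this gate). Pure ridge filters
  # alone cannot make this call: normalised texture ridges score high on
  # vesselness too.
  bright_thr <- otsu_threshold(reference_mip[head_reg])
  bright <- reference_mip >= bright_thr & head_reg
  if (!any(bright) || !any(head_reg & !bright) ||
        mean(reference_mip[bright]) /
          mean(reference_mip[head_reg & !bright]) < 1.5)
    abort("no hyperintense vessel class in the reference MIP",
          "tofrecon_empty_mask")
  v <- vesselness_2d(reference_mip)
  thr <- if (is.null(percentile)) {
    otsu_threshold(v[head_reg])
  } else {
    stats::quantile(v[head_reg], percentile / 100, names = FALSE)
  }
  # union: ridge response catches thin faint vessels, the bright class
  # catches crossings and thick-vessel plateaus that ridge filters miss
  m <- (v >= max(thr, floor) & head_reg) | bright
  if (any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_size)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (!any(m))
    abort("no vessel-like structures found in the reference MIP",
          "tofrecon_empty_mask")
  structure(list(mask = m, percentile = percentile, min_size = min_size,
                 floor = floor),
            class = "vessel_mask")
}

#' Vessel-masked SSIM
#'
#' Computes the axial MIPs of both volumes, the local 2D SSIM map between
#' them (uniform 7x7 window, same constants as [ssim3d()], dynamic range from
#' the reference MIP), and averages the map over the vessel-mask pixels only,
#' emphasising vascular fidelity.
#'
#' @inheritParams psnr
#' @param mask optional precomputed [vessel_mask()]; derived from the
#'   reference MIP when NULL.
#' @return scalar (at most 1).
#' @export
vm_ssim <- function(recon, reference, mask = NULL) {
  check_pair(recon, reference)
  mip_r <- mip_axial(recon)
  mip_ref <- mip_axial(reference)
  if (is.null(mask)) mask <- vessel_mask(mip_ref)
  if (!any(mask$mask))
    abort("empty vessel mask: VM-SSIM undefined", "tofrecon_undefined_metric")
  smap <- ssim_map_2d(mip_r, mip_ref)
  mean(smap[mask$mask])
}

#' Compute the full metrics record for a reconstruction
#'
#' @inheritParams psnr
#' @param mask optional [vessel_mask()] reused across methods (derived from
#'   the reference when NULL).
#' @return object of class `metrics_record` with fields `psnr`, `ssim`,
#'   `nmse`, `vm_ssim`.
#' @export
metrics_record <- function(recon, reference, mask = NULL) {
  structure(list(psnr = psnr(recon, reference),
                 ssim = ssim3d(recon, reference),
                 nmse = nmse(recon, reference),
                 vm_ssim = vm_ssim(recon, reference, mask)),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB | SSIM %.4f | NMSE %.5f | VM-SSIM %.4f\n",
              x$psnr, x$ssim, x$nmse, x$vm_ssim))
  invisible(x)
}
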