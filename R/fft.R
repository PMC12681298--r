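# Centered, unitary Fourier transforms.
#
# Convention used everywhere in the package: the image-domain array has its
# origin at the array centre (voxel floor(n/2)+1 per axis, 1-based) and the
# k-space array has DC at the same centre position. Forward and inverse are
# both scaled by 1/sqrt(N) so that Parseval's identity holds exactly:
# ||fft3c(x)|| == ||x||.

circshift <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    return(x[((seq_len(n) - 1 - shift) %% n) + 1])
  }
  idx <- lapply(seq_along(d), function(a) {
    n <- d[a]
    ((seq_len(n) - 1 - shift[a]) %% n) + 1
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Centered FFT shifts
#'
#' `fftshift()` moves the DC sample from the first array position to the
#' array centre; `ifftshift()` is its exact inverse (they differ for odd
#' lengths).
#'
#' @param x numeric or complex array.
#' @return array of the same shape.
#' @export
fftshift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  circshift(x, floor(d / 2))
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  circshift(x, -floor(d / 2))
}

#' Centered unitary 3D Fourier transform
#'
#' Maps a (complex) image volume to k-space with DC at the array centre,
#' scaled so the transform is unitary (`ifft3c(fft3c(x)) == x` and
#' `||fft3c(x)|| == ||x||`). Also accepts 1D/2D arrays (the same centred
#' unitary convention along every axis present).
#'
#' @param x complex (or numeric) array.
#' @return complex array of the same shape.
#' @export
fft3c <- function(x) {
  n <- length(x)
  fftshift(stats::fft(ifftshift(x))) / sqrt(n)
}

#' @rdname fft3c
#' @export
ifft3c <- function(x) {
  n <- length(x)
  fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / sqrt(n)
}

# apply fft3c / ifft3c per coil on a (ncoil, nx, ny, nz) array
fftc_coils <- function(k, inverse = FALSE) {
  d <- dim(k)
  out <- array(complex(real = 0), d)
  f <- if (inverse) ifft3c else fft3c
  for (i in seq_len(d[1])) {
    out[i, , , ] <- f(array(k[i, , , ], d[-1]))
  }
  out
}
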