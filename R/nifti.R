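# Minimal single-file NIfTI-1 (.nii / .nii.gz) I/O.
#
# Only what the pipeline needs: 3D single-channel volumes, float32 on disk
# (write), common numeric datatypes + scl_slope/scl_inter on read, voxel
# spacing from pixdim. Both endiannesses are handled on read (detected from
# sizeof_hdr); files are written little-endian.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE),
                 `512` = list(what = "integer", size = 2, signed = FALSE))

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a magnitude volume as NIfTI-1
#'
#' Data are stored as float32; voxel spacing goes to `pixdim[2:4]`.
#' `.nii.gz` paths are gzip-compressed. Volume invariants (finite,
#' non-negative) are asserted before writing.
#'
#' @param volume a [magnitude_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "magnitude_volume"))
  assert_that(all(is.finite(volume$data)) && all(volume$data >= 0),
              "volume violates magnitude invariants")
  d <- dim(volume$data)
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                    # sizeof_hdr
  w_raw(36)                     # data_type, db_name, extents, session_error,
                                # regular, dim_info
  w_i16(c(3, d, 1, 1, 1, 1))    # dim[8]
  w_f32(c(0, 0, 0))             # intent_p1..p3
  w_i16(0)                      # intent_code
  w_i16(16)                     # datatype = float32
  w_i16(32)                     # bitpix
  w_i16(0)                      # slice_start
  w_f32(c(1, volume$spacing, 1, 1, 1, 1)) # pixdim[8] (qfac = 1)
  w_f32(352)                    # vox_offset
  w_f32(1); w_f32(0)            # scl_slope, scl_inter
  w_i16(0); w_raw(2)            # slice_end, slice_code, xyzt_units
  w_f32(c(max(volume$data), 0)) # cal_max, cal_min
  w_f32(c(0, 0))                # slice_duration, toffset
  w_i32(c(0, 0))                # glmax, glmin
  w_raw(80 + 24)                # descrip, aux_file
  w_i16(c(0, 0))                # qform_code, sform_code
  w_f32(rep(0, 18))             # quaternions, qoffsets, srow
  w_raw(16)                     # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1) # magic
  w_raw(4)                      # extension flag
  w_f32(volume$data)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports 3D single-channel `.nii`/`.nii.gz` files with common numeric
#' datatypes; applies `scl_slope`/`scl_inter` when set. 2D or 4D files raise
#' a dimensionality error.
#'
#' @param path file path.
#' @return a [magnitude_volume()] (data coerced to non-negative is NOT done:
#'   negative voxels raise an error since magnitude input is expected).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path),
                                "tofrecon_io_error")
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr_sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (hdr_sz != 348) {
    endian <- "big"
    if (.swap_i32(hdr_sz) != 348) abort("not a NIfTI-1 file",
                                        "tofrecon_io_error")
  }
  readBin(con, "raw", 36)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dims[1]
  if (ndim != 3 && !(ndim == 4 && dims[5] <= 1))
    abort(sprintf("expected a 3D volume, got %dD", ndim),
          "tofrecon_dim_error")
  d <- dims[2:4]
  readBin(con, "double", 3, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 2, size = 2, endian = endian)
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) abort(sprintf("unsupported NIfTI datatype %d", datatype),
                         "tofrecon_io_error")
  readBin(con, "raw", vox_offset - 120) # rest of header + extensions
  n <- prod(d)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) abort("truncated NIfTI data", "tofrecon_io_error")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0)
    vals <- vals * scl_slope + scl_inter
  magnitude_volume(array(vals, d), spacing = pixdim[2:4],
                   meta = list(source = path))
}

.swap_i32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, size = 4, endian = "little")
}
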