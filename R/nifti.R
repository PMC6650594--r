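# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package ships with the supported toolchain, so the single-file
# NIfTI-1 format is implemented directly: the fixed 348-byte header, a 4-byte
# extension flag, and the voxel data at vox_offset. Only the features this
# pipeline needs are supported: 3D/4D volumes, little/big endian input,
# uint8/int16/int32/uint16/float32/float64 storage, scl_slope/scl_inter
# rescaling, and gzip compression (by file extension). Output is always
# little-endian with an identity-direction sform built from the voxel size.

NIFTI_DT <- list(
  "2"   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  "4"   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  "8"   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  "16"  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  "64"  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  "512" = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 image
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_labels logical; return a [label_map()] (data coerced to integer)
#'   instead of an [image_volume()].
#' @return An `image_volume` (3D or 4D) or `label_map`.
#' @export
read_nifti <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop_mri("no such file: %s", path)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr0 <- readBin(con, "raw", 4L)
  endian <- if (readBin(hdr0, "integer", 1L, 4L, endian = "little") == 348L)
    "little"
  else if (readBin(hdr0, "integer", 1L, 4L, endian = "big") == 348L)
    "big"
  else
    stop_mri("not a NIfTI-1 file: %s", path)
  readBin(con, "raw", 36L)                                   # unused fields
  dim8 <- readBin(con, "integer", 8L, 2L, endian = endian)
  ndim <- dim8[1L]
  if (!(ndim %in% c(3L, 4L)))
    stop_mri("only 3D/4D NIfTI supported, got %dD: %s", ndim, path)
  readBin(con, "raw", 14L)                                   # intent fields
  datatype <- readBin(con, "integer", 1L, 2L, endian = endian)
  readBin(con, "integer", 1L, 2L, endian = endian)           # bitpix
  readBin(con, "raw", 2L)                                    # slice_start
  pixdim <- readBin(con, "double", 8L, 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, 4L, endian = endian)
  readBin(con, "raw", 224L)                                  # rest of header
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop_mri("unsupported NIfTI magic in %s (two-file .hdr/.img not handled)",
             path)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop_mri("unsupported NIfTI datatype code %d", datatype)
  dims <- dim8[seq(2L, 1L + ndim)]
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop_mri("truncated NIfTI data in %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(vals, dim = dims)
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  if (as_labels) {
    if (ndim != 3L) stop_mri("label maps must be 3D, got %dD: %s", ndim, path)
    label_map(arr, spacing)
  } else {
    image_volume(arr, spacing)
  }
}

#' Write a NIfTI-1 image
#'
#' Label maps are stored as int32, scalar volumes as float64, so a write/read
#' round trip preserves voxel values exactly. Spacing is stored in `pixdim`
#' and in a diagonal sform.
#'
#' @param vol an [image_volume()] or [label_map()].
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  is_lab <- inherits(vol, "label_map")
  dims <- dim(vol$data)
  ndim <- length(dims)
  dim8 <- integer(8L)
  dim8[1L] <- ndim
  dim8[seq(2L, 1L + ndim)] <- dims
  dim8[dim8 == 0L] <- 1L
  pixdim <- numeric(8L)
  pixdim[1L] <- 1                       # qfac
  pixdim[2:4] <- vol$voxel_size_mm
  if (ndim == 4L) pixdim[5L] <- 1
  datatype <- if (is_lab) 8L else 64L
  bitpix <- if (is_lab) 32L else 64L

  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, 4L, endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wi(dim8, 2L)                                   # dim
  writeBin(raw(12L), con); wi(0L, 2L)            # intent_p*, intent_code
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)   # datatype, bitpix, slice_start
  wf(pixdim)
  wf(352); wf(1); wf(0)                          # vox_offset, scl_slope/inter
  wi(0L, 2L); writeBin(raw(2L), con)             # slice_end, codes
  wf(c(0, 0, 0, 0))                              # cal_max..toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  descrip <- charToRaw("mrirepro")
  writeBin(c(descrip, raw(80L - length(descrip))), con)
  writeBin(raw(24L), con)                        # aux_file
  wi(c(0L, 1L), 2L)                              # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                        # quatern, qoffset
  wf(c(vol$voxel_size_mm[1L], 0, 0, 0))          # srow_x
  wf(c(0, vol$voxel_size_mm[2L], 0, 0))          # srow_y
  wf(c(0, 0, vol$voxel_size_mm[3L], 0))          # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)    # magic
  writeBin(raw(4L), con)                         # extension flag
  if (is_lab) wi(vol$data, 4L)
  else writeBin(as.double(vol$data), con, 8L, endian = "little")
  invisible(path)
}
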