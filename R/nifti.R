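# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Scope: little-endian NIfTI-1 with the datatypes this pipeline emits
# (uint8, int16, int32, float32, float64), no extensions, sform from a
# diagonal voxel-size affine. Registration/reorientation is out of scope:
# data are returned in native voxel order and the affine is carried through
# untouched.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array, 3D or 4D), `pixdim` (voxel size
#'   in mm, length 3) and `affine` (4x4 sform matrix).
#' @export
read_nifti <- function(path) {
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(sizeof_hdr, 348L)) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  }
  readBin(con, "raw", 35L)                                   # unused fields
  readBin(con, "raw", 1L)                                    # dim_info
  dim <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")  # intent_p1..3
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  readBin(con, "raw", 2L + 1L + 1L)                          # slice_end/code/units
  readBin(con, "numeric", 4L, size = 4L, endian = "little")  # cal/slice_dur/toffset
  readBin(con, "integer", 2L, size = 4L, endian = "little")  # glmax/glmin
  readBin(con, "raw", 80L + 24L)                             # descrip, aux_file
  readBin(con, "integer", 2L, size = 2L, endian = "little")  # qform/sform codes
  readBin(con, "numeric", 6L, size = 4L, endian = "little")  # quatern/qoffset
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = "little"),
                 3L, 4L, byrow = TRUE)
  readBin(con, "raw", 16L)                                   # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!startsWith(magic, "n+1")) stop("unsupported NIfTI magic in ", path)

  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  ndim <- dim[1]
  shape <- dim[seq(2L, 1L + max(ndim, 1L))]
  n <- prod(shape)
  skip <- max(vox_offset, 352) - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- rbind(srow, c(0, 0, 0, 1))
  list(data = array(vals, dim = shape),
       pixdim = pixdim[2:4],
       affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric or integer array, 3D or 4D.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixdim voxel size in mm (length 3).
#' @param datatype one of `"float64"`, `"float32"`, `"int32"`, `"int16"`,
#'   `"uint8"`. Integer types require integral data.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(3, 3, 3),
                        datatype = c("float64", "float32", "int32", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  if (length(data) == 0L) stop("refusing to write an empty volume")
  shape <- dim(data)
  if (is.null(shape) || !(length(shape) %in% c(3L, 4L))) {
    stop("data must be a 3D or 4D array")
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
  bitpix <- switch(datatype, uint8 = 8L, int16 = 16L, int32 = 32L,
                   float32 = 32L, float64 = 64L)
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                      # sizeof_hdr
  w_raw(35L); w_raw(1L)            # unused + dim_info
  dim8 <- rep(1L, 8L)
  dim8[1] <- length(shape)
  dim8[seq_along(shape) + 1L] <- shape
  w_i16(dim8)
  w_f32(c(0, 0, 0)); w_i16(0L)     # intent
  w_i16(code); w_i16(bitpix); w_i16(0L)
  pd8 <- c(1, pixdim, rep(1, 4))
  w_f32(pd8)
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope / scl_inter
  w_i16(0L); w_raw(2L)             # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max/min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax/glmin
  w_raw(80L); w_raw(24L)           # descrip, aux_file
  w_i16(c(0L, 2L))                 # qform_code = 0, sform_code = 2
  w_f32(rep(0, 6))                 # quaternion + qoffset
  w_f32(c(pixdim[1], 0, 0, 0))     # srow_x
  w_f32(c(0, pixdim[2], 0, 0))     # srow_y
  w_f32(c(0, 0, pixdim[3], 0))     # srow_z
  w_raw(16L)                       # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)
  w_raw(4L)                        # extension flag: none

  vals <- as.vector(data)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(vals), con, size = bitpix %/% 8L, endian = "little")
  } else {
    if (max(abs(vals - round(vals))) > 0) {
      stop("integer datatype requested for non-integral data")
    }
    writeBin(as.integer(round(vals)), con, size = bitpix %/% 8L,
             endian = "little")
  }
  invisible(path)
}
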