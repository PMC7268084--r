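#' Minimal NIfTI-1 input/output
#'
#' The package reads and writes uncompressed single-file NIfTI-1 (`.nii`)
#' volumes: 3D scalar maps, 4D time series, and integer atlases. Data are
#' stored as float64 (or int32 for label volumes) so that round trips are
#' bit-exact; the affine is carried in the sform rows with `sform_code = 1`.
#' Only the subset of the format the pipeline needs is supported; reading
#' handles datatypes uint8/int16/int32/float32/float64 and both endiannesses.
#'
#' @param data numeric or integer array (3D or 4D).
#' @param path file path ending in `.nii`.
#' @param voxel_size numeric length-3, voxel edges in mm.
#' @param tr repetition time in seconds (written to `pixdim[5]` for 4D data).
#' @param datatype `"float64"` or `"int32"`.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   list with `data` (array), `voxel_size`, `tr`, and `affine` (4x4 matrix).
#' @examples
#' f <- tempfile(fileext = ".nii")
#' vol <- array(rnorm(27), c(3, 3, 3))
#' write_nifti(vol, f, voxel_size = c(2, 2, 2))
#' identical(read_nifti(f)$data, vol)
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1), tr = 0,
                        datatype = c("float64", "int32")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    stop("write_nifti: data must be a 3D or 4D array")
  ndim <- length(dims)
  dim8 <- c(ndim, dims, rep(1L, 7L - ndim))
  dtcode <- if (datatype == "float64") 64L else 8L
  bitpix <- if (datatype == "float64") 64L else 32L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused + dim_info
  wi(dim8, 2)                                   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..p3, intent_code
  wi(c(dtcode, bitpix, 0L), 2)                  # datatype, bitpix, slice_start
  wf(c(1, voxel_size, tr, 0, 0, 0))             # pixdim[0..7] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con)              # slice_end, slice_code
  writeBin(as.raw(if (ndim == 4L) 0x0aL else 0x02L), con) # xyzt_units mm(+s)
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_dur, toff
  wi(c(0L, 0L), 4)                              # glmax, glmin (unused)
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b,c,d + offsets
  wf(c(voxel_size[1], 0, 0, 0))                 # srow_x
  wf(c(0, voxel_size[2], 0, 0))                 # srow_y
  wf(c(0, 0, voxel_size[3], 0))                 # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  if (datatype == "float64")
    writeBin(as.double(data), con, size = 8, endian = "little")
  else
    writeBin(as.integer(data), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  endian <- "little"
  geti <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  getf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  if (geti(0, 4) != 348L) {
    endian <- "big"
    if (geti(0, 4) != 348L) stop("read_nifti: not a NIfTI-1 file: ", path)
  }
  dim8 <- geti(40, 2, 8)
  ndim <- dim8[1]
  dims <- dim8[2:(1 + ndim)]
  dtcode <- geti(70, 2)
  pixdim <- getf(76, 8)
  vox_offset <- getf(108)
  scl_slope <- getf(112)
  scl_inter <- getf(116)
  affine <- rbind(matrix(getf(280, 12), nrow = 3, byrow = TRUE),
                  c(0, 0, 0, 1))
  n <- prod(dims)
  seek(con, vox_offset)
  data <- switch(as.character(dtcode),
    "2"  = as.double(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"  = as.double(readBin(con, "integer", n, size = 2, endian = endian)),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "double", n, size = 4, endian = endian),
    "64" = readBin(con, "double", n, size = 8, endian = endian),
    stop("read_nifti: unsupported datatype code ", dtcode))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0) && dtcode != 8L)
    data <- data * scl_slope + scl_inter
  dim(data) <- dims
  list(data = data, voxel_size = pixdim[2:4],
       tr = if (ndim == 4L) pixdim[5] else 0, affine = affine)
}
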