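# Minimal NIfTI-1 single-file (.nii, uncompressed) reader/writer.
# Covers exactly what this package emits: 3D/4D volumes in float32, int32 or
# uint8, little-endian, isotropic in-plane spacing carried in pixdim, identity
# orientation (sform diagonal). No NIfTI R package is available offline, so
# this small codec is bundled rather than hand-waved.

NIFTI_DTYPES <- list(uint8 = list(code = 2L, size = 1L),
                     int32 = list(code = 8L, size = 4L),
                     float32 = list(code = 16L, size = 4L))

#' Write a volume as NIfTI-1
#'
#' @param vol 3D (or 4D) numeric/integer/logical array with `voxel_size_mm`
#'   metadata (see [as_volume()]); for 4D arrays the first three axes are
#'   spatial.
#' @param path output path, conventionally ending in `.nii`.
#' @param datatype one of `"float32"`, `"int32"`, `"uint8"`; defaults to
#'   `uint8` for logical input, `int32` for integer, else `float32`.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  nd <- length(dim(vol))
  if (!(nd %in% c(3L, 4L))) tc_stop("tc_bad_geometry", "write_volume expects a 3D or 4D array")
  vs <- voxel_size(vol)
  if (is.null(datatype))
    datatype <- if (is.logical(vol)) "uint8" else if (is.integer(vol)) "int32" else "float32"
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) tc_stop("tc_bad_format", "unsupported datatype '%s'", datatype)

  dm <- dim(vol)
  dim8 <- c(nd, dm, rep(1L, 7L - length(dm)))
  pixdim8 <- c(1, rep(vs, 3), rep(1, 4))
  if (nd == 4L) pixdim8[5] <- 1

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                          # sizeof_hdr
  writeBin(raw(36), con)               # data_type, db_name, extents, session_error, regular, dim_info
  wi(dim8, 2)                          # dim[8]
  wf(rep(0, 3))                        # intent_p1..p3
  wi(0L, 2)                            # intent_code
  wi(dt$code, 2)                       # datatype
  wi(8L * dt$size, 2)                  # bitpix
  wi(0L, 2)                            # slice_start
  wf(pixdim8)                          # pixdim[8]
  wf(352)                              # vox_offset
  wf(1); wf(0)                         # scl_slope, scl_inter
  wi(0L, 2)                            # slice_end
  writeBin(as.raw(c(0L, 2L)), con)     # slice_code, xyzt_units (2 = mm)
  wf(0); wf(0)                         # cal_max, cal_min
  wf(0); wf(0)                         # slice_duration, toffset
  wi(0L, 4); wi(0L, 4)                 # glmax, glmin
  writeBin(raw(80), con)               # descrip
  writeBin(raw(24), con)               # aux_file
  wi(0L, 2); wi(1L, 2)                 # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                        # quatern b,c,d + qoffset x,y,z
  wf(c(vs, 0, 0, 0))                   # srow_x
  wf(c(0, vs, 0, 0))                   # srow_y
  wf(c(0, 0, vs, 0))                   # srow_z
  writeBin(raw(16), con)               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                # extension flag
  if (datatype == "float32") {
    writeBin(as.numeric(vol), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(vol), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset written by [write_volume()] (plus big-endian detection),
#' returning an array with `voxel_size_mm` metadata. Anisotropic spatial
#' spacing raises a format error naming the field.
#'
#' @param path path to an uncompressed `.nii` file.
#' @param allow_anisotropic keep the three spacings as an attribute instead of
#'   erroring (downstream ops that require isotropy still guard themselves).
#' @return array with attributes `voxel_size_mm` (and `pixdim` when anisotropic).
#' @export
read_volume <- function(path, allow_anisotropic = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdr_size != 348L) {
    seek(con, 0)
    endian <- "big"
    hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (hdr_size != 348L) tc_stop("tc_bad_format", "not a NIfTI-1 file: sizeof_hdr != 348")
  }
  seek(con, 40)
  dm <- readBin(con, "integer", 8, size = 2, endian = endian)
  nd <- dm[1]
  if (nd < 3 || nd > 4) tc_stop("tc_bad_format", "unsupported dim[0] = %d", nd)
  dims <- dm[2:(1 + nd)]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  sp <- signif(pixdim[2:4], 7)  # undo float32 representation noise
  if (max(sp) - min(sp) > 1e-5 * max(sp)) {
    if (!allow_anisotropic)
      tc_stop("tc_bad_geometry", "anisotropic pixdim (%g, %g, %g) unsupported here",
              sp[1], sp[2], sp[3])
  }
  n <- prod(dims)
  seek(con, vox_offset)
  data <- switch(as.character(datatype),
    "2" = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian)),
    "4" = readBin(con, "integer", n, size = 2, endian = endian),
    "8" = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    tc_stop("tc_bad_format", "unsupported NIfTI datatype code %d", datatype))
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(data, dim = dims)
  attr(arr, "voxel_size_mm") <- sp[1]
  if (max(sp) - min(sp) > 1e-5 * max(sp)) attr(arr, "pixdim") <- sp
  arr
}
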