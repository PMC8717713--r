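# Minimal NIfTI-1 single-file (.nii) reader/writer.
#
# No NIfTI package is available in the supported dependency set, so the
# subset of the format the package needs is handled directly: uncompressed
# single-file images, magic "n+1", datatypes uint8/int16/int32/float32/
# float64, scl_slope/scl_inter honoured on read.  Files are written in the
# native byte order; reads detect and reject foreign byte order explicitly.

NIFTI_HDR_SIZE <- 348L
NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE))

#' Read a NIfTI-1 image
#'
#' @param path path to an uncompressed single-file `.nii` image.
#' @return a list with `data` (numeric array, up to 4-D) and `spacing`
#'   (pixdim for the spatial axes, mm).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L)
  if (!identical(sizeof_hdr, NIFTI_HDR_SIZE))
    stop("not a native-endian NIfTI-1 file (sizeof_hdr != 348)")
  readBin(con, "raw", 36L)                       # unused header fields
  dim <- readBin(con, "integer", 8L, size = 2L)  # dim[0..7]
  ndim <- dim[1]
  if (ndim < 1L || ndim > 4L) stop("only 1-4 dimensional images supported")
  readBin(con, "raw", 14L)                       # intent params etc.
  datatype <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "integer", 1L, size = 2L)         # bitpix
  readBin(con, "integer", 1L, size = 2L)         # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L)
  vox_offset <- readBin(con, "double", 1L, size = 4L)
  scl_slope <- readBin(con, "double", 1L, size = 4L)
  scl_inter <- readBin(con, "double", 1L, size = 4L)
  type <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(type)) stop("unsupported NIfTI datatype: ", datatype)
  dims <- pmax(dim[2:(ndim + 1L)], 1L)
  n <- prod(dims)
  seek(con, where = vox_offset, origin = "start")
  vals <- readBin(con, type$what, n, size = type$size, signed = type$signed)
  if (length(vals) != n) stop("truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims),
       spacing = pixdim[2:4])
}

#' Write a NIfTI-1 image
#'
#' @param data numeric array (up to 4-D).
#' @param path output `.nii` path.
#' @param spacing spatial voxel spacing in mm (length up to 3).
#' @return `path`, invisibly. Data are stored as float64.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1)) {
  d <- dim(data) %||% length(data)
  ndim <- length(d)
  if (ndim > 4L) stop("at most 4-D images supported")
  dim8 <- as.integer(c(ndim, d, rep(1L, 7L - ndim)))
  spacing <- rep_len(as.numeric(spacing), 3L)
  pixdim <- c(1, spacing, 1, 0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(NIFTI_HDR_SIZE, con, size = 4L)              # sizeof_hdr
  writeBin(raw(36L), con)                               # unused
  writeBin(dim8, con, size = 2L)                        # dim[0..7]
  writeBin(raw(14L), con)                               # intent etc.
  writeBin(64L, con, size = 2L)                         # datatype float64
  writeBin(64L, con, size = 2L)                         # bitpix
  writeBin(0L, con, size = 2L)                          # slice_start
  writeBin(pixdim, con, size = 4L)                      # pixdim[0..7]
  writeBin(352, con, size = 4L)                         # vox_offset
  writeBin(1, con, size = 4L)                           # scl_slope
  writeBin(0, con, size = 4L)                           # scl_inter
  # fill bytes 120..343, then magic at 344 and the 4-byte extension flag
  writeBin(raw(224L), con)
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                # extension flag
  writeBin(as.numeric(data), con, size = 8L)
  invisible(path)
}
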