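# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what phase sequences need: the 348-byte header, little-endian,
# datatypes uint8/int16/int32/float32/float64, no extensions, vox_offset 352.
# Integer-valued data are stored as int16 so intensities round-trip
# bit-exactly; anything else goes out as float64.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

nifti_write <- function(arr, path) {
  nd <- length(dim(arr))
  if (nd > 7L) stop("NIfTI supports at most 7 axes", call. = FALSE)
  vals <- as.vector(arr)
  integral <- all(is.finite(vals)) && all(vals == round(vals)) &&
    all(vals >= -32768 & vals <= 32767)
  datatype <- if (integral) 4L else 64L
  bitpix <- if (integral) 16L else 64L
  dim16 <- integer(8L); dim16[1L] <- nd; dim16[1L + seq_len(nd)] <- dim(arr)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi32(348L)                       # sizeof_hdr
  wraw(36L)                        # data_type..dim_info (unused)
  wi16(dim16)                      # dim[8]
  wf32(c(0, 0, 0)); wi16(0L)       # intent_p*, intent_code
  wi16(datatype); wi16(bitpix); wi16(0L)
  wf32(c(1, rep(1, 7)))            # pixdim[8] (unit voxels)
  wf32(352)                        # vox_offset
  wf32(1); wf32(0)                 # scl_slope, scl_inter
  wi16(0L); wraw(2L)               # slice_end, slice_code, xyzt_units
  wf32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  wi32(c(0L, 0L))                  # glmax, glmin
  desc <- charToRaw("recyclect phase sequence")
  writeBin(c(desc, raw(80L - length(desc))), con)
  wraw(24L)                        # aux_file
  wi16(c(0L, 0L))                  # qform_code, sform_code
  wf32(rep(0, 6))                  # quatern/qoffset
  wf32(c(1, 0, 0, 0)); wf32(c(0, 1, 0, 0)); wf32(c(0, 0, 1, 0))  # srow
  wraw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wraw(4L)                         # extension flag: none
  if (integral) wi16(vals) else writeBin(vals, con, size = 8L, endian = "little")
  invisible(path)
}

nifti_read <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header", call. = FALSE)
  ri32 <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "integer", n, size = 4L, endian = "little")
  ri16 <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 2L * n)], "integer", n, size = 2L, endian = "little")
  rf32 <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n, size = 4L, endian = "little")
  if (ri32(0L) != 348L)
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348)", call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("bad NIfTI magic '%s'", magic), call. = FALSE)
  dim16 <- ri16(40L, 8L)
  nd <- dim16[1L]
  if (nd < 1L || nd > 7L) stop("invalid NIfTI dim[0]", call. = FALSE)
  dims <- dim16[1L + seq_len(nd)]
  datatype <- ri16(70L)
  vox_offset <- rf32(108L)
  scl_slope <- rf32(112L); scl_inter <- rf32(116L)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- switch(as.character(datatype),
    "2"  = as.double(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.double(readBin(con, "integer", n, size = 2L, endian = "little")),
    "8"  = as.double(readBin(con, "integer", n, size = 4L, endian = "little")),
    "16" = readBin(con, "double", n, size = 4L, endian = "little"),
    "64" = readBin(con, "double", n, size = 8L, endian = "little"),
    stop(sprintf("unsupported NIfTI datatype code %d", datatype), call. = FALSE))
  if (length(vals) != n) stop("truncated NIfTI data section", call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  array(vals, dims)
}
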