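#' Write a volume as an uncompressed NIfTI-1 file
#'
#' Serializes a 3-D volume to a single-file NIfTI-1 (`.nii`) image with the
#' voxel size in `pixdim`, an sform affine equal to `diag(voxel_size)`, and
#' data stored as little-endian float64 so values round-trip exactly.
#'
#' @param vol a [volume()] or 3-D array.
#' @param path output file path.
#' @param datatype storage type, `"float64"` (default, lossless for doubles),
#'   `"float32"`, or `"int16"` (used for label volumes).
#' @return `path`, invisibly.
#' @seealso [read_nifti()]
#' @export
write_nifti <- function(vol, path, datatype = c("float64", "float32", "int16")) {
  datatype <- match.arg(datatype)
  data <- vol_data(vol)
  vox <- vol_voxel_size(vol)
  d <- dim(data)
  dt <- switch(datatype,
               float64 = list(code = 64L, bitpix = 64L, size = 8L, what = "double"),
               float32 = list(code = 16L, bitpix = 32L, size = 4L, what = "double"),
               int16   = list(code = 4L,  bitpix = 16L, size = 2L, what = "integer"))

  con <- file(path, "wb")
  on.exit(close(con))
  end <- "little"
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = end)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = end)
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }

  wi(348L, 4L)                       # sizeof_hdr
  wc("", 10L); wc("", 18L)           # data_type, db_name (unused)
  wi(0L, 4L); wi(0L, 2L)             # extents, session_error
  writeBin(charToRaw("r"), con)      # regular
  writeBin(as.raw(0L), con)          # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)   # dim[8]
  wf(c(0, 0, 0))                     # intent_p1..p3
  wi(0L, 2L)                         # intent_code
  wi(dt$code, 2L)                    # datatype
  wi(dt$bitpix, 2L)                  # bitpix
  wi(0L, 2L)                         # slice_start
  wf(c(1, vox, 1, 1, 1, 1))          # pixdim[8]; pixdim[0] = qfac
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0L, 2L)                         # slice_end
  writeBin(as.raw(c(0L, 2L)), con)   # slice_code, xyzt_units (2 = mm)
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  wc("t1gad", 80L)                   # descrip
  wc("", 24L)                        # aux_file
  wi(0L, 2L); wi(1L, 2L)             # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))            # quatern_b/c/d, qoffset_x/y/z
  wf(c(vox[1], 0, 0, 0))             # srow_x
  wf(c(0, vox[2], 0, 0))             # srow_y
  wf(c(0, 0, vox[3], 0))             # srow_z
  wc("", 16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)              # extension indicator

  if (dt$what == "integer") {
    writeBin(as.integer(round(as.vector(data))), con, size = dt$size, endian = end)
  } else {
    writeBin(as.numeric(as.vector(data)), con, size = dt$size, endian = end)
  }
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' Parses the 348-byte NIfTI-1 header (either endianness) and the image data
#' of a single-file `.nii` volume. Only 3-D volumes and the common scalar
#' datatypes (uint8, int16, int32, float32, float64, int8, uint16) are
#' supported; `scl_slope`/`scl_inter` scaling is applied when set.
#'
#' @param path path to a `.nii` file.
#' @return A [volume()] with the voxel size taken from `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  end <- "little"
  sz <- readBin(con, "integer", 1L, size = 4L, endian = end)
  if (sz != 348L) {
    end <- "big"
    seek(con, 0L)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = end)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  ri <- function(n, size) readBin(con, "integer", n, size = size, endian = end)
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = end)

  seek(con, 40L)
  dims <- ri(8L, 2L)
  ndim <- dims[1]
  if (ndim < 3L || any(dims[5:8] > 1L)) {
    stop("only 3-D NIfTI volumes are supported: ", path, call. = FALSE)
  }
  d <- dims[2:4]
  seek(con, 70L)
  datatype <- ri(1L, 2L)
  seek(con, 76L)
  pixdim <- rf(8L)
  vox_offset <- rf(1L)
  scl_slope <- rf(1L)
  scl_inter <- rf(1L)
  seek(con, 344L)
  magic <- rawToChar(readBin(con, "raw", 3L))
  if (!magic %in% c("n+1", "ni1")) {
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  }
  if (magic == "ni1") {
    stop("two-file NIfTI (.hdr/.img) is not supported: ", path, call. = FALSE)
  }

  spec <- switch(as.character(datatype),
                 "2"   = list(what = "integer", size = 1L, signed = FALSE),
                 "4"   = list(what = "integer", size = 2L, signed = TRUE),
                 "8"   = list(what = "integer", size = 4L, signed = TRUE),
                 "16"  = list(what = "numeric", size = 4L, signed = TRUE),
                 "64"  = list(what = "numeric", size = 8L, signed = TRUE),
                 "256" = list(what = "integer", size = 1L, signed = TRUE),
                 "512" = list(what = "integer", size = 2L, signed = FALSE),
                 stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE))

  n <- prod(d)
  seek(con, max(352L, as.integer(round(vox_offset))))
  raw_vals <- readBin(con, spec$what, n, size = spec$size,
                      signed = spec$signed, endian = end)
  if (length(raw_vals) != n) stop("truncated NIfTI data: ", path, call. = FALSE)
  vals <- as.numeric(raw_vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  vox <- pixdim[2:4]
  vox[!is.finite(vox) | vox <= 0] <- 1
  volume(array(vals, dim = d), voxel_size = vox)
}
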