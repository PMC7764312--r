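# Minimal NIfTI-1/2 reader and NIfTI-1 writer.
#
# No NIfTI codec is available in the supported dependency set, so the small
# subset of the format this package needs is implemented here directly:
# single-frame 3D scalar images, sform/qform affines, scl slope/intercept,
# both endiannesses, and gzip compression via R connections. DICOM and
# surface formats are out of scope.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

nifti_connection <- function(path, open) {
  # gzfile transparently reads plain files too
  if (open == "rb") gzfile(path, "rb") else {
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  }
}

quaternion_to_matrix <- function(b, c, d, qfac) {
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 > 0) sqrt(a2) else 0
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c + a * d), 2 * (b * d - a * c),
    2 * (b * c - a * d), a * a + c * c - b * b - d * d, 2 * (c * d + a * b),
    2 * (b * d + a * c), 2 * (c * d - a * b), a * a + d * d - c * c - b * b
  ), 3, 3)
  R[, 3] <- R[, 3] * qfac
  R
}

read_nifti_header <- function(con) {
  first <- readBin(con, "raw", n = 4)
  if (length(first) < 4) stop("not a NIfTI file (too short)")
  endian <- NA_character_
  for (e in c("little", "big")) {
    if (readBin(first, "integer", size = 4, endian = e) %in% c(348L, 540L)) {
      endian <- e
      break
    }
  }
  if (is.na(endian)) stop("not a NIfTI file (bad sizeof_hdr)")
  sizeof_hdr <- readBin(first, "integer", size = 4, endian = endian)

  hdr <- readBin(con, "raw", n = sizeof_hdr - 4L)
  if (length(hdr) < sizeof_hdr - 4L) stop("truncated NIfTI header")
  pos <- 0L # offset within hdr (i.e. file offset minus 4)
  take <- function(n) {
    out <- hdr[(pos + 1L):(pos + n)]
    pos <<- pos + as.integer(n)
    out
  }
  rint <- function(n, size, signed = TRUE)
    readBin(take(n * size), "integer", n = n, size = size, endian = endian,
            signed = signed)
  rdbl <- function(n, size)
    readBin(take(n * size), "numeric", n = n, size = size, endian = endian)
  skip <- function(n) pos <<- pos + as.integer(n)

  if (sizeof_hdr == 348L) {
    skip(36)                                     # data_type..dim_info
    dim <- rint(8, 2)
    rdbl(3, 4); rint(1, 2)                       # intent_p, intent_code
    datatype <- rint(1, 2)
    rint(2, 2)                                   # bitpix, slice_start
    pixdim <- rdbl(8, 4)
    vox_offset <- rdbl(1, 4)
    scl_slope <- rdbl(1, 4)
    scl_inter <- rdbl(1, 4)
    skip(4)                                      # slice_end/code, xyzt_units
    rdbl(4, 4)                                   # cal_max..toffset
    skip(8 + 104)                                # glmax/glmin, descrip, aux
    qform_code <- rint(1, 2)
    sform_code <- rint(1, 2)
    quat <- rdbl(6, 4)
    srow <- matrix(rdbl(12, 4), 3, 4, byrow = TRUE)
  } else {
    skip(8)                                      # magic
    datatype <- rint(1, 2)
    rint(1, 2)                                   # bitpix
    dim <- as.integer(rdbl(8, 8))                # int64, values are small
    rdbl(3, 8)                                   # intent_p
    pixdim <- rdbl(8, 8)
    # int64 vox_offset; offsets in practice fit in 32 bits, so read the
    # 8 bytes as two int32 words and keep the low one
    lo_hi <- readBin(take(8), "integer", n = 2, size = 4, endian = endian)
    vox_offset <- if (endian == "little") lo_hi[1] else lo_hi[2]
    scl_slope <- rdbl(1, 8)
    scl_inter <- rdbl(1, 8)
    rdbl(4, 8)                                   # cal_max..toffset
    skip(16 + 104)                               # slice_start/end, descrip, aux
    qform_code <- rint(1, 4)
    sform_code <- rint(1, 4)
    quat <- rdbl(6, 8)
    srow <- matrix(rdbl(12, 8), 3, 4, byrow = TRUE)
  }
  list(ndim = dim[1], shape = dim[2:8], pixdim = pixdim,
       datatype = datatype, vox_offset = vox_offset,
       scl_slope = scl_slope, scl_inter = scl_inter,
       qform_code = qform_code, sform_code = sform_code,
       quat = quat, srow = srow, endian = endian,
       sizeof_hdr = sizeof_hdr)
}

#' Read a 3D volume from a NIfTI-1/2 file
#'
#' Reads `.nii` or `.nii.gz`. Trailing singleton axes (e.g. a 4D file with
#' one frame) are squeezed; more than 3 non-singleton axes is an error.
#' Intensities are returned unmodified apart from the header's scl
#' slope/intercept scaling, and spacing/affine are taken from the header
#' (sform preferred, then qform, then pixdim).
#'
#' @param path Path to a NIfTI file.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  h <- read_nifti_header(con)

  shape <- h$shape[seq_len(h$ndim)]
  if (sum(shape > 1) > 3) stop("more than 3 non-singleton axes: not a 3D volume")
  if (h$ndim < 3) stop("fewer than 3 axes")
  dt <- NIFTI_DT[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", h$datatype)

  n <- prod(shape)
  # skip from end of parsed header to vox_offset
  skip <- h$vox_offset - ifelse(h$sizeof_hdr == 348L, 348L, 540L)
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = h$endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data section")
  vals <- as.double(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter

  data <- array(vals, shape[1:3])
  spacing <- h$pixdim[2:4]
  spacing[spacing <= 0 | !is.finite(spacing)] <- 1

  affine <- diag(c(spacing, 1))
  if (h$sform_code > 0) {
    affine <- rbind(h$srow, c(0, 0, 0, 1))
  } else if (h$qform_code > 0) {
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    R <- quaternion_to_matrix(h$quat[1], h$quat[2], h$quat[3], qfac)
    affine <- diag(4)
    affine[1:3, 1:3] <- R %*% diag(spacing)
    affine[1:3, 4] <- h$quat[4:6]
  }
  volume3d(data, spacing, affine)
}

write_nifti1 <- function(data, spacing, affine, path, datatype) {
  dt <- NIFTI_DT[[as.character(datatype)]]
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wdbl <- function(x, size) writeBin(as.double(x), con, size = size,
                                     endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  d <- dim(data)
  wint(348L, 4)                        # sizeof_hdr
  wraw(35)                             # data_type..regular
  wraw(1)                              # dim_info
  wint(c(3L, d, 1L, 1L, 1L, 1L), 2)    # dim[8]
  wdbl(c(0, 0, 0), 4); wint(0L, 2)     # intent
  wint(datatype, 2)
  wint(dt$size * 8L, 2)                # bitpix
  wint(0L, 2)                          # slice_start
  wdbl(c(1, spacing, 1, 1, 1, 1), 4)   # pixdim
  wdbl(352, 4)                         # vox_offset
  wdbl(1, 4); wdbl(0, 4)               # scl_slope, scl_inter
  wint(0L, 2); wraw(2)                 # slice_end, slice_code, xyzt_units
  wdbl(c(0, 0, 0, 0), 4)               # cal_max..toffset
  wint(c(0L, 0L), 4)                   # glmax, glmin
  wraw(104)                            # descrip, aux_file
  wint(0L, 2)                          # qform_code
  wint(1L, 2)                          # sform_code
  wdbl(c(0, 0, 0, 0, 0, 0), 4)         # quaternion + offsets
  wdbl(t(affine[1:3, ]), 4)            # srow_x/y/z (row-major)
  wraw(16)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  wraw(4)                              # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(data), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Write an intensity volume as NIfTI-1 (float32)
#'
#' @param v A [volume3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  write_nifti1(v$data, v$spacing, v$affine, path, 16L)
}

#' Write a label volume as integer NIfTI-1 plus a schema sidecar
#'
#' Labels are stored as int16 (int32 if any id exceeds the int16 range)
#' with the schema written alongside as `<path minus .nii[.gz]>.labels.tsv`.
#' Read-back equals the input exactly.
#'
#' @param lv A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  if (any(lv$data != round(lv$data))) stop("label data must be integers")
  dtype <- if (max(lv$data) > 32767L) 8L else 4L
  write_nifti1(lv$data, lv$spacing, lv$affine, path, dtype)
  write_schema(lv$schema, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path),
                                      ".labels.tsv")

#' Read a label volume written by [write_labels()]
#'
#' @param path Path to the NIfTI label file.
#' @param schema Optional [label_schema()]; when `NULL` the sidecar TSV is
#'   read.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, schema = NULL) {
  v <- read_volume(path)
  if (is.null(schema)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc)) stop("no schema given and no sidecar found: ", sc)
    schema <- read_schema(sc)
  }
  label_volume(v$data, schema, v$spacing, v$affine)
}
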