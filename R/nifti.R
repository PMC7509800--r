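# Minimal NIfTI-1 I/O. No NIfTI package is among the package's allowed
# dependencies, so the small subset of the format the pipeline needs is
# implemented directly: single-file little-endian .nii (optionally
# gzip-compressed .nii.gz), float32/float64/int16/uint8 data, affine stored
# in the srow fields (sform code 2). This is plumbing, not a general NIfTI
# implementation.

NIFTI_TYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE)     # float64
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D or 4D array as NIfTI-1
#'
#' @param data Numeric or logical array (3D or 4D). Logical arrays are
#'   written as uint8 masks, integer arrays as int32, doubles as float32
#'   (or float64 with `datatype = 64`).
#' @param path Output path; `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix (mm), stored as sform.
#' @param tr_s Repetition time stored in the 4th pixdim slot (default 0).
#' @param datatype Override the NIfTI datatype code (16 = float32,
#'   64 = float64, 8 = int32, 2 = uint8).
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, affine = diag(4), tr_s = 0,
                        datatype = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop_config("write_nifti expects a 3D or 4D array")
  if (is.null(datatype)) {
    datatype <- if (is.logical(data)) 2L else if (is.integer(data)) 8L else 16L
  }
  spec <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(spec)) stop_config("unsupported NIfTI datatype %s", datatype)

  d <- dim(data)
  dim_field <- c(nd, d, rep(1L, 7L - nd))
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, voxdim, tr_s, 0, 0, 0)

  # assemble the 348-byte header in a raw buffer, then write header + data
  header <- raw(348L)
  put <- function(header, offset, values, size, float = FALSE) {
    b <- if (float) {
      writeBin(as.double(values), raw(), size = size, endian = "little")
    } else {
      writeBin(as.integer(values), raw(), size = size, endian = "little")
    }
    header[(offset + 1L):(offset + length(b))] <- b
    header
  }
  header <- put(header, 0L, 348L, 4L)
  header <- put(header, 40L, dim_field, 2L)
  header <- put(header, 70L, datatype, 2L)
  header <- put(header, 72L, spec$size * 8L, 2L)              # bitpix
  header <- put(header, 76L, pixdim, 4L, float = TRUE)
  header <- put(header, 108L, 352, 4L, float = TRUE)          # vox_offset
  header <- put(header, 112L, 1, 4L, float = TRUE)            # scl_slope
  header <- put(header, 116L, 0, 4L, float = TRUE)            # scl_inter
  header <- put(header, 252L, 1L, 2L)                         # qform_code
  header <- put(header, 254L, 2L, 2L)                         # sform_code
  # qform: identity quaternion with the affine's translation
  header <- put(header, 256L, c(0, 0, 0), 4L, float = TRUE)   # quatern b,c,d
  header <- put(header, 268L, affine[1:3, 4], 4L, float = TRUE)
  header <- put(header, 280L, affine[1, ], 4L, float = TRUE)  # srow_x
  header <- put(header, 296L, affine[2, ], 4L, float = TRUE)  # srow_y
  header <- put(header, 312L, affine[3, ], 4L, float = TRUE)  # srow_z
  magic <- charToRaw("n+1")
  header[345:347] <- magic

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(raw(4L), con)  # extension flag
  if (spec$what == "double") {
    writeBin(as.double(as.vector(data)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.integer(as.vector(data)), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset written by [write_nifti()]: single-file little-endian
#' NIfTI-1, datatypes uint8/int16/int32/float32/float64, no extensions
#' beyond the standard 4-byte flag.
#'
#' @param path `.nii` or `.nii.gz` path.
#' @return List with `data` (array), `affine` (4x4, from sform when present,
#'   else pixdim scaling), `tr_s`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 348L)
  take <- function(offset, n, what, size, signed = TRUE) {
    readBin(header[(offset + 1L):(offset + n * size)], what, n = n,
            size = size, endian = "little", signed = signed)
  }
  sizeof_hdr <- take(0L, 1L, "integer", 4L)
  if (sizeof_hdr != 348L) stop_config("%s is not a little-endian NIfTI-1 file", path)
  dim_field <- take(40L, 8L, "integer", 2L)
  nd <- dim_field[1]
  d <- dim_field[2:(1 + nd)]
  datatype <- take(70L, 1L, "integer", 2L)
  spec <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(spec)) stop_config("unsupported NIfTI datatype %d in %s", datatype, path)
  pixdim <- take(76L, 8L, "double", 4L)
  vox_offset <- take(108L, 1L, "double", 4L)
  scl_slope <- take(112L, 1L, "double", 4L)
  scl_inter <- take(116L, 1L, "double", 4L)
  sform_code <- take(254L, 1L, "integer", 2L)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- take(280L, 4L, "double", 4L)
    affine[2, ] <- take(296L, 4L, "double", 4L)
    affine[3, ] <- take(312L, 4L, "double", 4L)
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }

  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(d)
  values <- readBin(con, spec$what, n = n_vox, size = spec$size,
                    endian = "little", signed = spec$signed)
  if (scl_slope != 0 && scl_slope != 1) {
    values <- values * scl_slope + scl_inter
  }
  list(data = array(values, dim = d), affine = affine, tr_s = pixdim[5])
}

#' Write a synthetic session to NIfTI
#'
#' @param session A `bold_session`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "bold_session"))
  write_nifti(session$data, path, affine = session$affine, tr_s = session$tr_s)
}

#' Read a session (4D BOLD + mask) from NIfTI
#'
#' @param bold_path 4D BOLD `.nii`/`.nii.gz`.
#' @param mask_path Optional 3D mask file; defaults to all voxels in-mask.
#' @param tr_s Repetition time override (else taken from the header).
#' @return A `bold_session`.
#' @export
read_session <- function(bold_path, mask_path = NULL, tr_s = NULL) {
  nii <- read_nifti(bold_path)
  if (length(dim(nii$data)) != 4L) stop_config("%s is not 4D", bold_path)
  mask <- if (is.null(mask_path)) {
    array(TRUE, dim(nii$data)[1:3])
  } else {
    m <- read_nifti(mask_path)
    if (!identical(dim(m$data), dim(nii$data)[1:3])) {
      stop_config("mask geometry does not match BOLD geometry")
    }
    m$data != 0
  }
  voxdim <- sqrt(colSums(nii$affine[1:3, 1:3]^2))
  structure(list(data = nii$data, tr_s = tr_s %||% nii$tr_s,
                 voxel_size_mm = voxdim[1], affine = nii$affine, mask = mask),
            class = "bold_session")
}
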