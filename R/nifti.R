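# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Hand-rolled because no NIfTI package is available in the target library;
# supports the subset of the format this pipeline touches: 3D/4D images,
# dtypes uint8/int16/int32/float32/float64, scl_slope/scl_inter, native or
# byte-swapped endianness.  Orientation metadata beyond pixdim is not
# interpreted: the pipeline's fixed RAS axis convention is a data contract.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 image
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3D or 4D numeric array), `voxel_size_mm`,
#'   `tr_s` (pixdim\[5\], NA when absent) and `dim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    # retry as big-endian
    close(con); on.exit()
    con <- open_maybe_gz(path, "rb"); on.exit(close(con))
    endian <- "big"
    sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stopf("not a NIfTI-1 file: %s", path)
  }
  readBin(con, "raw", 36L)                          # unused header fields
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                          # intent params etc.
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %d", datatype)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 3L))]
  shape[shape == 0L] <- 1L
  n <- prod(shape)
  # skip remainder of header + extension bytes up to vox_offset
  already <- 40L + 16L + 14L + 2L + 2L + 2L + 32L + 4L + 4L + 4L
  to_skip <- as.integer(round(vox_offset)) - already
  if (to_skip > 0L) readBin(con, "raw", to_skip)
  vals <- readBin(con, dt$what, n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n) stopf("truncated NIfTI data in %s", path)
  vals <- as.double(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)
  list(data = data,
       voxel_size_mm = abs(pixdim[2:4]),
       tr_s = if (ndim >= 4L) pixdim[5] else NA_real_,
       dim = shape)
}

#' Write a NIfTI-1 image
#'
#' @param data 3D or 4D numeric array.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param voxel_size_mm length-3 voxel size.
#' @param tr_s repetition time stored in pixdim\[5\] for 4D images.
#' @param datatype `"float32"`, `"float64"`, `"int16"` or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(2, 2, 2), tr_s = 0,
                        datatype = c("float32", "int32", "int16", "float64")) {
  datatype <- match.arg(datatype)
  code <- switch(datatype, float32 = 16L, float64 = 64L, int16 = 4L, int32 = 8L)
  size <- switch(datatype, float32 = 4L, float64 = 8L, int16 = 2L, int32 = 4L)
  d <- dim(data)
  if (is.null(d) || !length(d) %in% 3:4) stopf("data must be a 3D or 4D array")
  ndim <- length(d)
  dims <- integer(8); dims[1] <- ndim; dims[2:(1 + ndim)] <- d
  dims[dims == 0L] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1; pixdim[2:4] <- voxel_size_mm
  if (ndim == 4L) pixdim[5] <- tr_s
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L)                        # sizeof_hdr
  writeBin(raw(36L), con)                               # unused
  writeBin(as.integer(dims), con, size = 2L)            # dim[8]
  writeBin(raw(14L), con)                               # intent
  writeBin(code, con, size = 2L)                        # datatype
  writeBin(8L * size, con, size = 2L)                   # bitpix
  writeBin(0L, con, size = 2L)                          # slice_start
  writeBin(pixdim, con, size = 4L)                      # pixdim[8]
  writeBin(352, con, size = 4L)                         # vox_offset
  writeBin(1, con, size = 4L)                           # scl_slope
  writeBin(0, con, size = 4L)                           # scl_inter
  # slice_end..intent_name: 2+1+1+4+4+4+4+2+1+1 header tail is laid out as
  # raw padding; qform/sform codes left 0 (orientation by convention).
  writeBin(raw(224L), con)
  writeBin(c(charToRaw("n+1"), raw(1L)), con)           # magic, NUL-terminated
  writeBin(raw(4L), con)                                # extension flag
  vals <- as.vector(data)
  if (code %in% c(4L, 8L)) {
    writeBin(as.integer(round(vals)), con, size = size)
  } else {
    writeBin(as.double(vals), con, size = size)
  }
  invisible(path)
}

#' Load and validate a labeled segmentation volume from NIfTI
#'
#' @param path NIfTI file of integer labels.
#' @param label_map named integer vector (structure name to label value).
#' @param grid optional session [volume_grid()] to enforce.
#' @param require_all require the full set of [REQUIRED_LABELS].
#' @return a [labeled_volume()].
#' @export
load_labeled_volume <- function(path, label_map, grid = NULL, require_all = TRUE) {
  img <- read_nifti(path)
  arr <- img$data
  if (length(dim(arr)) == 4L) {
    if (dim(arr)[4] != 1L) stopf("label volume must be 3D")
    arr <- array(arr, dim(arr)[1:3])
  }
  if (any(arr != round(arr))) stopf("label volume has non-integer voxel values")
  g <- volume_grid(dim(arr), img$voxel_size_mm)
  if (!is.null(grid)) {
    assert_same_grid(grid, g, what = path)
    g <- grid
  }
  lv <- labeled_volume(g, arr, label_map, require_all = require_all)
  present <- unique(as.vector(lv$labels))
  absent <- names(lv$label_map)[!(lv$label_map %in% present) &
                                  names(lv$label_map) != "brain"]
  if (require_all && length(absent)) {
    stopf("missing required label(s): %s (present in map but empty in volume)",
          paste(absent, collapse = ", "))
  }
  lv
}

#' Write a BOLD series to NIfTI
#' @param bold a [bold_series()].
#' @param path output path.
#' @export
write_bold_nifti <- function(bold, path) {
  bold <- as_array_bold(bold)
  write_nifti(bold$data, path, voxel_size_mm = bold$grid$voxel_size_mm,
              tr_s = bold$tr_s, datatype = "float32")
}

#' Read a BOLD series from NIfTI
#' @inheritParams load_labeled_volume
#' @param tr_s repetition time override (else taken from the header).
#' @param kind,site,timestamps_s passed to [bold_series()].
#' @export
read_bold_nifti <- function(path, grid = NULL, tr_s = NULL,
                            kind = "rest-continuous", site = NULL,
                            timestamps_s = NULL) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 4L) stopf("BOLD file must be 4D: %s", path)
  g <- volume_grid(dim(img$data)[1:3], img$voxel_size_mm)
  if (!is.null(grid)) { assert_same_grid(grid, g, path); g <- grid }
  if (is.null(tr_s)) tr_s <- img$tr_s
  bold_series(g, img$data, tr_s = tr_s, timestamps_s = timestamps_s,
              kind = kind, site = site)
}
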