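# Minimal single-file NIfTI-1 (.nii, uncompressed) I/O in base R.
# Only axis-aligned geometry is supported: the sform is written as
# diag(spacing) with translation origin + 0.5*spacing so that the NIfTI
# index->world map (voxel centre at A %*% v + t) matches this package's
# voxel-centre convention. Spatial units are micrometres (xyzt_units = 3).

.nifti_dtypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

#' Read an uncompressed NIfTI-1 volume
#'
#' Supports datatypes uint8/int16/int32/float32/float64, native or
#' byte-swapped, with axis-aligned sform (or pixdim-only geometry). Off-axis
#' rotations are rejected; this package's warping contract only ever writes
#' axis-aligned volumes.
#'
#' @param path path to a `.nii` file.
#' @param regions optional `region_table`; when supplied the result is a
#'   `label_volume`, otherwise a `scalar_volume`.
#' @return a `scalar_volume` or `label_volume`.
#' @export
read_nifti <- function(path, regions = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- .Platform$endian
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- if (endian == "little") "big" else "little"
    seek(con, 0)
    sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, 2, endian = endian)
  if (dims[1] < 3L) stop("expected a 3D NIfTI volume")
  shape <- dims[2:4]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  row <- match(datatype, .nifti_dtypes$code)
  if (is.na(row)) stop("unsupported NIfTI datatype code ", datatype)
  seek(con, 76)
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  seek(con, 108)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  seek(con, 252)
  qform_code <- readBin(con, "integer", 1, 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, 2, endian = endian)
  seek(con, 280)
  srow <- matrix(readBin(con, "double", 12, 4, endian = endian), 3, 4,
                 byrow = TRUE)
  if (sform_code > 0L) {
    lin <- srow[, 1:3]
    if (max(abs(lin - diag(diag(lin)))) > 1e-4 * max(abs(lin)))
      stop("only axis-aligned NIfTI geometry is supported")
    spacing <- abs(diag(lin))
    origin <- srow[, 4] - 0.5 * spacing
  } else {
    spacing <- abs(pixdim[2:4])
    origin <- c(0, 0, 0)
  }
  spacing[spacing == 0] <- 1
  seek(con, round(vox_offset))
  n <- prod(shape)
  vals <- readBin(con, .nifti_dtypes$what[row], n, .nifti_dtypes$size[row],
                  signed = .nifti_dtypes$signed[row], endian = endian)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  g <- voxel_grid(shape, spacing, origin)
  if (is.null(regions)) {
    scalar_volume(array(vals, shape), g)
  } else {
    label_volume(array(as.integer(round(vals)), shape), g, regions)
  }
}

#' Write a volume as uncompressed NIfTI-1
#'
#' Scalar volumes are written as float32, label volumes as int32.
#'
#' @param vol a `scalar_volume` or `label_volume`.
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  is_labels <- inherits(vol, "label_volume")
  data <- if (is_labels) vol$labels else vol$values
  g <- vol$grid
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4)
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                         # sizeof_hdr
  wc(10 + 18); wi(0L, 4); wi(0L, 2)   # data_type, db_name, extents, session_error
  writeBin(charToRaw("r"), con); wc(1)  # regular, dim_info
  wi(c(3L, g$shape, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)           # intent_p1..p3, intent_code
  wi(if (is_labels) 8L else 16L, 2)   # datatype
  wi(32L, 2); wi(0L, 2)               # bitpix, slice_start
  wf(c(1, g$spacing, 1, 1, 1, 1))     # pixdim[8]
  wf(352); wf(1); wf(0)               # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc(1)                    # slice_end, slice_code
  writeBin(as.raw(3L), con)           # xyzt_units: micrometres
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4) # cal_max/min, slice_duration, toffset, glmax/glmin
  wc(80 + 24)                         # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))      # quaterns, qoffsets
  off <- g$origin + 0.5 * g$spacing
  wf(c(g$spacing[1], 0, 0, off[1]))   # srow_x
  wf(c(0, g$spacing[2], 0, off[2]))   # srow_y
  wf(c(0, 0, g$spacing[3], off[3]))   # srow_z
  wc(16)                              # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wc(4)                               # extension flag
  if (is_labels) wi(as.vector(data), 4) else wf(as.vector(data))
  invisible(path)
}
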