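# Minimal NIfTI-1 I/O.
#
# No NIfTI reader is available in the supported R stack, so the package
# carries its own single-file implementation of the NIfTI-1 format
# (348-byte header, single-file .nii / .nii.gz). It covers what the
# pipeline emits: 3D scalar maps, 3D integer label volumes and 4D BOLD
# runs, little-endian, datatypes uint8 / int16 / int32 / float32 /
# float64, with scl_slope/scl_inter honoured on read.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D/4D array as a NIfTI-1 file
#'
#' @param x numeric or integer array, 3 or 4 dimensional.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param tr_seconds repetition time stored in `pixdim[4]` for 4D data.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = 3, tr_seconds = 2,
                        datatype = "float32") {
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("only 3D or 4D arrays supported")
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  dims <- c(nd, dim(x), rep(1L, 7 - nd))
  pixdim <- c(1, rep(voxel_size_mm, 3),
              if (nd == 4L) tr_seconds else 1, 1, 1, 1)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                    # unused
  writeBin(as.integer(dims), con, size = 2, endian = "little")
  writeBin(raw(14), con)                                    # intent etc.
  writeBin(as.integer(c(dt, NIFTI_BITPIX[[as.character(dt)]], 0L)),
           con, size = 2, endian = "little")                # datatype, bitpix, slice_start
  writeBin(pixdim, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope, scl_inter
  writeBin(raw(4), con)                                     # slice_end, slice_code, xyzt_units
  writeBin(c(0, 0), con, size = 4, endian = "little")       # cal_max, cal_min
  writeBin(c(0, 0), con, size = 4, endian = "little")       # slice_duration, toffset
  writeBin(raw(8), con)                                     # glmax, glmin
  writeBin(raw(104), con)                                   # descrip(80) + aux_file(24)
  writeBin(raw(4), con)                                     # qform_code, sform_code
  writeBin(numeric(6), con, size = 4, endian = "little")    # quatern b/c/d, qoffset x/y/z
  writeBin(numeric(12), con, size = 4, endian = "little")   # srow_x/y/z
  writeBin(raw(16), con)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)             # magic
  writeBin(raw(4), con)                                     # extender
  vals <- as.vector(x)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(vals)), con,
             size = NIFTI_BITPIX[[as.character(dt)]] / 8L,
             endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = if (dt == 64L) 8 else 4,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any single-file
#' little/big-endian NIfTI-1 with a supported datatype)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array), `voxel_size_mm`, `tr_seconds`
#'   (NA for 3D), `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  dims <- readBin(hdr[41:56], "integer", size = 2, n = 8, endian = endian)
  nd <- dims[1]
  if (!nd %in% c(3L, 4L)) stop("only 3D/4D NIfTI supported, got dim ", nd)
  datatype <- readBin(hdr[71:72], "integer", size = 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "double", size = 4, n = 8, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", size = 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", size = 4, endian = endian)
  n <- prod(dims[2:(nd + 1)])
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    `2`  = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                   endian = endian),
    `4`  = readBin(con, "integer", n = n, size = 2, endian = endian),
    `8`  = readBin(con, "integer", n = n, size = 4, endian = endian),
    `16` = readBin(con, "double", n = n, size = 4, endian = endian),
    `64` = readBin(con, "double", n = n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  dim(data) <- dims[2:(nd + 1)]
  list(data = data,
       voxel_size_mm = pixdim[2],
       tr_seconds = if (nd == 4L) pixdim[5] else NA_real_,
       datatype = names(NIFTI_DT)[match(datatype, unlist(NIFTI_DT))])
}

#' Read / write `volume_map` and `bold_run` objects as NIfTI
#'
#' `write_volume()`/`read_volume()` round-trip a [volume_map()] (the mask
#' is stored as a companion file only when `mask_path` is given;
#' otherwise the reader is handed a mask or defaults to nonzero voxels).
#' `write_bold()`/`read_bold()` round-trip a [bold_run()] including its
#' repetition time.
#'
#' @param vol a `volume_map`.
#' @param path destination `.nii`/`.nii.gz`.
#' @param datatype storage type; label volumes should use `"int32"`.
#' @export
write_volume <- function(vol, path, datatype = "float64") {
  write_nifti(vol$values, path, voxel_size_mm = vol$voxel_size_mm,
              datatype = datatype)
}

#' @param mask optional logical array or `volume_map` supplying the mask.
#' @rdname write_volume
#' @export
read_volume <- function(path, mask = NULL) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3L) stop("expected a 3D volume in ", path)
  if (inherits(mask, "volume_map")) mask <- mask$mask
  if (is.null(mask)) mask <- array(TRUE, dim(nii$data))
  volume_map(nii$data, mask = mask, voxel_size_mm = nii$voxel_size_mm)
}

#' @param run a `bold_run`.
#' @rdname write_volume
#' @export
write_bold <- function(run, path, datatype = "float32") {
  write_nifti(run$values, path, tr_seconds = run$tr_seconds,
              datatype = datatype)
}

#' @rdname write_volume
#' @export
read_bold <- function(path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4L) stop("expected a 4D run in ", path)
  bold_run(nii$data, tr_seconds = nii$tr_seconds)
}

#' Read / write subject tables and generic TSV
#'
#' Subject tables carry one row per subject with columns `id`, `gender`
#' (`"male"`/`"female"`), `age` (years) and `education` (years).
#'
#' @param table data.frame.
#' @param path TSV destination.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
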