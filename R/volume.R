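#' Volume and time-series containers
#'
#' `volume_map()` wraps a 3D scalar grid together with a binary analysis
#' mask and an isotropic voxel size; it holds gray-matter-volume maps,
#' ReHo maps, t-maps and label volumes alike. `bold_run()` wraps a 4D
#' (x, y, z, t) BOLD array with its repetition time.
#'
#' @param values numeric 3D array (or integer array for label volumes).
#' @param mask logical/0-1 3D array of the same dimensions; defaults to
#'   all-TRUE.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length.
#' @return An object of class `volume_map` with elements `values`,
#'   `mask`, `voxel_size_mm`.
#' @examples
#' v <- volume_map(array(rnorm(27), c(3, 3, 3)))
#' @export
volume_map <- function(values, mask = NULL, voxel_size_mm = 3) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(values)))
    stop("mask and values dimensions differ")
  if (!any(mask)) stop("mask is empty")
  if (any(!is.finite(values[mask])))
    stop("non-finite values inside mask")
  stopifnot(voxel_size_mm > 0)
  structure(list(values = values, mask = mask,
                 voxel_size_mm = voxel_size_mm),
            class = "volume_map")
}

#' @param tr_seconds positive scalar repetition time in seconds.
#' @rdname volume_map
#' @export
bold_run <- function(values, tr_seconds = 2) {
  if (length(dim(values)) != 4L)
    stop("`values` must be a 4D array (x, y, z, t)")
  if (dim(values)[4] < 8L)
    stop("a BOLD run needs at least 8 time points")
  if (any(!is.finite(values))) stop("non-finite values in BOLD run")
  stopifnot(tr_seconds > 0)
  structure(list(values = values, tr_seconds = tr_seconds),
            class = "bold_run")
}

#' @export
print.volume_map <- function(x, ...) {
  cat("<volume_map> ", paste(dim(x$values), collapse = "x"),
      " grid, ", sum(x$mask), " voxels in mask, ",
      x$voxel_size_mm, " mm voxels\n", sep = "")
  invisible(x)
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$values)
  cat("<bold_run> ", paste(d[1:3], collapse = "x"), " grid, ",
      d[4], " volumes, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Fisher-z functional connectivity matrix container
#'
#' Symmetric R x R matrix of Fisher r-to-z transformed Pearson
#' correlations with a zero diagonal.
#'
#' @param z_values symmetric numeric matrix, zero diagonal.
#' @param region_labels character vector of length R.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix_obj <- function(z_values, region_labels = NULL) {
  stopifnot(is.matrix(z_values), nrow(z_values) == ncol(z_values))
  if (is.null(region_labels))
    region_labels <- paste0("R", seq_len(nrow(z_values)))
  if (length(region_labels) != nrow(z_values))
    stop("region_labels length must match matrix order")
  if (max(abs(z_values - t(z_values))) > 1e-10)
    stop("z matrix must be symmetric")
  if (any(diag(z_values) != 0)) stop("diagonal must be zero")
  off <- z_values[upper.tri(z_values)]
  if (any(!is.finite(off))) stop("non-finite off-diagonal z values")
  structure(list(z_values = z_values, region_labels = region_labels),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  r <- nrow(x$z_values)
  cat("<fc_matrix> ", r, " regions, ", r * (r - 1) / 2,
      " unique edges\n", sep = "")
  invisible(x)
}

#' Enumerate the unique edges of an R-region parcellation
#'
#' Edges are the unordered region pairs (i < j), listed in column-major
#' upper-triangle order. This ordering is shared by every edge-wise
#' vector in the package.
#'
#' @param n_regions integer >= 2.
#' @return data.frame with integer columns `i`, `j`, one row per edge.
#' @export
edge_index <- function(n_regions) {
  stopifnot(n_regions >= 2)
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

#' Extract the upper-triangle edge vector from an fc_matrix
#' @param fc an `fc_matrix`.
#' @return numeric vector of length R(R-1)/2 in `edge_index()` order.
#' @export
edge_vector <- function(fc) {
  fc$z_values[upper.tri(fc$z_values)]
}
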