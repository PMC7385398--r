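# Imaging features: preprocessed BOLD, regional homogeneity (Kendall's
# W over a voxel's 26-neighborhood), and Fisher-z functional
# connectivity over an atlas parcellation.

# Flatten a 4D run into a T x V matrix over in-mask voxels (column
# order = which(mask), i.e. column-major voxel order).
run_matrix <- function(run, mask) {
  d <- dim(run$values)
  flat <- matrix(run$values, nrow = prod(d[1:3]), ncol = d[4])
  t(flat[which(mask), , drop = FALSE])
}

matrix_to_run <- function(Y, mask, template_run) {
  d <- dim(template_run$values)
  flat <- matrix(0, prod(d[1:3]), d[4])
  flat[which(mask), ] <- t(Y)
  bold_run(array(flat, d), tr_seconds = template_run$tr_seconds)
}

#' Zero-phase band-pass filter of a BOLD run
#'
#' Frequency-domain rectangular masking: the discrete Fourier transform
#' of each voxel series is computed, bins whose frequency falls outside
#' `[low_hz, high_hz]` are zeroed (the DC bin always is, so the output
#' is mean-removed), and the series is inverse-transformed. This is the
#' ideal-filter variant used by the resting-state toolbox lineage.
#'
#' @param run a [bold_run()].
#' @param low_hz,high_hz band edges in Hz; `0 <= low < high <= Nyquist`
#'   where Nyquist is `1 / (2 * TR)`.
#' @param mask optional logical array restricting computation; voxels
#'   outside are zeroed.
#' @return A filtered `bold_run`.
#' @export
bandpass_filter <- function(run, low_hz = 0.01, high_hz = 0.08,
                            mask = NULL) {
  nyq <- 1 / (2 * run$tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz || high_hz > nyq + 1e-12)
    stop("band must satisfy 0 <= low < high <= Nyquist (",
         signif(nyq, 4), " Hz)")
  d <- dim(run$values)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  Y <- run_matrix(run, mask)
  Tn <- nrow(Y)
  f <- (seq_len(Tn) - 1) / (Tn * run$tr_seconds)
  f <- pmin(f, 1 / run$tr_seconds - f)       # two-sided spectrum
  keep <- f >= low_hz & f <= high_hz & f > 0
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Yf <- Re(stats::mvfft(F, inverse = TRUE)) / Tn
  matrix_to_run(Yf, mask, run)
}

#' Regress nuisance signals out of a BOLD run
#'
#' Ordinary least squares per voxel: an intercept is prepended to the
#' regressor matrix (drift, motion parameters, global/WM/CSF means) and
#' the residual series are returned. Residuals are exactly orthogonal
#' to every regressor column.
#'
#' @param run a [bold_run()].
#' @param regressors T x k numeric matrix, `T` = number of volumes.
#' @param mask optional logical array restricting computation.
#' @return A residual `bold_run`.
#' @export
regress_nuisance <- function(run, regressors, mask = NULL) {
  d <- dim(run$values)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != d[4])
    stop("regressor rows must equal the number of volumes")
  X <- cbind(1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("nuisance design is rank deficient")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  Y <- run_matrix(run, mask)
  res <- Y - X %*% qr.coef(qx, Y)
  matrix_to_run(res, mask, run)
}

neighborhood_offsets <- function(neighborhood) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  manh <- rowSums(abs(off))
  switch(as.character(neighborhood),
         `6`  = off[manh == 1, , drop = FALSE],
         `18` = off[manh <= 2, , drop = FALSE],
         `26` = off,
         stop("neighborhood must be one of 6, 18, 26"))
}

#' Regional homogeneity map (Kendall's coefficient of concordance)
#'
#' For every in-mask voxel, Kendall's W is computed between the voxel's
#' time series and those of its in-mask neighbors:
#' `W = 12 * sum_t (R_t - mean(R))^2 / (K^2 * (n^3 - n))`, where `K` is
#' 1 plus the number of available in-mask neighbors, `n` the number of
#' time points and `R_t` the rank sum across the `K` series at time
#' `t`. Ranks use average tie-breaking with no tie-correction term, as
#' in the original formulation. At mask edges `K` shrinks rather than
#' dropping the voxel, so the output has one value per mask voxel.
#' Voxels with no in-mask neighbor at all (`K = 1`) are undefined: they
#' are removed from the output mask and flagged in the `"undefined"`
#' attribute, with a warning.
#'
#' @param run a [bold_run()] (typically already filtered/regressed).
#' @param mask logical array or binary `volume_map`.
#' @param neighborhood 6, 18 or 26 (default 26).
#' @return A `volume_map` of W values in [0, 1].
#' @export
compute_reho <- function(run, mask, neighborhood = 26) {
  m <- if (inherits(mask, "volume_map")) mask$mask else mask
  d <- dim(run$values)
  stopifnot(identical(dim(m), d[1:3]))
  Tn <- d[4]
  if (Tn < 2) stop("need at least 2 time points")
  Y <- run_matrix(run, m)
  Rk <- matrixStats::colRanks(Y, ties.method = "average",
                              preserveShape = TRUE)
  V <- ncol(Y)
  coords <- which(m, arr.ind = TRUE)
  idxmap <- array(NA_integer_, d[1:3])
  idxmap[which(m)] <- seq_len(V)
  S <- Rk
  K <- rep(1L, V)
  offs <- neighborhood_offsets(neighborhood)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nc <- sweep(coords, 2, off, "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
      nc[, 2] >= 1 & nc[, 2] <= d[2] &
      nc[, 3] >= 1 & nc[, 3] <= d[3]
    nidx <- rep(NA_integer_, V)
    nidx[ok] <- idxmap[nc[ok, , drop = FALSE]]
    ok <- ok & !is.na(nidx)
    if (any(ok)) {
      S[, ok] <- S[, ok] + Rk[, nidx[ok], drop = FALSE]
      K[ok] <- K[ok] + 1L
    }
  }
  dev <- sweep(S, 2, colMeans(S))
  W <- 12 * colSums(dev^2) / (K^2 * (Tn^3 - Tn))
  vals <- array(0, d[1:3])
  vals[which(m)] <- W
  out_mask <- m
  flagged <- K == 1L
  if (any(flagged)) {
    warning(sum(flagged), " voxel(s) had no in-mask neighbor; ",
            "flagged as undefined and dropped from the output mask")
    undef <- which(m)[flagged]
    vals[undef] <- NA_real_
    out_mask[undef] <- FALSE
  }
  vsz <- if (inherits(mask, "volume_map")) mask$voxel_size_mm else 3
  out <- volume_map(vals, mask = out_mask, voxel_size_mm = vsz)
  attr(out, "undefined") <- if (any(flagged)) which(m)[flagged]
                            else integer(0)
  out
}

#' Standardize a ReHo map by its in-mask mean
#'
#' Divides every in-mask value by the mean over all mask voxels, so the
#' output map has in-mask mean exactly 1.
#'
#' @param map a `volume_map` with positive in-mask mean.
#' @return A standardized `volume_map`.
#' @export
standardize_reho <- function(map) {
  mu <- mean(map$values[map$mask])
  if (!is.finite(mu) || mu <= 0)
    stop("in-mask mean must be positive to standardize")
  vals <- map$values
  vals[map$mask] <- vals[map$mask] / mu
  volume_map(vals, mask = map$mask, voxel_size_mm = map$voxel_size_mm)
}

# 1D Gaussian convolution matrix (rows renormalize later via the mask).
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  x <- seq_len(n)
  M <- exp(-outer(x, x, "-")^2 / (2 * sigma_vox^2))
  M[abs(outer(x, x, "-")) > ceiling(4 * sigma_vox)] <- 0
  M
}

apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- M %*% matrix(a, nrow = da[1])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Gaussian smoothing of a volume with mask renormalization
#'
#' Smooths with an isotropic Gaussian of the given FWHM
#' (`sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis, in mm). Kernel
#' weight falling outside the mask is discarded and the remaining
#' weights rescaled, so constant in-mask maps are unchanged and no
#' signal bleeds in from outside the mask. `fwhm_mm = 0` is the
#' identity.
#'
#' @param map a `volume_map`.
#' @param fwhm_mm full width at half maximum in millimeters (>= 0).
#' @return A smoothed `volume_map`.
#' @export
smooth_volume <- function(map, fwhm_mm = 4) {
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  if (fwhm_mm == 0) return(map)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / map$voxel_size_mm
  d <- dim(map$values)
  Ms <- lapply(1:3, function(ax) gauss_conv_matrix(d[ax], sigma_vox))
  num <- map$values * map$mask
  den <- array(as.numeric(map$mask), d)
  for (ax in 1:3) {
    num <- apply_axis(num, Ms[[ax]], ax)
    den <- apply_axis(den, Ms[[ax]], ax)
  }
  vals <- array(0, d)
  vals[map$mask] <- num[map$mask] / den[map$mask]
  volume_map(vals, mask = map$mask, voxel_size_mm = map$voxel_size_mm)
}

#' Mean time series per atlas region
#'
#' Row `r` of the result is the unweighted mean of the series of all
#' in-mask voxels carrying atlas label `r`.
#'
#' @param run a [bold_run()].
#' @param atlas integer label `volume_map`.
#' @param gm_mask logical array or `volume_map` restricting voxels.
#' @return R x T numeric matrix with rownames `"R1"..`.
#' @export
region_timeseries <- function(run, atlas, gm_mask = NULL) {
  m <- if (is.null(gm_mask)) atlas$mask
       else if (inherits(gm_mask, "volume_map")) gm_mask$mask
       else gm_mask
  labs <- atlas$values[which(m)]
  if (!any(labs > 0)) stop("atlas has no labeled in-mask voxel")
  regions <- seq_len(max(labs))
  Y <- run_matrix(run, m)
  keep <- labs > 0
  Y <- Y[, keep, drop = FALSE]
  labs <- labs[keep]
  counts <- table(factor(labs, levels = regions))
  if (any(counts == 0)) {
    stop("region(s) with no in-mask voxel: ",
         paste(regions[counts == 0], collapse = ", "))
  }
  ts <- rowsum(t(Y), group = labs) / as.numeric(counts)
  rownames(ts) <- paste0("R", regions)
  ts
}

#' Fisher-z functional connectivity matrix from region time series
#'
#' Pearson correlation between every pair of region series, Fisher
#' r-to-z transformed (`z = atanh(r)`), with `r` clamped to
#' `+/-(1 - 1e-7)` so z stays finite. Diagonal is zero.
#'
#' @param region_ts R x T matrix from [region_timeseries()].
#' @return An `fc_matrix`.
#' @export
fc_matrix <- function(region_ts) {
  if (ncol(region_ts) < 3) stop("need at least 3 time points")
  v <- matrixStats::rowVars(region_ts)
  if (any(v <= 0)) stop("zero-variance region series: ",
                        paste(which(v <= 0), collapse = ", "))
  r <- stats::cor(t(region_ts))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  fc_matrix_obj(z, rownames(region_ts))
}
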