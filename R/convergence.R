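# Structural/functional convergence: voxel overlap between thresholded
# difference maps and spatial correlation of the unthresholded maps.

#' Overlap between two thresholded difference maps
#'
#' Quantifies the convergence of two modality difference maps (e.g.
#' gray-matter volume vs ReHo): the count of voxels significant in both
#' corrected maps, that count as a percentage of each map's significant
#' voxels, and the relaxed-threshold variants — trend voxels of one
#' modality (two-sided uncorrected p below the trend threshold) inside
#' the other modality's corrected mask. If a corrected mask is empty
#' its percentages are `NA` while counts are still returned.
#'
#' When t-maps are supplied, the report additionally breaks out how
#' many overlap voxels agree in sign (same direction of group
#' difference in both modalities).
#'
#' @param sigA,sigB binary `volume_map`s: corrected significance masks
#'   of modalities A and B.
#' @param trendA,trendB binary `volume_map`s: uncorrected trend masks;
#'   each must contain its modality's corrected mask.
#' @param tmapA,tmapB optional `tmap`s for the sign-agreement breakout.
#' @return list of class `overlap_report`.
#' @export
overlap_analysis <- function(sigA, sigB, trendA, trendB,
                             tmapA = NULL, tmapB = NULL) {
  ms <- list(sigA, sigB, trendA, trendB)
  d <- dim(sigA$values)
  for (m in ms)
    if (!identical(dim(m$values), d))
      stop("all maps must share one grid")
  a <- sigA$values > 0; b <- sigB$values > 0
  ta <- trendA$values > 0; tb <- trendB$values > 0
  if (any(a & !ta) || any(b & !tb))
    stop("corrected masks must be subsets of their trend masks")
  n_a <- sum(a); n_b <- sum(b)
  n_ab <- sum(a & b)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  n_tb_in_a <- sum(a & tb)       # B-trend voxels inside corrected A
  n_ta_in_b <- sum(b & ta)
  rep <- list(
    n_overlap_corrected = n_ab,
    pct_of_A = pct(n_ab, n_a),
    pct_of_B = pct(n_ab, n_b),
    n_trendB_in_sigA = n_tb_in_a,
    pct_trendB_in_sigA = pct(n_tb_in_a, n_a),
    n_trendA_in_sigB = n_ta_in_b,
    pct_trendA_in_sigB = pct(n_ta_in_b, n_b))
  if (!is.null(tmapA) && !is.null(tmapB)) {
    ov <- which(a & b)
    rep$n_overlap_same_sign <- sum(
      sign(tmapA$t_values$values[ov]) == sign(tmapB$t_values$values[ov]))
  }
  class(rep) <- "overlap_report"
  rep
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n",
      "  corrected overlap: ", x$n_overlap_corrected, " voxels (",
      signif(x$pct_of_A, 4), "% of A, ", signif(x$pct_of_B, 4),
      "% of B)\n",
      "  trend-B within sig-A: ", x$n_trendB_in_sigA, " (",
      signif(x$pct_trendB_in_sigA, 4), "%)\n",
      "  trend-A within sig-B: ", x$n_trendA_in_sigB, " (",
      signif(x$pct_trendA_in_sigB, 4), "%)\n", sep = "")
  invisible(x)
}

#' Spatial correlation of two unthresholded t-maps
#'
#' Pearson correlation across in-mask voxels of the raw t-values of two
#' difference maps.
#'
#' @param tmapA,tmapB `tmap`s (or `volume_map`s) on one grid.
#' @param mask optional logical array / `volume_map`; defaults to the
#'   first map's mask.
#' @return scalar correlation.
#' @export
spatial_correlation <- function(tmapA, tmapB, mask = NULL) {
  va <- if (inherits(tmapA, "tmap")) tmapA$t_values else tmapA
  vb <- if (inherits(tmapB, "tmap")) tmapB$t_values else tmapB
  if (!identical(dim(va$values), dim(vb$values)))
    stop("maps must share one grid")
  m <- if (is.null(mask)) va$mask
       else if (inherits(mask, "volume_map")) mask$mask else mask
  if (!any(m)) stop("mask is empty")
  x <- va$values[m]; y <- vb$values[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance inside the mask")
  stats::cor(x, y)
}
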