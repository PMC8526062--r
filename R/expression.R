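#' Z-score an expression map within the thalamus
#'
#' Normalizes voxel-wise expression values to mean 0 and unit sample SD
#' across the thalamic voxels the map is defined on.
#'
#' @param map A `voxel_stat_map` of raw expression values.
#' @return The map with z-scored values and provenance flag
#'   `normalized = TRUE`.
#' @export
normalize_expression_zscore <- function(map) {
  assert_that(length(map$values) >= 2,
              "invalid input: need at least 2 in-mask voxels")
  s <- stats::sd(map$values)
  assert_that(s > 0, "degenerate input: constant expression map")
  out <- map
  out$values <- (map$values - mean(map$values)) / s
  out$provenance$normalized <- TRUE
  out
}

#' Expression contrast between lesion sites
#'
#' Kolmogorov-Smirnov contrast of the normalized expression values sampled
#' at the voxels of two disjoint lesion sites, with the direction of the
#' mean difference.
#'
#' @param norm_map Normalized expression `voxel_stat_map`.
#' @param multi_site,single_site Disjoint, non-empty site masks.
#' @return As [site_contrast_voxelwise()].
#' @export
expression_site_contrast <- function(norm_map, multi_site, single_site) {
  site_contrast_voxelwise(norm_map, multi_site, single_site)
}

#' Matrix-minus-core expression difference map
#'
#' Voxel-wise difference of the normalized calbindin-like and
#' parvalbumin-like maps; positive values mark voxels with relatively higher
#' matrix-cell density.
#'
#' @param calb1_z,pvalb_z Normalized expression maps on one grid.
#' @return A `voxel_stat_map` of differences.
#' @export
core_matrix_difference_map <- function(calb1_z, pvalb_z) {
  assert_that(identical(calb1_z$grid_shape, pvalb_z$grid_shape) &&
                identical(calb1_z$coords, pvalb_z$coords),
              "geometry error: expression maps are not on a shared grid")
  assert_that(isTRUE(calb1_z$provenance$normalized) &&
                isTRUE(pvalb_z$provenance$normalized),
              "invalid input: maps must be normalized first")
  out <- calb1_z
  out$values <- calb1_z$values - pvalb_z$values
  out$statistic <- "matrix_core_difference"
  out$provenance <- list(normalized = TRUE)
  out
}

#' Dice overlap between a thresholded expression map and a lesion site
#'
#' Binarizes the expression map at `value > threshold_z` over the thalamic
#' voxels and computes the Dice coefficient with the site mask.
#'
#' @param norm_map Normalized expression `voxel_stat_map`.
#' @param site_mask Non-empty binary site mask on the map's grid.
#' @param threshold_z Binarization threshold (default 0, i.e. above-average
#'   expression).
#' @return Dice coefficient in \[0, 1\].
#' @export
expression_lesion_dice <- function(norm_map, site_mask, threshold_z = 0) {
  high <- norm_map$values > threshold_z
  assert_that(sum(high) > 0, "invalid input: thresholded expression map is empty")
  arr <- array(0L, dim = norm_map$grid_shape)
  arr[norm_map$coords[high, , drop = FALSE]] <- 1L
  dice(arr, site_mask)
}
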