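#' ROI-to-network partition
#'
#' @param membership Integer vector assigning each cortical ROI to a network
#'   (values in 1..n_networks), or a factor/character vector of labels.
#' @param networks Optional character vector of network names.
#' @return A `network_partition`: list with integer `membership`, `networks`,
#'   `n_networks`.
#' @export
network_partition <- function(membership, networks = NULL) {
  if (is.character(membership) || is.factor(membership)) {
    f <- factor(membership, levels = networks %||% unique(as.character(membership)))
    membership <- as.integer(f)
    networks <- levels(f)
  }
  membership <- as.integer(membership)
  assert_that(!anyNA(membership) && all(membership >= 1),
              "invalid input: every ROI must be assigned a network")
  nm <- max(membership)
  if (is.null(networks)) networks <- paste0("N", seq_len(nm))
  assert_that(length(networks) >= nm, "invalid input: network names too short")
  assert_that(nm >= 2, "invalid input: need at least 2 networks")
  structure(list(membership = membership, networks = networks[seq_len(nm)],
                 n_networks = nm),
            class = "network_partition")
}

# n_roi x n_network indicator matrix
partition_indicator <- function(partition, n_rois) {
  assert_that(length(partition$membership) == n_rois,
              "invalid input: partition does not cover all ROIs")
  M <- matrix(0, nrow = n_rois, ncol = partition$n_networks,
              dimnames = list(NULL, partition$networks))
  M[cbind(seq_len(n_rois), partition$membership)] <- 1
  M
}

#' Thalamocortical functional connectivity from region time series
#'
#' Entry (v, r) is the Pearson correlation of thalamic voxel v's time series
#' with cortical ROI r's time series. No voxel-to-voxel correlations exist in
#' the output by construction.
#'
#' @param thal_ts Voxel x time matrix.
#' @param roi_ts ROI x time matrix (same number of time points, >= 3).
#' @param subject_id Optional label.
#' @return Voxel x ROI correlation matrix with attribute `subject_id`.
#' @export
fc_from_timeseries <- function(thal_ts, roi_ts, subject_id = NULL) {
  assert_that(ncol(thal_ts) == ncol(roi_ts),
              "invalid input: time series must have equal length")
  assert_that(ncol(thal_ts) >= 3, "invalid input: need at least 3 time points")
  sd_t <- apply(thal_ts, 1, stats::sd)
  sd_r <- apply(roi_ts, 1, stats::sd)
  if (any(sd_t == 0)) {
    stopf("degenerate input: constant time series for thalamic voxel(s) %s",
          paste(which(sd_t == 0), collapse = ", "))
  }
  if (any(sd_r == 0)) {
    stopf("degenerate input: constant time series for ROI(s) %s",
          paste(which(sd_r == 0), collapse = ", "))
  }
  W <- stats::cor(t(thal_ts), t(roi_ts))
  attr(W, "subject_id") <- subject_id
  W
}

#' Density-threshold a connectivity matrix
#'
#' Negative weights are removed first (the participation coefficient is
#' defined for non-negative weights), then the top `floor(density * E)`
#' positive weights of the whole matrix are retained (E = total number of
#' entries) and all others set to zero. Ties at the cutoff are broken by
#' entry order, deterministically.
#'
#' @param matrix Voxel x ROI weight matrix.
#' @param density Fraction of entries to retain, in (0, 1].
#' @return Thresholded matrix (attributes preserved).
#' @export
threshold_by_density <- function(matrix, density) {
  assert_that(density > 0 && density <= 1,
              "invalid config: density must lie in (0, 1]")
  k <- floor(density * length(matrix))
  assert_that(k >= 1, "invalid config: density retains zero edges")
  pos <- which(matrix > 0)
  assert_that(length(pos) >= 1,
              "invalid config: no positive weights to retain at this density")
  keep <- pos[order(matrix[pos], decreasing = TRUE)][seq_len(min(k, length(pos)))]
  out <- matrix
  out[] <- 0
  out[keep] <- matrix[keep]
  out
}

# Core PC computation on a non-negative voxel x ROI matrix; returns values
# and the zero-strength flag vector.
pc_values <- function(matrix, partition) {
  assert_that(all(matrix >= 0),
              "invalid input: PC requires non-negative weights (threshold first)")
  M <- partition_indicator(partition, ncol(matrix))
  Ks <- matrix %*% M                       # K_is: voxel x network strengths
  Ki <- rowSums(Ks)                        # K_i: total strength
  pc <- numeric(nrow(matrix))
  ok <- Ki > 0
  pc[ok] <- 1 - rowSums((Ks[ok, , drop = FALSE] / Ki[ok])^2)
  list(values = pc, zero_strength = !ok)
}

#' Voxel-wise participation coefficient
#'
#' For voxel i with strength K_is to network s and total strength K_i, the
#' participation coefficient is `1 - sum_s (K_is / K_i)^2`: 0 when all weight
#' sits in one network, approaching `1 - 1/NM` when spread uniformly across
#' the NM networks. Voxels with zero total strength get PC = 0 and are
#' flagged.
#'
#' @param matrix Thresholded, non-negative voxel x ROI matrix.
#' @param partition A `network_partition` covering all ROIs.
#' @param coords Optional voxel coordinate matrix (n x 3) to return a
#'   [voxel_stat_map()]; otherwise a bare numeric vector is returned.
#' @param grid_shape,voxel_size_mm Grid geometry when `coords` is given.
#' @return Numeric PC vector (attribute `zero_strength`), or a
#'   `voxel_stat_map` when `coords` is supplied.
#' @export
participation_coefficient <- function(matrix, partition, coords = NULL,
                                      grid_shape = NULL, voxel_size_mm = 1) {
  res <- pc_values(matrix, partition)
  if (is.null(coords)) {
    out <- res$values
    attr(out, "zero_strength") <- res$zero_strength
    return(out)
  }
  voxel_stat_map(res$values, coords, grid_shape, voxel_size_mm,
                 statistic = "participation_coefficient",
                 flags = res$zero_strength)
}

#' Participation coefficient averaged across density thresholds
#'
#' Thresholds the matrix at each density, computes the voxel-wise PC, and
#' averages the per-density maps element-wise.
#'
#' @param matrix Raw voxel x ROI weight matrix (negatives discarded during
#'   thresholding).
#' @param partition A `network_partition`.
#' @param densities Density grid within (0, 1].
#' @inheritParams participation_coefficient
#' @return As [participation_coefficient()], averaged over densities.
#' @export
pc_across_densities <- function(matrix, partition,
                                densities = seq(0.01, 0.15, length.out = 15),
                                coords = NULL, grid_shape = NULL,
                                voxel_size_mm = 1) {
  assert_that(length(densities) >= 1 && all(densities > 0 & densities <= 1),
              "invalid config: densities must be a non-empty grid in (0, 1]")
  W <- pmax(matrix, 0)
  acc <- NULL
  zero_all <- NULL
  for (d in densities) {
    res <- pc_values(threshold_by_density(W, d), partition)
    acc <- if (is.null(acc)) res$values else acc + res$values
    zero_all <- if (is.null(zero_all)) res$zero_strength else zero_all & res$zero_strength
  }
  vals <- acc / length(densities)
  if (is.null(coords)) {
    attr(vals, "zero_strength") <- zero_all
    return(vals)
  }
  voxel_stat_map(vals, coords, grid_shape, voxel_size_mm,
                 statistic = "participation_coefficient",
                 flags = zero_all,
                 provenance = list(densities = densities))
}

#' Average per-subject PC maps across subjects
#'
#' @param per_subject_maps List of `voxel_stat_map` (or numeric vectors) on
#'   one grid.
#' @return Voxel-wise arithmetic mean, same container as the inputs.
#' @export
group_average_pc <- function(per_subject_maps) {
  assert_that(length(per_subject_maps) >= 1, "invalid input: need at least one map")
  first <- per_subject_maps[[1]]
  if (inherits(first, "voxel_stat_map")) {
    for (m in per_subject_maps) {
      assert_that(identical(m$grid_shape, first$grid_shape) &&
                    identical(dim(m$coords), dim(first$coords)),
                  "geometry error: maps are not on a shared grid")
    }
    vals <- Reduce(`+`, lapply(per_subject_maps, `[[`, "values")) /
      length(per_subject_maps)
    out <- first
    out$values <- vals
    out$flags <- NULL
    out$provenance$subjects_averaged <- length(per_subject_maps)
    return(out)
  }
  lens <- vapply(per_subject_maps, length, integer(1))
  assert_that(length(unique(lens)) == 1, "geometry error: maps differ in length")
  Reduce(`+`, lapply(per_subject_maps, as.numeric)) / length(per_subject_maps)
}

#' Functional connectivity weight ratios (network selectivity)
#'
#' Divides each voxel's summed connectivity to a target system by its total
#' summed connectivity, yielding a selectivity profile: a ratio near 1 means
#' the voxel couples to a single system, overlapping moderate ratios mean
#' diffuse coupling with several. Negative weights are clipped to zero
#' first. With a `network_partition` the targets are the cortical networks
#' and the per-voxel ratios sum to 1; with a named list of ROI index sets
#' (e.g. meta-analytic term maps) ratios are normalized over the union of
#' the target sets.
#'
#' @param matrix Voxel x ROI weight matrix.
#' @param targets A `network_partition`, or a named list of ROI index
#'   vectors.
#' @return Voxel x target ratio matrix with attribute `zero_strength`
#'   flagging voxels with no positive weight (their ratios are NA).
#' @export
fc_weight_ratio <- function(matrix, targets) {
  W <- pmax(matrix, 0)
  if (inherits(targets, "network_partition")) {
    M <- partition_indicator(targets, ncol(W))
  } else {
    assert_that(is.list(targets) && length(targets) >= 1 &&
                  !is.null(names(targets)),
                "invalid input: targets must be a partition or named list of ROI sets")
    union_set <- sort(unique(unlist(targets)))
    assert_that(all(union_set >= 1 & union_set <= ncol(W)),
                "invalid input: target ROI indices out of range")
    M <- matrix(0, nrow = ncol(W), ncol = length(targets),
                dimnames = list(NULL, names(targets)))
    for (j in seq_along(targets)) M[targets[[j]], j] <- 1
    W <- W[, union_set, drop = FALSE]
    M <- M[union_set, , drop = FALSE]
  }
  num <- W %*% M
  tot <- rowSums(W)
  ratio <- num / tot
  ratio[tot == 0, ] <- NA_real_
  attr(ratio, "zero_strength") <- tot == 0
  ratio
}

#' Voxel-wise PC contrast between two lesion sites
#'
#' Samples the group-average PC map at the voxels of each site and contrasts
#' the two value distributions with a two-sample Kolmogorov-Smirnov test.
#'
#' @param group_pc_map A `voxel_stat_map`.
#' @param site_a,site_b Disjoint, non-empty site masks on the map's grid.
#' @return List with `ks` (a `ks_result`), `mean_a`, `mean_b`,
#'   `mean_difference`, `n_a`, `n_b`.
#' @export
site_contrast_voxelwise <- function(group_pc_map, site_a, site_b) {
  a_arr <- mask_array(site_a)
  b_arr <- mask_array(site_b)
  assert_that(sum(a_arr & b_arr) == 0, "invalid input: sites must be disjoint")
  va <- site_values(group_pc_map, site_a)
  vb <- site_values(group_pc_map, site_b)
  assert_that(length(va) >= 1 && length(vb) >= 1,
              "invalid input: a site contains no mapped voxels")
  ks <- ks_statistic(va, vb)
  list(ks = ks, mean_a = mean(va), mean_b = mean(vb),
       mean_difference = mean(va) - mean(vb),
       n_a = length(va), n_b = length(vb))
}

#' Subject-wise PC contrast between two lesion sites
#'
#' For each subject, averages the PC map within each site, then runs a
#' paired t test on the per-subject (site A, site B) pairs; df = number of
#' subjects - 1.
#'
#' @param per_subject_maps List of per-subject `voxel_stat_map`.
#' @param site_a,site_b Disjoint, non-empty site masks.
#' @return The [paired_t()] result plus `per_subject_a`, `per_subject_b`.
#' @export
site_contrast_subjectwise <- function(per_subject_maps, site_a, site_b) {
  assert_that(length(per_subject_maps) >= 2, "invalid input: need at least 2 subjects")
  a <- vapply(per_subject_maps, function(m) mean(site_values(m, site_a)), numeric(1))
  b <- vapply(per_subject_maps, function(m) mean(site_values(m, site_b)), numeric(1))
  res <- paired_t(a, b)
  res$per_subject_a <- a
  res$per_subject_b <- b
  res
}
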