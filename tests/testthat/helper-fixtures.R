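# Small study configurations used across tests; fixtures are generated in
# code, never stored.

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_subjects = 4L, n_thal_voxels = 200L,
                   n_rois = 28L, n_networks = 7L,
                   grid_shape = c(10L, 10L, 10L),
                   n_patients = 12L, lesion_size_range = c(100, 400),
                   n_control_sites = 4L, n_perm = 199L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Brute-force two-sample KS D: sup of |ECDF_a - ECDF_b| over all sample
# points, written independently of the package implementation.
brute_ks_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(fa - fb))
}

# Exhaustive permutation p for the absolute mean difference, written
# independently of the package implementation.
brute_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(length(pooled), n_a)
  stats <- apply(idx, 2, function(i) abs(mean(pooled[i]) - mean(pooled[-i])))
  mean(stats >= obs - 1e-12 * max(1, obs))
}

# A small binary 3-D mask from voxel linear indices.
mask_from_index <- function(idx, shape = c(4L, 4L, 4L), voxel_size = 1) {
  arr <- array(0L, dim = shape)
  arr[idx] <- 1L
  lesion_mask(arr, voxel_size_mm = voxel_size, allow_empty = length(idx) == 0)
}
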