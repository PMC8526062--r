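#' Per-voxel scalar field on the thalamus grid
#'
#' Holds one scalar per thalamic voxel (a PC map, a weight-ratio map, an
#' expression z-map) together with the voxel coordinate table that embeds it
#' into the 3-D grid.
#'
#' @param values Numeric vector, one value per thalamic voxel.
#' @param coords Integer matrix (n x 3) of voxel grid coordinates (1-based).
#' @param grid_shape Integer 3-vector.
#' @param voxel_size_mm Voxel edge length in mm.
#' @param statistic Name of the statistic.
#' @param flags Optional logical QC vector (e.g. zero-strength voxels).
#' @param provenance Optional list (densities, subjects averaged, ...).
#' @return A `voxel_stat_map`.
#' @export
voxel_stat_map <- function(values, coords, grid_shape, voxel_size_mm = 1,
                           statistic = "value", flags = NULL,
                           provenance = list()) {
  assert_that(is.matrix(coords) && ncol(coords) == 3,
              "invalid input: coords must be an n x 3 matrix")
  assert_that(length(values) == nrow(coords),
              "invalid input: values and coords must have matching length")
  assert_that(all(coords >= 1) && all(t(coords) <= grid_shape),
              "geometry error: coordinates outside grid")
  structure(list(values = as.numeric(values), coords = coords,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, statistic = statistic,
                 flags = flags, provenance = provenance),
            class = "voxel_stat_map")
}

#' Embed a voxel map into its full 3-D volume
#'
#' Off-thalamus voxels are filled with `background`.
#'
#' @param map A `voxel_stat_map`.
#' @param background Fill value outside the mapped voxels.
#' @return 3-D numeric array.
#' @export
as_volume <- function(map, background = 0) {
  arr <- array(background, dim = map$grid_shape)
  arr[map$coords] <- map$values
  arr
}

# Values of a voxel map inside a binary site mask (site given as lesion_mask
# or 3-D array on the map's grid).
site_values <- function(map, site) {
  arr <- mask_array(site)
  assert_that(identical(dim(arr), as.integer(map$grid_shape)),
              "geometry error: site mask not on the map's grid")
  inside <- arr[map$coords] > 0
  map$values[inside]
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat(sprintf("Voxel map `%s`: %d voxels on a %s grid (%g mm), range [%.4g, %.4g]\n",
              x$statistic, length(x$values),
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              min(x$values), max(x$values)))
  invisible(x)
}
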