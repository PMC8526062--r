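#' Simulation configuration for a synthetic lesion cohort
#'
#' Collects every knob of the synthetic-cohort generator: the voxel grid the
#' thalamus lives on, the planted connector-hub site, the normative connectome
#' cohort, the patient lesion cohort, the behavioural effect model, and the
#' two-gene expression gradient. All randomness in the generator flows from
#' the single `seed`.
#'
#' The defaults define the reference study conditions used throughout the
#' package's tests: a 500-voxel thalamus at 2 mm isotropic resolution, 100
#' cortical ROIs grouped into 7 functional networks, 30 normative subjects,
#' and 40 patients of whom half carry lesions at the planted hub site.
#'
#' @param seed Integer seed for the cohort-level RNG stream.
#' @param n_subjects Number of normative connectome subjects.
#' @param n_thal_voxels Number of thalamic voxels on the grid.
#' @param n_rois Number of cortical ROIs.
#' @param n_networks Number of cortical functional networks (must be >= 2).
#' @param grid_shape Integer 3-vector, voxel grid dimensions.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param hub_center Voxel coordinates (length 3) of the planted hub site;
#'   `NULL` places it at 70% of the thalamus radius along `gene_gradient_axis`.
#' @param hub_radius Hub site radius in voxels (> 0).
#' @param n_patients Number of lesion patients.
#' @param hub_fraction Fraction of patients whose lesions are seeded at the
#'   hub site; the rest are spread over scattered control sites.
#' @param n_control_sites Number of scattered control lesion sites.
#' @param lesion_size_range Length-2 mm^3 interval for lesion volumes.
#' @param effect_size_beta Behavioural effect in z-units per unit
#'   lesion-site overlap fraction.
#' @param noise_sd SD of the Gaussian noise on neuropsychological z-scores.
#' @param fc_noise_sd SD of the truncated Gaussian noise on per-edge
#'   connectivity weights.
#' @param expression_noise_sd SD of noise on the raw expression gradients; 0
#'   makes the two gene maps exactly complementary.
#' @param gene_gradient_axis Axis index (1-3) of the expression gradient and
#'   hub placement (emulating the anterior-posterior axis).
#' @param densities Density grid for graph thresholding, within (0, 1].
#' @param impairment_threshold z cutoff below which a test is impaired.
#' @param multi_domain_min_domains Minimum impaired-domain count for the
#'   "multi" classification.
#' @param n_perm Monte-Carlo permutations for group tests in the pipeline.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_subjects = 30L,
                              n_thal_voxels = 500L,
                              n_rois = 100L,
                              n_networks = 7L,
                              grid_shape = c(14L, 14L, 14L),
                              voxel_size_mm = 2,
                              hub_center = NULL,
                              hub_radius = 4,
                              n_patients = 40L,
                              hub_fraction = 0.5,
                              n_control_sites = 12L,
                              lesion_size_range = c(60, 250),
                              effect_size_beta = 3,
                              noise_sd = 1,
                              fc_noise_sd = 0.005,
                              expression_noise_sd = 0.1,
                              gene_gradient_axis = 1L,
                              densities = seq(0.01, 0.15, length.out = 15),
                              impairment_threshold = -1.645,
                              multi_domain_min_domains = 2L,
                              n_perm = 1999L) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_thal_voxels = as.integer(n_thal_voxels),
    n_rois = as.integer(n_rois),
    n_networks = as.integer(n_networks),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    hub_center = hub_center,
    hub_radius = hub_radius,
    n_patients = as.integer(n_patients),
    hub_fraction = hub_fraction,
    n_control_sites = as.integer(n_control_sites),
    lesion_size_range = lesion_size_range,
    effect_size_beta = effect_size_beta,
    noise_sd = noise_sd,
    fc_noise_sd = fc_noise_sd,
    expression_noise_sd = expression_noise_sd,
    gene_gradient_axis = as.integer(gene_gradient_axis),
    densities = densities,
    impairment_threshold = impairment_threshold,
    multi_domain_min_domains = as.integer(multi_domain_min_domains),
    n_perm = as.integer(n_perm)
  )
  validate_config(cfg)
  if (is.null(cfg$hub_center)) cfg$hub_center <- default_hub_center(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  counts <- c("n_subjects", "n_thal_voxels", "n_rois", "n_networks",
              "n_patients", "n_control_sites", "n_perm")
  for (nm in counts) {
    assert_that(is_count(cfg[[nm]]), "invalid config: `%s` must be a positive integer", nm)
  }
  assert_that(cfg$n_networks >= 2, "invalid config: need at least 2 networks")
  assert_that(cfg$n_rois >= cfg$n_networks,
              "invalid config: n_rois (%d) < n_networks (%d)",
              cfg$n_rois, cfg$n_networks)
  assert_that(length(cfg$grid_shape) == 3 && all(cfg$grid_shape >= 1),
              "invalid config: grid_shape must be 3 positive integers")
  assert_that(cfg$n_thal_voxels <= prod(cfg$grid_shape),
              "invalid config: n_thal_voxels exceeds grid capacity")
  assert_that(cfg$voxel_size_mm > 0, "invalid config: voxel_size_mm must be > 0")
  assert_that(cfg$hub_radius > 0, "invalid config: hub_radius must be > 0")
  assert_that(length(cfg$lesion_size_range) == 2 &&
                all(cfg$lesion_size_range > 0) &&
                diff(cfg$lesion_size_range) >= 0,
              "invalid config: lesion_size_range must be a positive ordered interval")
  assert_that(cfg$noise_sd >= 0 && cfg$fc_noise_sd >= 0 && cfg$expression_noise_sd >= 0,
              "invalid config: noise SDs must be >= 0")
  assert_that(cfg$hub_fraction >= 0 && cfg$hub_fraction <= 1,
              "invalid config: hub_fraction must lie in [0, 1]")
  assert_that(cfg$gene_gradient_axis %in% 1:3,
              "invalid config: gene_gradient_axis must be 1, 2 or 3")
  assert_that(all(cfg$densities > 0 & cfg$densities <= 1),
              "invalid config: densities must lie in (0, 1]")
  if (!is.null(cfg$hub_center)) {
    assert_that(length(cfg$hub_center) == 3 &&
                  all(cfg$hub_center >= 1 & cfg$hub_center <= cfg$grid_shape),
                "invalid config: hub_center outside grid")
  }
  invisible(TRUE)
}

# Hub placed inside the thalamus blob, at half its radius towards the high
# end of the gradient axis (the "anterior" pole) — deep enough that a
# hub_radius sphere is mostly inside the blob, so hub lesions grown there
# genuinely overlap the hub site.
default_hub_center <- function(cfg) {
  ctr <- (cfg$grid_shape + 1) / 2
  thal_radius <- (3 * cfg$n_thal_voxels / (4 * pi))^(1 / 3)
  hub <- ctr
  hub[cfg$gene_gradient_axis] <- ctr[cfg$gene_gradient_axis] + 0.5 * thal_radius
  round(hub)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  grid %s at %g mm, %d thalamic voxels\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm, x$n_thal_voxels))
  cat(sprintf("  %d ROIs in %d networks, %d normative subjects\n",
              x$n_rois, x$n_networks, x$n_subjects))
  cat(sprintf("  %d patients (hub fraction %.2f), beta = %g, noise SD = %g, seed = %d\n",
              x$n_patients, x$hub_fraction, x$effect_size_beta, x$noise_sd, x$seed))
  invisible(x)
}
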