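#' Run the full lesion-network analysis pipeline
#'
#' Orchestrates the whole analysis as one reproducible run: generate (or
#' receive) a cohort, orient and score the neuropsychological battery,
#' compare groups test-by-test with permutation tests, classify patients by
#' impairment breadth, build the exclusive multi- vs single-domain lesion
#' sites, compute voxel-wise participation coefficients across density
#' thresholds from the normative connectomes and contrast the sites both
#' voxel-wise (Kolmogorov-Smirnov) and subject-wise (paired t), profile the
#' functional connectivity weight ratios of the multi-domain site, and
#' contrast the normalized two-gene expression maps between sites. All
#' randomness flows from `config$seed`, so the same config yields an
#' identical report.
#'
#' @param config A [simulation_config()].
#' @param cohort Optional pre-generated `synthetic_cohort`; by default one is
#'   generated from `config`.
#' @param out_dir Optional run directory; when given, the cohort, the
#'   derived maps and the JSON report are written under it.
#' @return A `thalamap_report` (nested list with one section per stage).
#' @export
run_pipeline <- function(config = simulation_config(), cohort = NULL,
                         out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  battery <- test_battery()
  vs <- config$voxel_size_mm

  ## --- neuropsych stage -------------------------------------------------
  oriented <- orient_scores(cohort$scores, battery)
  comparison <- group_comparison(oriented, battery,
                                 groups = c("hub", "control"),
                                 n_perm = config$n_perm,
                                 seed = config$seed + 1000L)
  profiles <- patient_profiles(oriented, battery,
                               threshold = config$impairment_threshold,
                               min_domains = config$multi_domain_min_domains)
  flags <- impairment_flags(oriented, battery, config$impairment_threshold)

  ## --- lesion stage -----------------------------------------------------
  masks <- cohort$lesions$masks
  per_task <- lapply(battery$test, function(tst) masks[flags[, tst]])
  names(per_task) <- battery$test
  composite <- task_overlap_composite(per_task, grid_shape = config$grid_shape)
  peak <- which(composite == max(composite), arr.ind = TRUE)

  is_multi <- profiles$classification == "multi"
  site_contrast <- NULL
  multi_site <- single_site <- NULL
  if (any(is_multi) && any(!is_multi)) {
    site_contrast <- withCallingHandlers(
      exclusive_site_contrast(masks[is_multi], masks[!is_multi], vs),
      warning = function(w) invokeRestart("muffleWarning"))
    multi_site <- site_contrast$multi_site
    single_site <- site_contrast$single_site
  }
  sites_usable <- !is.null(site_contrast) && !site_contrast$empty_output

  vol_domain_cor <- pearson_correlation(profiles$lesion_volume_mm3,
                                        profiles$n_impaired_domains)

  ## --- hub stage --------------------------------------------------------
  pc_maps <- lapply(cohort$connectomes, function(W) {
    pc_across_densities(W, cohort$partition, config$densities,
                        coords = cohort$coords,
                        grid_shape = config$grid_shape, voxel_size_mm = vs)
  })
  group_pc <- group_average_pc(pc_maps)
  pc_voxelwise <- pc_subjectwise <- NULL
  if (sites_usable) {
    pc_voxelwise <- site_contrast_voxelwise(group_pc, multi_site, single_site)
    pc_subjectwise <- site_contrast_subjectwise(pc_maps, multi_site, single_site)
  }
  mean_W <- Reduce(`+`, cohort$connectomes) / length(cohort$connectomes)
  ratios <- fc_weight_ratio(mean_W, cohort$partition)
  ratio_map <- voxel_stat_map(rep(0, nrow(cohort$coords)), cohort$coords,
                              config$grid_shape, vs, "weight_ratio")
  ratio_summary <- NULL
  if (sites_usable) {
    in_multi <- mask_array(multi_site)[cohort$coords] > 0
    ratio_summary <- colMeans(ratios[in_multi, , drop = FALSE], na.rm = TRUE)
  }

  ## --- expression stage -------------------------------------------------
  calb1_z <- normalize_expression_zscore(cohort$expression$geneA)
  pvalb_z <- normalize_expression_zscore(cohort$expression$geneB)
  diff_map <- core_matrix_difference_map(calb1_z, pvalb_z)
  expr <- list()
  if (sites_usable) {
    expr$calb1 <- expression_site_contrast(calb1_z, multi_site, single_site)
    expr$pvalb <- expression_site_contrast(pvalb_z, multi_site, single_site)
    expr$dice_calb1_multi <- expression_lesion_dice(calb1_z, multi_site)
    expr$dice_calb1_single <- expression_lesion_dice(calb1_z, single_site)
  }

  ## --- report -----------------------------------------------------------
  report <- list(
    config = unclass(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("thalamap")),
    neuropsych = list(group_comparison = comparison,
                      bonferroni_threshold = attr(comparison, "bonferroni_threshold"),
                      profiles = profiles,
                      n_multi = sum(is_multi),
                      n_single = sum(profiles$classification == "single"),
                      n_none = sum(profiles$classification == "none"),
                      volume_vs_domains = vol_domain_cor),
    sites = list(usable = sites_usable,
                 multi_voxels = if (!is.null(multi_site)) sum(multi_site$data) else 0L,
                 single_voxels = if (!is.null(single_site)) sum(single_site$data) else 0L,
                 multi_volume_mm3 = if (!is.null(multi_site)) lesion_volume(multi_site) else 0,
                 single_volume_mm3 = if (!is.null(single_site)) lesion_volume(single_site) else 0,
                 composite_peak = unname(peak[1, ]),
                 composite_peak_ties = nrow(peak)),
    hubs = list(pc_mean = mean(group_pc$values),
                pc_range = range(group_pc$values),
                densities = config$densities,
                voxelwise = pc_voxelwise,
                subjectwise = if (is.null(pc_subjectwise)) NULL else
                  pc_subjectwise[c("t", "df", "p_value", "mean_difference", "degenerate")],
                weight_ratio_multi_site = as.list(ratio_summary)),
    expression = expr
  )
  class(report) <- "thalamap_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write_map(group_pc, file.path(out_dir, "pc_map.nii.gz"))
    write_map(diff_map, file.path(out_dir, "calb1_minus_pvalb.nii.gz"))
    if (sites_usable) {
      write_map(multi_site, file.path(out_dir, "multi_site.nii.gz"))
      write_map(single_site, file.path(out_dir, "single_site.nii.gz"))
    }
    utils::write.table(profiles, file.path(out_dir, "patient_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# Flatten report components that jsonlite cannot round-trip cleanly.
report_to_json <- function(report) {
  r <- unclass(report)
  r$neuropsych$group_comparison <- as.data.frame(r$neuropsych$group_comparison)
  if (!is.null(r$hubs$voxelwise)) {
    r$hubs$voxelwise$ks <- unclass(r$hubs$voxelwise$ks)
  }
  for (nm in c("calb1", "pvalb")) {
    if (!is.null(r$expression[[nm]])) {
      r$expression[[nm]]$ks <- unclass(r$expression[[nm]]$ks)
    }
  }
  r
}

#' @export
print.thalamap_report <- function(x, ...) {
  cat("thalamap pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  patients: %d multi / %d single / %d none\n",
              x$neuropsych$n_multi, x$neuropsych$n_single, x$neuropsych$n_none))
  sig <- x$neuropsych$group_comparison$significant
  cat(sprintf("  group comparison: %d/%d tests significant at Bonferroni %.4g\n",
              sum(sig), length(sig), x$neuropsych$bonferroni_threshold))
  if (x$sites$usable) {
    cat(sprintf("  sites: multi %d voxels, single %d voxels\n",
                x$sites$multi_voxels, x$sites$single_voxels))
    cat(sprintf("  PC contrast: KS d = %.3f (p = %.3g), paired t(%d) = %.2f (p = %.3g)\n",
                x$hubs$voxelwise$ks$d, x$hubs$voxelwise$ks$p_value,
                x$hubs$subjectwise$df, x$hubs$subjectwise$t,
                x$hubs$subjectwise$p_value))
    cat(sprintf("  CALB1-like contrast: KS d = %.3f; Dice multi %.3f vs single %.3f\n",
                x$expression$calb1$ks$d, x$expression$dice_calb1_multi,
                x$expression$dice_calb1_single))
  } else {
    cat("  sites: unusable (empty exclusive site); contrasts skipped\n")
  }
  invisible(x)
}
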