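test_that("partition assigns every ROI to one non-empty network, reproducibly", {
  p <- generate_partition(7, 7, seed = 1)
  expect_equal(sort(tabulate(p$membership, 7)), rep(1L, 7))

  p400 <- generate_partition(400, 7, seed = 1)
  expect_length(p400$membership, 400)
  expect_true(all(tabulate(p400$membership, 7) >= 1))
  expect_equal(p400$networks, c("VIS", "SM", "DA", "CO", "LM", "FP", "DMN"))

  expect_identical(generate_partition(14, 7, seed = 1)$membership,
                   generate_partition(14, 7, seed = 1)$membership)
  expect_error(generate_partition(5, 7), "n_rois")
})

test_that("noiseless connectomes realize the planted analytic PC", {
  cfg <- tiny_config(fc_noise_sd = 0, n_subjects = 1L)
  coords <- head(thalamap:::thalamus_coords(cfg), 11)
  part <- generate_partition(cfg$n_rois, cfg$n_networks, seed = 2)
  g <- seq(0, 1, by = 0.1)
  W <- generate_connectome_cohort(cfg, g, part, coords, seed = 3)[[1]]
  pc <- participation_coefficient(W, part)

  # g = 0: all weight in the home network; g = 1: uniform across 7 networks
  expect_equal(pc[1], 0)
  expect_equal(pc[11], 6 / 7)
  # analytic PC is strictly increasing in the gradient
  expect_true(all(diff(pc) > 0))
})

test_that("connectome noise is truncated so weights stay non-negative", {
  cfg <- tiny_config(fc_noise_sd = 0.5, n_subjects = 2L)
  coh <- generate_connectome_cohort(cfg, seed = 4)
  expect_true(all(vapply(coh, function(W) all(W >= 0), logical(1))))
  expect_error(generate_connectome_cohort(tiny_config(), g = c(-0.1, rep(0.5, 199))),
               "\\[0, 1\\]")
})

test_that("lesion cohort hits target volumes, stays reproducible, obeys hub fraction", {
  cfg <- tiny_config()
  les <- generate_lesion_cohort(cfg, seed = 5)
  vols <- vapply(les$masks, lesion_volume, numeric(1))
  expect_equal(vols, les$info$volume_mm3)
  expect_true(all(vols >= cfg$lesion_size_range[1] - cfg$voxel_size_mm^3 &
                    vols <= cfg$lesion_size_range[2]))

  les2 <- generate_lesion_cohort(cfg, seed = 5)
  expect_identical(lapply(les$masks, `[[`, "data"),
                   lapply(les2$masks, `[[`, "data"))

  cfg0 <- tiny_config(hub_fraction = 0)
  les0 <- generate_lesion_cohort(cfg0, seed = 6)
  hub <- thalamap:::hub_site_mask(cfg0)
  overlaps <- vapply(les0$masks, function(m) sum(m$data & hub$data), numeric(1))
  expect_true(all(les0$info$group == "control"))
  expect_true(all(overlaps == 0))  # control lesions spare the hub site

  expect_error(generate_lesion_cohort(
    tiny_config(lesion_size_range = c(1e6, 2e6))), "capacity")
})

test_that("planted score model is exact without noise and recovered with it", {
  bat <- test_battery()
  cfg0 <- tiny_config(effect_size_beta = 0, noise_sd = 0)
  les <- generate_lesion_cohort(cfg0, seed = 7)
  hub <- thalamap:::hub_site_mask(cfg0)
  sc0 <- generate_neuropsych_scores(les, hub, cfg0, seed = 8)
  expect_true(all(as.matrix(sc0[, bat$test]) == 0))

  # noiseless linear model: oriented scores equal -beta * overlap on loaded tests
  cfg1 <- tiny_config(noise_sd = 0)
  les1 <- generate_lesion_cohort(cfg1, seed = 9)
  hub1 <- thalamap:::hub_site_mask(cfg1)
  sc1 <- generate_neuropsych_scores(les1, hub1, cfg1, seed = 10)
  tr <- attr(sc1, "truth")
  oriented <- orient_scores(sc1, bat)
  loaded <- bat$test[bat$domain %in% c("executive", "verbal", "memory")]
  hub_rows <- sc1$group == "hub"
  for (tst in loaded) {
    expect_equal(oriented[[tst]][hub_rows], tr$planted_effect[hub_rows])
  }
  off <- setdiff(bat$test, loaded)
  expect_true(all(as.matrix(oriented[hub_rows, off]) == 0))

  # Monte-Carlo recovery: mean loaded-test z within 3 SE of -beta * mean overlap
  cfg2 <- simulation_config(seed = 2, noise_sd = 0.5, n_patients = 40L)
  les2 <- generate_lesion_cohort(cfg2, seed = 11)
  hub2 <- thalamap:::hub_site_mask(cfg2)
  sc2 <- generate_neuropsych_scores(les2, hub2, cfg2, seed = 12)
  tr2 <- attr(sc2, "truth")
  or2 <- orient_scores(sc2, bat)
  hub2_rows <- sc2$group == "hub"
  z_loaded <- as.matrix(or2[hub2_rows, loaded])
  expected <- -cfg2$effect_size_beta * mean(tr2$hub_overlap[hub2_rows])
  se <- 0.5 / sqrt(length(z_loaded))
  expect_lt(abs(mean(z_loaded) - expected), 3 * se)
})

test_that("expression gradients are complementary, axis-aligned and seeded", {
  cfg <- tiny_config(expression_noise_sd = 0)
  maps <- generate_expression_maps(cfg, seed = 13)
  expect_equal(maps$geneA$values + maps$geneB$values,
               rep(1, length(maps$geneA$values)))

  cfg2 <- tiny_config(expression_noise_sd = 0.1)
  maps2 <- generate_expression_maps(cfg2, seed = 14)
  coords <- thalamap:::thalamus_coords(cfg2)
  axis_coord <- coords[, cfg2$gene_gradient_axis]
  expect_gt(cor(maps2$geneA$values, axis_coord), 0)
  expect_lt(cor(maps2$geneB$values, axis_coord), 0)

  maps3 <- generate_expression_maps(cfg2, seed = 14)
  expect_identical(maps2$geneA$values, maps3$geneA$values)
})

test_that("full cohort is reproducible from its config seed alone", {
  cfg <- tiny_config(seed = 21)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$scores, c2$scores)
  expect_identical(c1$connectomes[[1]], c2$connectomes[[1]])
  expect_identical(c1$gradient, c2$gradient)
  # all masks and maps share one grid
  expect_true(all(vapply(c1$lesions$masks,
                         function(m) identical(dim(m$data), dim(c1$hub_site$data)),
                         logical(1))))
  expect_length(c1$truth$gradient, cfg$n_thal_voxels)
})

test_that("cohort round-trips through the on-disk layout", {
  cfg <- tiny_config(seed = 22, n_patients = 3L, n_subjects = 2L)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "scores.tsv")))
  sc <- read.delim(file.path(dir, "scores.tsv"))
  expect_equal(names(sc)[1:3], c("patient_id", "group", "lesion_volume_mm3"))
  m <- read_mask(file.path(dir, "lesions", "pat-001.nii.gz"))
  expect_identical(m$data, coh$lesions$masks[[1]]$data)
})
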