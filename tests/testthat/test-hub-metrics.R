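# A 3-network partition over 4 ROIs: networks {1}, {2}, {3,4}
part3 <- network_partition(c(1L, 2L, 3L, 3L))
# A 7-network partition over 7 ROIs, one ROI each
part7 <- network_partition(1:7)

test_that("FC from time series is voxel-to-ROI Pearson correlation", {
  t_axis <- seq(0, 2 * pi, length.out = 64)[-64]
  v <- rbind(sin(t_axis), cos(t_axis))
  r <- rbind(sin(t_axis), -sin(t_axis), cos(t_axis))
  W <- fc_from_timeseries(v, r)
  expect_equal(dim(W), c(2L, 3L))
  expect_equal(W[1, 1], 1)
  expect_equal(W[1, 2], -1)
  # quadrature pair over full periods is orthogonal
  expect_lt(abs(W[1, 3]), 1e-6)

  bad <- rbind(sin(t_axis), rep(1, length(t_axis)))
  expect_error(fc_from_timeseries(bad, r), "voxel\\(s\\) 2")
  expect_error(fc_from_timeseries(v, r[, 1:10]), "equal length")
})

test_that("density thresholding keeps the top global fraction of positive weights", {
  W <- matrix(c(5, 4, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1), nrow = 2)
  thr <- threshold_by_density(W, 0.2)
  expect_equal(sum(thr > 0), 2)
  expect_equal(sort(thr[thr > 0], decreasing = TRUE), c(5, 4))

  Wpos <- matrix(runif(20) + 0.1, nrow = 4)
  expect_equal(threshold_by_density(Wpos, 1), Wpos)

  expect_error(threshold_by_density(-Wpos, 0.5), "no positive weights")
  expect_error(threshold_by_density(Wpos, 0), "density")
})

test_that("participation coefficient matches hand-computed values", {
  # all weight in one network -> 0
  w_single <- matrix(c(3, 0, 0, 0), nrow = 1)
  expect_equal(unname(participation_coefficient(w_single, part3)[1]), 0)

  # uniform across 7 networks -> 1 - 7 (1/7)^2 = 6/7
  w_unif <- matrix(rep(1, 7), nrow = 1)
  expect_equal(unname(participation_coefficient(w_unif, part7)[1]), 6 / 7)

  # network strengths (2, 1, 1) with NM = 3 -> 1 - (0.25 + 0.0625 + 0.0625)
  w_211 <- matrix(c(2, 1, 0.5, 0.5), nrow = 1)
  expect_equal(unname(participation_coefficient(w_211, part3)[1]), 0.625)

  # zero-strength voxels get PC = 0 and a QC flag
  w0 <- matrix(0, nrow = 1, ncol = 4)
  pc0 <- participation_coefficient(w0, part3)
  expect_equal(unname(pc0[1]), 0)
  expect_true(attr(pc0, "zero_strength")[1])
  expect_error(participation_coefficient(matrix(-1, 1, 4), part3), "non-negative")
})

test_that("PC is scale-invariant and maximal exactly at uniform spread", {
  set.seed(19)
  for (i in 1:20) {
    w <- matrix(runif(7), nrow = 1)
    pc1 <- participation_coefficient(w, part7)
    pc2 <- participation_coefficient(w * runif(1, 0.1, 50), part7)
    expect_equal(unname(pc1[1]), unname(pc2[1]), tolerance = 1e-12)
    if (stats::sd(w) > 1e-6) expect_lt(unname(pc1[1]), 6 / 7)
  }
  expect_equal(unname(participation_coefficient(matrix(2, 1, 7), part7)[1]), 6 / 7)
})

test_that("PC across densities averages the per-density maps", {
  set.seed(20)
  W <- matrix(runif(40), nrow = 10)
  one <- pc_across_densities(W, part3, densities = 0.5)
  direct <- participation_coefficient(threshold_by_density(W, 0.5), part3)
  expect_equal(as.numeric(one), as.numeric(direct))

  # uniform rows retained whole keep their maximal PC = 6/7
  Wu <- matrix(1, nrow = 3, ncol = 7)
  pcu <- pc_across_densities(Wu, part7, densities = 1)
  expect_equal(as.numeric(pcu), rep(6 / 7, 3))

  dens <- c(0.2, 0.5, 0.9)
  per <- sapply(dens, function(d)
    as.numeric(participation_coefficient(threshold_by_density(W, d), part3)))
  avg <- as.numeric(pc_across_densities(W, part3, densities = dens))
  expect_true(all(avg >= apply(per, 1, min) - 1e-12 &
                    avg <= apply(per, 1, max) + 1e-12))
})

test_that("group averaging of PC maps is the voxel-wise mean", {
  coords <- cbind(1:5, 1, 1)
  m1 <- voxel_stat_map(rep(0.4, 5), coords, c(5, 5, 5))
  m2 <- voxel_stat_map(rep(0.6, 5), coords, c(5, 5, 5))
  avg <- group_average_pc(list(m1, m2))
  expect_equal(avg$values, rep(0.5, 5))
  expect_equal(group_average_pc(list(m1))$values, m1$values)
  expect_equal(group_average_pc(list(m2, m1))$values, avg$values)
})

test_that("FC weight ratios normalize per voxel and sum to one over networks", {
  w_unif <- matrix(1, nrow = 1, ncol = 7)
  expect_equal(as.numeric(fc_weight_ratio(w_unif, part7)), rep(1 / 7, 7))

  w_single <- matrix(c(3, 0, 0, 0), nrow = 1)
  expect_equal(as.numeric(fc_weight_ratio(w_single, part3)), c(1, 0, 0))

  w_211 <- matrix(c(2, 1, 0.5, 0.5), nrow = 1)
  expect_equal(as.numeric(fc_weight_ratio(w_211, part3)), c(0.5, 0.25, 0.25))

  set.seed(21)
  W <- matrix(runif(70), nrow = 10)
  r <- fc_weight_ratio(W, part7)
  expect_equal(unname(rowSums(r)), rep(1, 10), tolerance = 1e-12)

  # term-map targets: ratios normalized over the union of the sets
  terms <- list(executive = c(1, 2), recall = c(3, 4, 5))
  rt <- fc_weight_ratio(W, terms)
  expect_equal(colnames(rt), c("executive", "recall"))
  union_tot <- rowSums(W[, 1:5])
  expect_equal(unname(rt[, 1]), unname(rowSums(W[, 1:2]) / union_tot))

  w0 <- rbind(W[1, ], 0)
  r0 <- fc_weight_ratio(w0, part7)
  expect_true(attr(r0, "zero_strength")[2])
  expect_true(all(is.na(r0[2, ])))
})

test_that("voxel-wise site contrast recovers a planted gradient and is symmetric", {
  coords <- as.matrix(expand.grid(x = 1:6, y = 1:6, z = 1))
  vals <- coords[, 1] / 6  # gradient along x
  map <- voxel_stat_map(vals, coords, c(6, 6, 2))
  site_a <- array(0L, dim = c(6, 6, 2)); site_a[5:6, , 1] <- 1L
  site_b <- array(0L, dim = c(6, 6, 2)); site_b[1:2, , 1] <- 1L

  res <- site_contrast_voxelwise(map, site_a, site_b)
  expect_gt(res$ks$d, 0)
  expect_gt(res$mean_a, res$mean_b)

  swapped <- site_contrast_voxelwise(map, site_b, site_a)
  expect_equal(swapped$ks$d, res$ks$d)
  expect_equal(swapped$mean_difference, -res$mean_difference)

  # identical value multisets across disjoint sites -> d = 0
  map2 <- voxel_stat_map(rep(0.5, nrow(coords)), coords, c(6, 6, 2))
  expect_equal(site_contrast_voxelwise(map2, site_a, site_b)$ks$d, 0)
  expect_error(site_contrast_voxelwise(map, site_a, site_a), "disjoint")
})

test_that("subject-wise site contrast is a paired t over per-subject site means", {
  coords <- as.matrix(expand.grid(x = 1:6, y = 1:6, z = 1))
  site_a <- array(0L, dim = c(6, 6, 2)); site_a[5:6, , 1] <- 1L
  site_b <- array(0L, dim = c(6, 6, 2)); site_b[1:2, , 1] <- 1L

  # 235 subjects, constant maps -> t = 0 (degenerate), df = 234
  maps_const <- lapply(1:235, function(s)
    voxel_stat_map(rep(0.3, nrow(coords)), coords, c(6, 6, 2)))
  res0 <- site_contrast_subjectwise(maps_const, site_a, site_b)
  expect_equal(res0$t, 0)
  expect_equal(res0$df, 234L)

  set.seed(22)
  maps <- lapply(1:20, function(s)
    voxel_stat_map(coords[, 1] / 6 + rnorm(nrow(coords), 0, 0.05),
                   coords, c(6, 6, 2)))
  res <- site_contrast_subjectwise(maps, site_a, site_b)
  expect_gt(res$t, 0)
  expect_equal(res$df, 19L)
})

test_that("the same machinery applies to a whole-brain voxel-by-ROI matrix", {
  # grey-matter variant: more voxels, subcortical labels appended as extra
  # networks; only the shape/contract is asserted
  part9 <- network_partition(c(1:7, 8L, 9L),
                             networks = c("VIS", "SM", "DA", "CO", "LM", "FP",
                                          "DMN", "BG", "THAL"))
  set.seed(23)
  W <- matrix(runif(900), nrow = 100)
  pc <- pc_across_densities(W, part9, densities = c(0.05, 0.1))
  expect_length(pc, 100)
  expect_true(all(pc >= 0 & pc <= 1 - 1 / 9 + 1e-12))
})
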