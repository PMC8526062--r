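test_that("masks round-trip through NIfTI and invalid images are rejected", {
  m <- mask_from_index(c(1, 5, 20), voxel_size = 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_map(m, path)
  back <- read_mask(path)
  expect_identical(back$data, m$data)
  expect_equal(back$voxel_size_mm, 2)

  # 4-D images are not lesion masks
  p4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(3, 3, 3, 2))), p4)
  expect_error(read_mask(p4), "3-D")

  # empty masks are rejected
  p0 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(3, 3, 3))), p0)
  expect_error(read_mask(p0), "empty")

  # non-binary input binarized with a warning
  pnb <- withr::local_tempfile(fileext = ".nii.gz")
  arr <- array(0, dim = c(3, 3, 3))
  arr[1:3] <- c(0, 0.2, 0.9)
  RNifti::writeNifti(RNifti::asNifti(arr), pnb)
  expect_warning(mb <- read_mask(pnb), "binarized")
  expect_equal(sum(mb$data), 1)
})

test_that("overlap map sums masks voxel-wise and ignores order", {
  a <- mask_from_index(1:10)
  b <- mask_from_index(6:15)
  expect_equal(unclass(overlap_map(list(a)))[1:10], rep(1L, 10),
               ignore_attr = TRUE)

  om <- overlap_map(list(a, b))
  expect_equal(sum(om == 2), 5)     # voxels 6..10 shared
  expect_equal(max(overlap_map(list(mask_from_index(1:3), mask_from_index(10:12)))), 1)

  om_rev <- overlap_map(list(b, a))
  expect_equal(as.vector(om), as.vector(om_rev))
  expect_error(overlap_map(list(a, mask_from_index(1, shape = c(5, 5, 5)))),
               "geometry")
})

test_that("task composite binarizes per task before summing", {
  a <- mask_from_index(1:6)
  b <- mask_from_index(4:9)
  tasks <- list(t1 = list(a, b), t2 = list(a), t3 = list(), t4 = list(b))
  comp <- task_overlap_composite(tasks)
  # voxel 5 is covered in tasks t1, t2, t4 -> 3; per-task count is irrelevant
  expect_equal(comp[5], 3)
  expect_lte(max(comp), length(tasks))

  single <- task_overlap_composite(list(only = list(a, b)))
  expect_equal(as.vector(single), as.vector(overlap_map(list(a, b)) >= 1) * 1L)

  empty <- task_overlap_composite(list(x = list(), y = list()),
                                  grid_shape = c(4, 4, 4))
  expect_equal(sum(empty), 0)
})

test_that("exclusive site contrast is a set difference with disjoint outputs", {
  multi <- list(mask_from_index(c(1, 2, 3)))
  single <- list(mask_from_index(c(3, 4)))
  res <- exclusive_site_contrast(multi, single)
  expect_equal(which(res$multi_site$data == 1), c(1L, 2L))
  expect_equal(which(res$single_site$data == 1), 4L)
  expect_false(res$empty_output)

  expect_warning(
    res_id <- exclusive_site_contrast(list(mask_from_index(1:5)),
                                      list(mask_from_index(1:5))),
    "empty")
  expect_true(res_id$empty_output)

  res_dj <- exclusive_site_contrast(list(mask_from_index(1:3)),
                                    list(mask_from_index(10:12)))
  expect_equal(which(res_dj$multi_site$data == 1), 1:3)
  expect_equal(which(res_dj$single_site$data == 1), 10:12)

  # property: outputs disjoint from each other and the opposite union
  set.seed(17)
  for (i in 1:20) {
    m <- lapply(1:3, function(.) mask_from_index(sample(64, 12)))
    s <- lapply(1:3, function(.) mask_from_index(sample(64, 12)))
    r <- suppressWarnings(exclusive_site_contrast(m, s))
    expect_equal(sum(r$multi_site$data & r$single_site$data), 0)
    expect_equal(sum(r$multi_site$data & (overlap_map(s) >= 1)), 0)
    expect_equal(sum(r$single_site$data & (overlap_map(m) >= 1)), 0)
  }
})

test_that("lesion volume is voxel count times voxel volume", {
  expect_equal(lesion_volume(mask_from_index(1:100, shape = c(5, 5, 5),
                                             voxel_size = 2)), 800)
  expect_equal(lesion_volume(mask_from_index(1, voxel_size = 1)), 1)
  expect_equal(lesion_volume(mask_from_index(integer(0))), 0)
})

test_that("atlas overlap reports per-label percentages over lesion voxels", {
  atlas <- array(0L, dim = c(4, 4, 4))
  atlas[1:6] <- 1L   # label A
  atlas[7:10] <- 2L  # label B
  lesion <- mask_from_index(1:10)
  res <- atlas_overlap(lesion, atlas,
                       labels = data.frame(label = 1:2, name = c("AN", "MD")))
  expect_equal(res$labels_hit, 2L)
  expect_equal(res$table$pct_of_lesion[res$table$name == "AN"], 60)
  expect_equal(res$table$pct_of_lesion[res$table$name == "MD"], 40)

  bg <- atlas_overlap(mask_from_index(30:35), atlas)
  expect_equal(bg$labels_hit, 0L)

  inside <- atlas_overlap(mask_from_index(1:4), atlas)
  expect_equal(inside$table$pct_of_lesion, 100)
})

test_that("Dice is the symmetric overlap ratio", {
  a <- mask_from_index(1:10)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(mask_from_index(1:5), mask_from_index(6:10)), 0)
  expect_equal(dice(mask_from_index(1:10), mask_from_index(6:15)), 0.5)
  expect_error(dice(a, mask_from_index(integer(0))), "empty")

  set.seed(18)
  for (i in 1:10) {
    x <- mask_from_index(sample(64, 20))
    y <- mask_from_index(sample(64, 15))
    expect_equal(dice(x, y), dice(y, x))
  }
})
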