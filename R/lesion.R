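#' Construct a binary lesion mask
#'
#' @param data 3-D array, strictly binary (0/1 or logical).
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param patient_id Optional label.
#' @param allow_empty Permit an all-zero mask (used for derived site masks).
#' @return A `lesion_mask`: list with integer `data`, `voxel_size_mm`,
#'   `patient_id`.
#' @export
lesion_mask <- function(data, voxel_size_mm = 1, patient_id = NULL,
                        allow_empty = FALSE) {
  assert_that(length(dim(data)) == 3, "invalid input: mask must be a 3-D array")
  vals <- unique(as.vector(data))
  assert_that(all(vals %in% c(0, 1, TRUE, FALSE)),
              "invalid input: mask must be strictly binary")
  arr <- array(as.integer(data != 0), dim = dim(data))
  if (!allow_empty) {
    assert_that(sum(arr) > 0, "invalid input: mask is empty")
  }
  structure(list(data = arr, voxel_size_mm = voxel_size_mm,
                 patient_id = patient_id),
            class = "lesion_mask")
}

mask_array <- function(x) {
  if (inherits(x, "lesion_mask")) x$data else x
}

check_shared_grid <- function(masks) {
  dims <- lapply(masks, function(m) dim(mask_array(m)))
  assert_that(length(unique(vapply(dims, paste, character(1), collapse = "x"))) == 1,
              "geometry error: masks are not on a shared grid")
  invisible(dims[[1]])
}

#' Read a lesion mask from a NIfTI file
#'
#' Values are binarized at > 0.5 (with a warning if the stored image was not
#' already binary); 4-D images and empty masks are rejected.
#'
#' @param path NIfTI file path.
#' @param patient_id Optional label.
#' @return A `lesion_mask`.
#' @export
read_mask <- function(path, patient_id = NULL) {
  assert_that(file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  assert_that(length(dim(img)) == 3,
              "invalid input: expected a 3-D image, got %d-D", length(dim(img)))
  vals <- unique(as.vector(img))
  if (!all(vals %in% c(0, 1))) {
    warning("non-binary input image binarized at > 0.5", call. = FALSE)
  }
  vs <- RNifti::pixdim(img)[1]
  lesion_mask(array(img > 0.5, dim = dim(img)), voxel_size_mm = vs,
              patient_id = patient_id)
}

#' Write a mask or voxel map as NIfTI
#'
#' @param map A `lesion_mask`, 3-D array, or `voxel_stat_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size for plain arrays.
#' @return The path, invisibly.
#' @export
write_map <- function(map, path, voxel_size_mm = NULL) {
  if (inherits(map, "voxel_stat_map")) {
    arr <- as_volume(map)
    vs <- map$voxel_size_mm
  } else if (inherits(map, "lesion_mask")) {
    arr <- map$data
    vs <- map$voxel_size_mm
  } else {
    arr <- map
    vs <- voxel_size_mm %||% 1
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, rep(vs, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel-wise lesion overlap map
#'
#' Sums binary masks voxel by voxel; the count at a voxel is the number of
#' contributing lesions covering it.
#'
#' @param masks List of `lesion_mask` (or arrays) on a shared grid.
#' @return Integer 3-D array with attribute `n_masks`.
#' @export
overlap_map <- function(masks) {
  assert_that(length(masks) >= 1, "invalid input: need at least one mask")
  check_shared_grid(masks)
  out <- Reduce(`+`, lapply(masks, mask_array))
  attr(out, "n_masks") <- length(masks)
  out
}

#' Composite overlap of task-wise impairment maps
#'
#' For each task, the overlap of the lesions of patients impaired on that
#' task is binarized (voxel present iff covered by at least
#' `min_patients_per_task` lesions), then the binarized maps are summed
#' across tasks. The value at a voxel is the number of tasks whose
#' impairment-associated lesion territory includes it.
#'
#' @param per_task_masks Named list: task -> list of masks (possibly empty).
#' @param grid_shape Grid dimensions, required if every task list is empty.
#' @param min_patients_per_task Binarization count per task.
#' @return Integer 3-D array with attribute `n_tasks`.
#' @export
task_overlap_composite <- function(per_task_masks, grid_shape = NULL,
                                   min_patients_per_task = 1L) {
  nonempty <- Filter(function(m) length(m) > 0, per_task_masks)
  if (length(nonempty) == 0) {
    assert_that(!is.null(grid_shape),
                "invalid input: grid_shape needed when all task lists are empty")
    out <- array(0L, dim = grid_shape)
    attr(out, "n_tasks") <- length(per_task_masks)
    return(out)
  }
  check_shared_grid(unlist(nonempty, recursive = FALSE))
  shape <- dim(mask_array(nonempty[[1]][[1]]))
  out <- array(0L, dim = shape)
  for (masks in per_task_masks) {
    if (length(masks) == 0) next
    out <- out + (overlap_map(masks) >= min_patients_per_task)
  }
  out <- array(as.integer(out), dim = shape)
  attr(out, "n_tasks") <- length(per_task_masks)
  out
}

#' Exclusive multi- vs single-domain lesion sites
#'
#' The multi-domain site is the union of the multi-impairment lesions minus
#' every voxel also covered by the comparison (single/no impairment)
#' lesions, and vice versa; voxels lesioned in both patient groups are
#' excluded from both sites. The two outputs are disjoint by construction.
#'
#' @param multi_masks Masks of patients with multi-domain impairment.
#' @param single_masks Masks of patients with single-domain or no impairment.
#' @param voxel_size_mm Voxel size of the output site masks.
#' @return List with `multi_site` and `single_site` (`lesion_mask`, possibly
#'   empty with a warning) and logical `empty_output`.
#' @export
exclusive_site_contrast <- function(multi_masks, single_masks,
                                    voxel_size_mm = NULL) {
  assert_that(length(multi_masks) >= 1 && length(single_masks) >= 1,
              "invalid input: both groups need at least one mask")
  check_shared_grid(c(multi_masks, single_masks))
  vs <- voxel_size_mm %||%
    (if (inherits(multi_masks[[1]], "lesion_mask")) multi_masks[[1]]$voxel_size_mm else 1)
  u_multi <- overlap_map(multi_masks) >= 1
  u_single <- overlap_map(single_masks) >= 1
  multi_site <- u_multi & !u_single
  single_site <- u_single & !u_multi
  empty <- sum(multi_site) == 0 || sum(single_site) == 0
  if (empty) {
    warning("exclusive site contrast produced an empty site; downstream contrasts need both",
            call. = FALSE)
  }
  list(multi_site = lesion_mask(multi_site, vs, "multi_site", allow_empty = TRUE),
       single_site = lesion_mask(single_site, vs, "single_site", allow_empty = TRUE),
       empty_output = empty)
}

#' Lesion volume in mm^3
#'
#' @param mask A `lesion_mask` (or array with `voxel_size_mm`).
#' @param voxel_size_mm Voxel size for plain arrays.
#' @return Voxel count times voxel volume.
#' @export
lesion_volume <- function(mask, voxel_size_mm = NULL) {
  vs <- if (inherits(mask, "lesion_mask")) mask$voxel_size_mm else voxel_size_mm %||% 1
  sum(mask_array(mask)) * vs^3
}

#' Overlap of a lesion with an atlas parcellation
#'
#' Tabulates the lesion's voxels by atlas label (0 = background, excluded
#' from percentages), reporting per-label counts, the percentage of lesioned
#' voxels in each label, and how many labels are hit.
#'
#' @param mask A `lesion_mask` or binary array.
#' @param atlas Integer label array on the same grid.
#' @param labels Optional data frame `label`, `name` for naming.
#' @return List with data frame `table` (label, name, n_voxels,
#'   pct_of_lesion) and `labels_hit`.
#' @export
atlas_overlap <- function(mask, atlas, labels = NULL) {
  arr <- mask_array(mask)
  check_shared_grid(list(arr, atlas))
  assert_that(all(atlas >= 0), "invalid input: atlas labels must be non-negative")
  n_lesion <- sum(arr)
  hit <- atlas[arr > 0]
  hit <- hit[hit > 0]
  tab <- table(hit)
  df <- data.frame(label = as.integer(names(tab)),
                   n_voxels = as.integer(tab),
                   pct_of_lesion = 100 * as.integer(tab) / n_lesion)
  if (!is.null(labels)) {
    df$name <- labels$name[match(df$label, labels$label)]
    df <- df[, c("label", "name", "n_voxels", "pct_of_lesion")]
  }
  df <- df[order(-df$n_voxels), , drop = FALSE]
  rownames(df) <- NULL
  list(table = df, labels_hit = nrow(df))
}

#' Dice coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; symmetric, in \[0, 1\].
#'
#' @param mask_a,mask_b Non-empty binary masks on a shared grid.
#' @return Numeric scalar.
#' @export
dice <- function(mask_a, mask_b) {
  a <- mask_array(mask_a) > 0
  b <- mask_array(mask_b) > 0
  check_shared_grid(list(a, b))
  assert_that(sum(a) > 0 && sum(b) > 0,
              "invalid input: Dice undefined for an empty mask")
  2 * sum(a & b) / (sum(a) + sum(b))
}
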