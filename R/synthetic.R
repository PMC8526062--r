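#' Synthetic lesion-cohort generator
#'
#' Generates every input the analysis pipeline consumes — ROI partition,
#' normative connectome cohort, patient lesion cohort, neuropsychological
#' scores, and a two-gene expression gradient — with planted, recoverable
#' hub structure: connectivity spread (hence PC) peaks at a configured hub
#' site, lesions overlapping the hub induce deficits across several
#' cognitive domains while control-site lesions hit one domain, and the
#' calbindin-like gene expression gradient peaks at the hub pole.
#'
#' @name synthetic_cohort
NULL

# Coordinates (1-based, n x 3) of the n_thal_voxels grid voxels nearest the
# grid centre: a compact ellipsoidal blob standing in for the thalamus.
thalamus_coords <- function(config) {
  gs <- config$grid_shape
  coords <- as.matrix(expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]),
                                  z = seq_len(gs[3])))
  ctr <- (gs + 1) / 2
  d2 <- colSums((t(coords) - ctr)^2)
  idx <- order(d2)[seq_len(config$n_thal_voxels)]  # ties broken by index
  out <- coords[idx, , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Planted hub gradient over the thalamic voxels
#'
#' A Gaussian bump centred on the hub site: `g(v) = exp(-d^2 / (2 r^2))`
#' with d the Euclidean voxel distance to `hub_center` and r = `hub_radius`.
#' g lies in (0, 1], peaks at the hub, and decays monotonically with
#' distance, so the analytic PC planted through it is monotone in hub
#' proximity.
#'
#' @param config A `simulation_config`.
#' @param coords Thalamic voxel coordinates (defaults to the config's grid).
#' @return Numeric vector in (0, 1], one value per thalamic voxel.
#' @export
hub_gradient <- function(config, coords = thalamus_coords(config)) {
  d2 <- colSums((t(coords) - config$hub_center)^2)
  exp(-d2 / (2 * config$hub_radius^2))
}

# Binary hub-site mask: thalamic voxels within hub_radius of hub_center.
hub_site_mask <- function(config, coords = thalamus_coords(config)) {
  d2 <- colSums((t(coords) - config$hub_center)^2)
  arr <- array(0L, dim = config$grid_shape)
  arr[coords[d2 <= config$hub_radius^2, , drop = FALSE]] <- 1L
  lesion_mask(arr, config$voxel_size_mm, "hub_site")
}

#' Generate a random ROI-to-network partition
#'
#' Assigns `n_rois` cortical ROIs to `n_networks` functional networks with
#' near-balanced sizes; every network is non-empty, and the assignment is
#' deterministic given the seed. With 7 networks the canonical resting-state
#' network names are used.
#'
#' @param n_rois Number of ROIs (>= n_networks).
#' @param n_networks Number of networks.
#' @param seed Optional seed.
#' @return A [network_partition()].
#' @export
generate_partition <- function(n_rois, n_networks, seed = NULL) {
  assert_that(is_count(n_rois) && is_count(n_networks),
              "invalid config: counts must be positive integers")
  assert_that(n_rois >= n_networks,
              "invalid config: n_rois (%d) < n_networks (%d)", n_rois, n_networks)
  names7 <- c("VIS", "SM", "DA", "CO", "LM", "FP", "DMN")
  nets <- if (n_networks == 7) names7 else paste0("N", seq_len(n_networks))
  membership <- with_seed(seed, {
    sample(rep(seq_len(n_networks), length.out = n_rois))
  })
  network_partition(membership, nets)
}

#' Generate a cohort of synthetic thalamocortical connectivity matrices
#'
#' Each thalamic voxel gets a home network; its expected connectivity weight
#' to the home network is proportional to `(1 - g) + g/NM` and to each other
#' network to `g/NM`, where g is the planted hub gradient: at g = 0 all
#' weight sits in the home network (analytic PC 0), at g = 1 the weight is
#' uniform across networks (analytic PC 1 - 1/NM). Network-level weight is
#' split equally among the network's ROIs, and independent Gaussian edge
#' noise (truncated at zero, so weights stay non-negative) is added per
#' subject.
#'
#' @param config A `simulation_config`.
#' @param g Hub gradient in \[0, 1\] over the thalamic voxels.
#' @param partition A `network_partition` over the config's ROIs.
#' @param coords Thalamic voxel coordinates.
#' @param seed Optional seed.
#' @return List of voxel x ROI matrices (one per subject), each carrying
#'   attributes `subject_id` and `voxel_coords`; the list carries
#'   `home_network`.
#' @export
generate_connectome_cohort <- function(config, g = hub_gradient(config),
                                       partition = generate_partition(
                                         config$n_rois, config$n_networks),
                                       coords = thalamus_coords(config),
                                       seed = NULL) {
  assert_that(length(g) == nrow(coords),
              "invalid config: gradient not defined on all thalamic voxels")
  assert_that(all(g >= 0 & g <= 1), "invalid config: gradient must lie in [0, 1]")
  nm <- partition$n_networks
  net_size <- tabulate(partition$membership, nm)
  with_seed(seed, {
    home <- sample.int(nm, length(g), replace = TRUE)
    # expected voxel x network weight, then split equally across ROIs
    w_net <- matrix(g / nm, nrow = length(g), ncol = nm)
    w_net[cbind(seq_along(g), home)] <- (1 - g) + g / nm
    base <- (w_net / rep(net_size, each = length(g)))[, partition$membership]
    cohort <- lapply(seq_len(config$n_subjects), function(s) {
      W <- base
      if (config$fc_noise_sd > 0) {
        W <- pmax(W + matrix(stats::rnorm(length(W), 0, config$fc_noise_sd),
                             nrow = nrow(W)), 0)
      }
      attr(W, "subject_id") <- sprintf("sub-%03d", s)
      attr(W, "voxel_coords") <- coords
      W
    })
    attr(cohort, "home_network") <- home
    cohort
  })
}

# n nearest thalamic voxels to `center` (connected blob inside the thalamus).
grow_lesion <- function(coords, center, n_vox) {
  d2 <- colSums((t(coords) - center)^2)
  coords[order(d2)[seq_len(n_vox)], , drop = FALSE]
}

# Control lesion sites: scattered over the low-gradient half of the
# thalamus (away from the hub) by deterministic farthest-point sampling, so
# sites are well separated. Each site stands for one domain-specific
# thalamocortical system.
control_centers <- function(config, coords, g = hub_gradient(config, coords)) {
  candidates <- which(g <= stats::quantile(g, 0.5))
  assert_that(length(candidates) >= config$n_control_sites,
              "invalid config: too few low-gradient voxels for %d control sites",
              config$n_control_sites)
  cand <- coords[candidates, , drop = FALSE]
  chosen <- which.min(g[candidates])      # farthest from the hub
  while (length(chosen) < config$n_control_sites) {
    d2min <- rep(Inf, nrow(cand))
    for (j in chosen) {
      d2 <- colSums((t(cand) - cand[j, ])^2)
      d2min <- pmin(d2min, d2)
    }
    d2min[chosen] <- -Inf
    chosen <- c(chosen, which.max(d2min))
  }
  lapply(chosen, function(j) cand[j, ])
}

#' Generate a cohort of binary lesion masks
#'
#' A fraction `hub_fraction` of patients get lesions grown at the hub site
#' (centre jittered by up to one voxel); the rest are assigned round-robin
#' to scattered control sites far from the hub, and their lesions spare the
#' hub site by construction. Each lesion is the target number of thalamic
#' voxels nearest its centre — a connected blob with the exact target
#' volume, drawn uniformly from `lesion_size_range`.
#'
#' @param config A `simulation_config`.
#' @param coords Thalamic voxel coordinates.
#' @param seed Optional seed.
#' @return List with `masks` (list of `lesion_mask`), `info` (data frame:
#'   patient_id, group, site, volume_mm3), `control_sites` (list of centre
#'   coordinates).
#' @export
generate_lesion_cohort <- function(config, coords = thalamus_coords(config),
                                   seed = NULL) {
  vs3 <- config$voxel_size_mm^3
  n_min <- ceiling(config$lesion_size_range[1] / vs3)
  n_max <- floor(config$lesion_size_range[2] / vs3)
  assert_that(n_max >= 1 && n_min <= n_max,
              "invalid config: lesion_size_range holds no whole voxel count")
  assert_that(n_max <= nrow(coords),
              "invalid config: requested lesion volume exceeds grid capacity")
  n_hub <- round(config$n_patients * config$hub_fraction)
  ctrl_centers <- control_centers(config, coords)
  # control lesions spare the hub site by construction (they emulate patients
  # whose damage lies in domain-specific territory, not the hub)
  hub_arr <- hub_site_mask(config, coords)$data
  ctrl_coords <- coords[hub_arr[coords] == 0, , drop = FALSE]
  assert_that(nrow(ctrl_coords) >= n_max,
              "invalid config: requested lesion volume exceeds non-hub capacity")
  with_seed(seed, {
    masks <- vector("list", config$n_patients)
    info <- data.frame(patient_id = sprintf("pat-%03d", seq_len(config$n_patients)),
                       group = character(config$n_patients),
                       site = character(config$n_patients),
                       volume_mm3 = numeric(config$n_patients),
                       stringsAsFactors = FALSE)
    for (i in seq_len(config$n_patients)) {
      if (i <= n_hub) {
        center <- config$hub_center
        info$group[i] <- "hub"
        info$site[i] <- "hub"
      } else {
        j <- (i - n_hub - 1) %% length(ctrl_centers) + 1
        center <- ctrl_centers[[j]]
        info$group[i] <- "control"
        info$site[i] <- sprintf("control-%d", j)
      }
      center <- center + stats::runif(3, -1, 1)
      n_vox <- round(stats::runif(1, config$lesion_size_range[1],
                                  config$lesion_size_range[2]) / vs3)
      n_vox <- min(max(n_vox, n_min), n_max)
      vox <- if (info$group[i] == "hub") {
        grow_lesion(coords, center, n_vox)
      } else {
        grow_lesion(ctrl_coords, center, n_vox)
      }
      arr <- array(0L, dim = config$grid_shape)
      arr[vox] <- 1L
      masks[[i]] <- lesion_mask(arr, config$voxel_size_mm, info$patient_id[i])
      info$volume_mm3[i] <- n_vox * vs3
    }
    list(masks = masks, info = info, control_sites = ctrl_centers)
  })
}

# Fraction of a lesion's voxels inside a site mask.
overlap_fraction <- function(mask, site) {
  a <- mask_array(mask)
  s <- mask_array(site)
  sum(a & s) / sum(a)
}

#' Generate neuropsychological z-scores with planted lesion effects
#'
#' Patients whose lesions overlap the hub site receive an oriented-score
#' effect of `-beta * overlap_fraction` on every loaded test — the tests of
#' the executive, verbal, and memory domains (three domains, five tests) —
#' emulating multi-domain impairment from hub damage. Control patients
#' receive the same-sized effect on the tests of a single domain (cycled
#' across control patients), scaled by overlap with their own control site.
#' Gaussian noise with SD `noise_sd` is added to every score, and tests
#' flagged `invert` in the battery are stored in their raw (flipped)
#' direction, so the table must pass through [orient_scores()] like real
#' data.
#'
#' @param lesions Output of [generate_lesion_cohort()].
#' @param hub_site Hub-site mask (from the config geometry).
#' @param config A `simulation_config`.
#' @param battery A `test_battery`.
#' @param coords Thalamic voxel coordinates.
#' @param seed Optional seed.
#' @return Raw score table (data frame: patient_id, group,
#'   lesion_volume_mm3, one column per test) with attribute `truth` holding
#'   the planted per-patient effects.
#' @export
generate_neuropsych_scores <- function(lesions, hub_site, config,
                                       battery = test_battery(),
                                       coords = thalamus_coords(config),
                                       seed = NULL) {
  check_shared_grid(c(lesions$masks, list(hub_site)))
  info <- lesions$info
  n <- nrow(info)
  loaded_domains <- c("executive", "verbal", "memory")
  all_domains <- unique(battery$domain)
  ctrl_sites <- lapply(lesions$control_sites, function(cc) {
    d2 <- colSums((t(coords) - cc)^2)
    arr <- array(0L, dim = config$grid_shape)
    arr[coords[d2 <= config$hub_radius^2, , drop = FALSE]] <- 1L
    arr
  })
  with_seed(seed, {
    effects <- matrix(0, nrow = n, ncol = nrow(battery),
                      dimnames = list(info$patient_id, battery$test))
    ov <- numeric(n)
    target_domain <- character(n)
    for (i in seq_len(n)) {
      if (info$group[i] == "hub") {
        ov[i] <- overlap_fraction(lesions$masks[[i]], hub_site)
        tests <- battery$test[battery$domain %in% loaded_domains]
        target_domain[i] <- paste(loaded_domains, collapse = "+")
      } else {
        # each control site stands for one domain-specific system
        j <- as.integer(sub("control-", "", info$site[i]))
        ov[i] <- overlap_fraction(lesions$masks[[i]], ctrl_sites[[j]])
        dom <- all_domains[(j - 1L) %% length(all_domains) + 1L]
        tests <- battery$test[battery$domain == dom]
        target_domain[i] <- dom
      }
      effects[i, tests] <- -config$effect_size_beta * ov[i]
    }
    oriented <- effects
    if (config$noise_sd > 0) {
      oriented <- oriented + matrix(stats::rnorm(length(effects), 0, config$noise_sd),
                                    nrow = n)
    }
    raw <- oriented
    for (tst in battery$test[battery$invert]) raw[, tst] <- -raw[, tst]
    out <- data.frame(patient_id = info$patient_id, group = info$group,
                      lesion_volume_mm3 = info$volume_mm3,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(raw))
    rownames(out) <- NULL
    attr(out, "oriented") <- FALSE
    attr(out, "truth") <- data.frame(patient_id = info$patient_id,
                                     hub_overlap = ov,
                                     target_domain = target_domain,
                                     planted_effect = -config$effect_size_beta * ov,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Generate complementary two-gene expression gradients
#'
#' Gene A (calbindin-like) increases and gene B (parvalbumin-like) decreases
#' monotonically along the configured gradient axis, oriented so the gene-A
#' pole coincides with the hub site; with `expression_noise_sd = 0` the two
#' raw gradients sum to a constant field.
#'
#' @param config A `simulation_config`.
#' @param coords Thalamic voxel coordinates.
#' @param seed Optional seed.
#' @return List with `geneA` and `geneB` raw-expression `voxel_stat_map`s.
#' @export
generate_expression_maps <- function(config, coords = thalamus_coords(config),
                                     seed = NULL) {
  axis <- config$gene_gradient_axis
  assert_that(axis <= ncol(coords), "invalid config: gradient axis outside grid")
  x <- coords[, axis]
  t_axis <- (x - min(x)) / max(max(x) - min(x), 1)
  ctr <- mean(x)
  if (config$hub_center[axis] < ctr) t_axis <- 1 - t_axis
  with_seed(seed, {
    noise <- function() {
      if (config$expression_noise_sd > 0) {
        stats::rnorm(length(t_axis), 0, config$expression_noise_sd)
      } else 0
    }
    geneA <- voxel_stat_map(t_axis + noise(), coords, config$grid_shape,
                            config$voxel_size_mm, statistic = "expression",
                            provenance = list(gene = "CALB1-like"))
    geneB <- voxel_stat_map((1 - t_axis) + noise(), coords, config$grid_shape,
                            config$voxel_size_mm, statistic = "expression",
                            provenance = list(gene = "PVALB-like"))
    list(geneA = geneA, geneB = geneB)
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator under one RNG stream seeded from `config$seed`, so
#' the whole cohort is reproducible from the config alone.
#'
#' @param config A `simulation_config`.
#' @return A `synthetic_cohort`: list with `config`, `coords`, `partition`,
#'   `gradient`, `hub_site`, `connectomes`, `lesions`, `scores`,
#'   `expression`, and `truth` (the planted gradient and per-patient effect
#'   record).
#' @export
generate_cohort <- function(config = simulation_config()) {
  with_seed(config$seed, {
    coords <- thalamus_coords(config)
    partition <- generate_partition(config$n_rois, config$n_networks)
    g <- hub_gradient(config, coords)
    hub_site <- hub_site_mask(config, coords)
    connectomes <- generate_connectome_cohort(config, g, partition, coords)
    lesions <- generate_lesion_cohort(config, coords)
    scores <- generate_neuropsych_scores(lesions, hub_site, config,
                                         coords = coords)
    expression <- generate_expression_maps(config, coords)
    structure(list(config = config, coords = coords, partition = partition,
                   gradient = g, hub_site = hub_site,
                   connectomes = connectomes, lesions = lesions,
                   scores = scores, expression = expression,
                   truth = list(gradient = g,
                                hub_center = config$hub_center,
                                patients = attr(scores, "truth"))),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Lesion masks, the hub-site mask and expression maps as NIfTI, scores as
#' TSV (`patient_id, group, lesion_volume_mm3, <test columns>`), the truth
#' record as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(dir, "lesions")
  dir.create(mask_dir, showWarnings = FALSE)
  for (m in cohort$lesions$masks) {
    write_map(m, file.path(mask_dir, paste0(m$patient_id, ".nii.gz")))
  }
  write_map(cohort$hub_site, file.path(dir, "hub_site.nii.gz"))
  write_map(cohort$expression$geneA, file.path(dir, "geneA.nii.gz"))
  write_map(cohort$expression$geneB, file.path(dir, "geneB.nii.gz"))
  utils::write.table(cohort$scores, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(hub_center = cohort$truth$hub_center,
                            gradient = cohort$truth$gradient,
                            patients = cohort$truth$patients),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
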