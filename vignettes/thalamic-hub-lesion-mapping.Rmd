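---
title: "Mapping multi-domain impairment to thalamic connector hubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping multi-domain impairment to thalamic connector hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Connector hubs are regions whose connectivity is spread across several
functional networks rather than concentrated in one. The thalamus contains
such hubs: subregions — notably the anterior-medio-dorsal territory — whose
voxels couple to frontoparietal, cingulo-opercular, default-mode and other
cortical networks at once. If a hub genuinely supports the interactions of
many systems, focal damage to it should impair behaviour across several
cognitive domains, whereas damage to a non-hub, domain-specific territory
should produce circumscribed deficits.

`thalamap` implements the full analysis that tests this prediction:

1. **Neuropsychology.** Ten standard tests (Trail Making A/B, Boston Naming,
   COWA, four RAVLT components, two Complex Figure trials), expressed as
   age-adjusted z-scores against published population norms, grouped into six
   domains (executive, verbal, memory, learning, psychomotor, visuospatial).
   A test is *impaired* when its oriented z lies strictly below −1.645, the
   normative 5th percentile. Patients are classed `none` / `single` / `multi`
   by the number of domains containing an impaired test. Group differences
   per test use randomized permutation tests with Bonferroni correction
   (ten tests, per-test threshold 0.005).
2. **Lesion geometry.** Binary masks on a common voxel grid: overlap maps
   per task, a task composite, and the *exclusive* site contrast — voxels
   lesioned only in multi-domain patients versus voxels lesioned only in
   single/no-impairment patients, with shared voxels excluded from both.
3. **Hub metrics.** From each normative subject's thalamus-voxel × cortical-ROI
   functional connectivity matrix, the participation coefficient
   PC = 1 − Σ_s (K_is / K_i)², computed after retaining the top fraction of
   positive weights at each of 15 graph densities (0.01–0.15) and averaging
   across densities, then across subjects. Site contrasts are run voxel-wise
   (two-sample Kolmogorov-Smirnov on PC values) and subject-wise (paired t on
   per-subject site means). Functional connectivity weight ratios
   (per-network strength over total strength) profile the selectivity of
   each voxel.
4. **Expression density.** Two gene-expression maps — calbindin-like (CALB1,
   marking diffusely-projecting matrix cells) and parvalbumin-like (PVALB,
   marking topographically-projecting core cells) — z-scored within the
   thalamus, contrasted between sites by KS, differenced voxel-wise, and
   compared with site masks by Dice after binarizing at z > 0.

The real inputs of such a study (clinical lesion masks, large normative
fMRI cohorts, Allen-atlas expression volumes) are restricted or large, so
the package ships a synthetic-cohort generator with planted, recoverable
structure, and the whole pipeline is validated by parameter recovery.

## The synthetic cohort and its reference conditions

`simulation_config()` fixes the study conditions; its defaults are the
reference configuration used throughout the tests:

* a 14×14×14 grid at 2 mm isotropic resolution, with the **thalamus** as the
  500 voxels nearest the grid centre (4000 mm³);
* **100 cortical ROIs** in **7 networks**, near-balanced, named after the
  canonical resting-state networks;
* a **hub site** of radius 4 voxels (8 mm) centred at half the thalamus
  radius along the gradient axis — deep enough that the sphere is not
  clipped away by the organ boundary;
* a planted **hub gradient** g(v) = exp(−d²/2r²) (d = distance to the hub
  centre, r = hub radius). Each voxel's expected connectivity to its home
  network is ∝ (1−g) + g/NM and to every other network ∝ g/NM, so the
  analytic PC rises monotonically from 0 (g = 0) to 1 − 1/NM (g = 1);
* **30 normative subjects**, each the expected matrix plus independent
  Gaussian edge noise truncated at zero. The noise SD (0.005) is about half
  the weakest planted per-edge weight ((1/7)/14 ≈ 0.01): measurement noise
  that blurs but does not drown the structure;
* **40 patients**, half with lesions at the hub, half scattered over 12
  control sites placed in the low-gradient half of the thalamus by
  farthest-point sampling, each site standing for one domain-specific
  system; control lesions spare the hub site by construction. Lesion
  volumes are uniform on 60–250 mm³, chosen so the cohort's summed lesion
  volume is about 1.5× the organ volume — the same total-coverage regime as
  a published thalamic cohort (20 lesions of mean 1364 mm³ on a
  2227-voxel, ~17,800 mm³ thalamus). The exclusive site construction
  depends directly on this ratio: at much higher coverage the lesion unions
  tile the organ and the set differences collapse. Lesions are grown as the
  target number of in-organ voxels nearest a jittered centre: connected,
  exactly volume-controlled;
* **behaviour**: hub patients receive an oriented-score shift of
  −β · overlap-fraction on the five tests of the executive, verbal and
  memory domains (β = 3 z-units); each control patient receives the same
  shift on the tests of their site's single domain; all scores get
  N(0, 1) noise. Trail-making scores are stored in their raw (inverted)
  direction so the data must pass through score orientation like real data;
* **expression**: gene A rises and gene B falls linearly along the gradient
  axis (plus N(0, 0.1) noise), with the gene-A pole at the hub, emulating
  the anterior-posterior matrix/core gradient.

What the generator deliberately does *not* emulate: fMRI time-series
autocorrelation and preprocessing artefacts, registration error, irregular
lesion shapes, correlated noise across tests, and inter-subject anatomical
variability. Passing recovery tests therefore shows the analysis machinery
is correct and sensitive under clean planted structure — not that the
clinical effect sizes would be attainable in real data.

## Numerical and design choices

* **Permutation tests** are two-sided on the mean difference. When the
  number of distinct label assignments is ≤ 20,000 the null is enumerated
  exhaustively and p is exact (unit-test-sized problems); otherwise p uses
  the add-one estimator (1 + c)/(1 + n_perm), which is positive by
  construction and counts the observed labelling in the null.
* **KS p-values** use the asymptotic two-sample approximation; the voxel
  samples routinely contain ties, where the exact method is unavailable
  anyway. The D statistic is checked in the tests against a brute-force
  ECDF supremum oracle.
* **Density thresholding** removes negative correlations first — the PC
  formulation used here is defined for non-negative weights — and retains
  the top `floor(density · E)` positive entries of the whole matrix
  (E = all entries), matching a whole-matrix reading of density. Ties at
  the cutoff break deterministically by entry order. The density grid is 15
  evenly spaced values on 0.01–0.15; thresholding is per subject, before
  averaging, since per-subject maps are averaged afterwards.
* **Zero-strength voxels** (all weights removed at a harsh threshold) get
  PC = 0 with a QC flag rather than NaN, keeping maps complete for masking.
* **Multi-domain classification** uses impaired-domain count ≥ 2
  (configurable via `multi_domain_min_domains`): the analysis contrasts
  "one versus multiple" domains. The multi-domain impairment *score* counts
  impaired tests (0–10), with a domain-counting variant available, and the
  impairment cutoff is z < −1.645 on oriented scores (negative = worse)
  throughout.
* **Lesion-size adjustment** regresses scores on raw volume by OLS; no
  volume transform is applied. Residuals are exactly orthogonal to volume.
* **Correlation df**: clinical reports sometimes quote r(n−1); the Pearson
  helper reports the conventional df = n − 2 inference and the n − 1
  variant side by side rather than guessing intent.
* **Expression**: z-scoring uses the sample SD (n−1). The Dice comparison
  binarizes the normalized CALB1-like map at z > 0 by default (threshold
  configurable); the CALB1−PVALB difference map is also available for
  binarization if preferred.
* **Missing scores** abort composite scoring unless `allow_missing = TRUE`
  (mean over available tests); there is no silent imputation.
* **Reproducibility**: one RNG stream per cohort seeded from the config;
  every sub-generator also accepts its own seed. Derived seeds in the
  pipeline are small offsets of the config seed. The same config yields a
  byte-identical report.

## What the recovery analysis shows

On the reference configuration, the pipeline (i) classifies essentially all
hub-overlap patients as multi-domain while control patients are mostly
single-domain (with an expected ~1/3 of them crossing into `multi` through
chance flags — ten tests at a 5% cutoff under unit score noise); (ii)
builds non-empty exclusive sites whose PC distributions separate sharply in
the planted direction, both voxel-wise and subject-wise; and (iii) finds
higher calbindin-like expression in the multi-domain site with the Dice
asymmetry in the planted direction. The acceptance script
(`scripts/acceptance.R`) recomputes these quantities from scratch, plus a
200-replicate null calibration in which the per-test permutation rejection
rate at α = 0.05 must stay inside its binomial 99% band. Problem sizes
(500 voxels, 30 subjects, 200 null replicates with 499 permutations per
test) are chosen so the whole analysis runs in minutes on one CPU while
leaving the planted contrasts far from marginal.

## Limitations

The voxel grid is small and the organ a sphere-like blob; boundary effects
of real thalamic anatomy (nuclei shapes, left/right asymmetry) are absent.
The KS p-value is asymptotic and anti-conservative for very small sites.
Exclusive site construction is sensitive to misclassification when lesions
are large relative to the organ or control sites are few and co-located —
the generator defaults avoid this regime, and real analyses should check
site sizes before interpreting contrasts. The whole-brain grey-matter PC
variant is supported at the contract level (any voxel × ROI matrix with
appended subcortical labels) but is not exercised at realistic scale.
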