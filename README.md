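# thalamap

Lesion-network mapping of thalamic connector hubs: a tested R pipeline that
links *where* a focal thalamic lesion sits to *how broadly* it impairs
cognition.

## The problem

The thalamus is not a relay with one job per nucleus. Parts of it — the
anterior-medio-dorsal territory in particular — behave as **connector
hubs**: their functional connectivity is spread across several cortical
networks (frontoparietal, cingulo-opercular, default-mode, …) rather than
concentrated in one. The hub hypothesis predicts that damage to such a
region should impair behaviour across *multiple* cognitive domains, while
damage to a domain-specific territory should produce a circumscribed
deficit.

`thalamap` implements the complete analysis that tests this prediction, for
researchers working with lesion cohorts and normative connectomes:

* **Neuropsychological scoring** — ten standard tests (Trail Making A/B,
  Boston Naming, COWA, four RAVLT components, two Complex Figure trials) as
  age-adjusted z-scores, oriented so negative = impaired, grouped into six
  cognitive domains. A test is impaired when z < −1.645 (the normative 5th
  percentile); patients are classed `none`/`single`/`multi` by the number
  of impaired domains. Group contrasts use randomized permutation tests
  (exact by enumeration on small problems) with Bonferroni correction.
* **Lesion geometry** — NIfTI mask I/O, task-wise overlap maps and their
  composite, lesion volumes, atlas-parcellation overlap percentages, Dice,
  and the **exclusive site contrast**: voxels lesioned only in multi-domain
  patients vs only in single/no-impairment patients.
* **Hub metrics** — from each subject's thalamus-voxel × cortical-ROI
  connectivity matrix, the **participation coefficient**

  PC_i = 1 − Σ_s (K_is / K_i)²,

  where K_i is voxel i's total positive connectivity weight and K_is its
  weight into network s: 0 when all weight sits in one network, up to
  1 − 1/NM when spread uniformly over NM networks. PC is computed after
  density thresholding (top fraction of positive weights, 15 densities over
  0.01–0.15), averaged across densities and subjects, and contrasted
  between lesion sites voxel-wise (Kolmogorov-Smirnov) and subject-wise
  (paired t). Functional connectivity **weight ratios** (per-network weight
  over total weight) profile each voxel's network selectivity.
* **Expression density** — calbindin-like (CALB1, matrix cells) and
  parvalbumin-like (PVALB, core cells) expression maps z-scored within the
  thalamus, contrasted between sites, differenced voxel-wise, and compared
  with site masks by Dice.
* **Synthetic cohort** — the real inputs of such a study are restricted
  (clinical lesion masks) or heavy (normative fMRI cohorts), so
  `generate_cohort()` plants a recoverable hub: a connectivity-spread
  gradient peaking at a hub site, hub lesions that impair three domains,
  scattered control lesions that impair one, and a complementary two-gene
  expression gradient. Everything is reproducible from a single seed.

## Worked example

```r
library(thalamap)

cfg <- simulation_config(seed = 1)   # the reference study conditions
report <- run_pipeline(cfg)          # simulate + analyse end to end
print(report)
```

```
thalamap pipeline report (seed 1 )
  patients: 32 multi / 8 single / 0 none
  group comparison: 5/10 tests significant at Bonferroni 0.005
  sites: multi 205 voxels, single 46 voxels
  PC contrast: KS d = 0.582 (p = 1.81e-11), paired t(29) = 112.65 (p = 7.2e-40)
  CALB1-like contrast: KS d = 0.603; Dice multi 0.560 vs single 0.013
```

Reading the output: all 20 hub-lesion patients (and 12 controls, through
chance flags) are classified multi-domain; exactly the five loaded tests —
executive, verbal and memory — separate the groups at the Bonferroni
threshold:

```r
report$neuropsych$group_comparison[, c("test", "mean_a", "mean_b", "p_value", "significant")]
#>                        test mean_a mean_b p_value significant
#> 2                     TMT_B -3.194 -0.966  0.0005        TRUE
#> 3                       BNT -2.842 -0.298  0.0005        TRUE
#> 4                      COWA -3.304 -0.486  0.0005        TRUE
#> 7      RAVLT_Delayed_Recall -2.874 -0.345  0.0005        TRUE
#> 8 RAVLT_Delayed_Recognition -3.465 -0.799  0.0005        TRUE
#> ... (TMT_A, learning and visuospatial tests not significant)
```

The exclusive multi-domain site (205 voxels at the planted hub) has sharply
higher participation coefficients than the single-domain site (46 scattered
voxels): KS d = 0.58 voxel-wise, and the per-subject site means differ with
t(29) = 112.7. The calbindin-like expression map is higher in the
multi-domain site (KS d = 0.60) and its above-average territory overlaps
the multi-domain site (Dice 0.56) but not the single-domain site (0.013) —
the planted matrix/core gradient, recovered.

`run_pipeline(cfg, out_dir = "run1")` additionally writes the cohort
(NIfTI masks and maps, TSV scores), the PC and expression maps, the site
masks, per-patient profiles and a JSON report.

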