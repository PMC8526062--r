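Package: thalamap
Title: Lesion-Network Mapping of Thalamic Connector Hubs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking focal thalamic lesion sites to
    multi-domain neuropsychological impairment through connector-hub metrics
    of the thalamocortical functional connectome. Implements impairment
    flagging and domain classification of age-adjusted neuropsychological
    z-scores, lesion-mask geometry (overlap maps, exclusive site contrasts,
    atlas overlap, Dice), voxel-wise participation coefficients across graph
    density thresholds, functional connectivity weight-ratio selectivity
    profiles, and two-gene (calbindin/parvalbumin-like) expression-density
    contrasts, together with permutation, bootstrap, and Kolmogorov-Smirnov
    resampling kernels. A synthetic-cohort generator with planted,
    recoverable hub structure stands in for restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
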