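Package: cardiohub
Title: Cardiac Amplitude Signatures and Voxel-Wise Brain Network Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links a 12-lead electrocardiogram amplitude signature (the Ekappa
    score, built from the T- and RS-wave amplitudes of lead aVL, the R-wave of
    lead III and the maximal chest-lead RS excursion) and NEO personality
    scores to functional and structural brain maps. Provides seeded generators
    for synthetic 12-lead ECG cohorts, epoch-designed BOLD-like 4D series and
    modulated grey-matter maps with known ground truth; an ECG pipeline (beat
    detection, artifact-free averaging, amplitude measurement, Ekappa scoring);
    eigenvector centrality mapping of voxel similarity graphs by matrix-free
    power iteration after discrete-cosine high-pass filtering and Gaussian
    spatial smoothing; and second-level voxel-wise inference with nuisance
    covariates, Monte Carlo cluster-extent/cluster-mass familywise-error
    correction, uncorrected extent-thresholded maps and permutation-based
    small-volume correction, plus phenotype-level normality gating,
    median-split dichotomization and Bonferroni-corrected directed group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
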