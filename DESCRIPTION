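Package: radscan
Title: Radiome-Wide Association Scanning of Somatic Gene Burdens in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking 3D radiomic tumor phenotypes to somatic
    mutation profiles in small oncology cohorts. Implements IBSI-style
    radiomic feature extraction from volumetric images (first-order,
    shape, GLCM, GLRLM, GLSZM, NGTDM and GLDM texture features under
    original, Laplacian-of-Gaussian and undecimated wavelet filters),
    somatic-variant gene-burden construction with consequence and
    significance filters, a variance-component (SKAT-type) score test
    between every gene and every radiomic feature with
    mixture-of-chi-square p-values and Benjamini-Hochberg adjustment,
    feature-heterogeneity summaries with recursive correlation pruning,
    Kaplan-Meier/log-rank carrier survival comparison, and a synthetic
    tumor-cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    survival,
    RNifti,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
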