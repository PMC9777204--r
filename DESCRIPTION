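Package: ramanclass
Title: Chemometric Classification of Serum Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end chemometric analysis of biofluid Raman spectra:
    plain-text spectral input/output, rubber-band (lower convex hull)
    baseline correction and vector normalisation over the biological
    fingerprint region, PCA-LDA and PLS-DA classification, cluster-vector
    discovery of discriminatory wavenumbers, Monte Carlo cross-validation
    with accuracy/sensitivity/specificity reporting, a synthetic serum
    cohort generator for method evaluation, and summary statistics for
    anti-dsDNA (ELIA/CLIFT) clinical audit tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
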