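Package: nmrmet
Title: Serum 1H-NMR Metabolomics: Binning, OPLS-DA and Biomarker ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for serum 1H-NMR metabolomics of
    colorectal polyp and colorectal cancer cohorts. Simulates CPMG-style serum
    spectra from a packaged 23-metabolite reference table, bins spectra into
    uniform ppm buckets with water-region exclusion and total-intensity
    normalization, fits PCA, PLS-DA and OPLS-DA latent-variable models with
    stratified cross-validation, response permutation testing and CV-ANOVA,
    identifies differential metabolites by VIP and correlation-loading
    thresholds with fold-change tables, and ranks candidate biomarkers by
    Monte-Carlo multivariate ROC analysis and metabolite-ratio diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
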