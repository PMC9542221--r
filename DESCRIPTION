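Package: synthrs
Title: Physics-Constrained Synthetic MRI for Radiomics-Based Glioblastoma
    Survival Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised synthesis of missing MR weighted contrasts
    (FLAIR, T2w) from acquired ones through quantitative relaxometry maps
    (T1, T2, PD) and closed-form spin-echo / inversion-recovery signal
    equations, together with a radiomics-based classifier of glioblastoma
    survival (more or less than 480 days) and a replacement-evaluation
    protocol comparing acquired, synthesized and absent input channels.
    Includes a seeded generator of brain-like relaxometry phantoms with
    tumor sub-regions and survival metadata so the whole pipeline can be
    exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    e1071,
    xgboost,
    ranger,
    class,
    pROC,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
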