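Package: calvarisk
Title: Calvarial Bone Quantification and Intracranial-Pressure Risk from CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify local cranial bone thickness (mm) and density
    (Hounsfield units) from CT-like volumes of the pediatric calvaria, compare
    them against a covariate-adjusted normative reference (age, sex and
    acquisition voxel volume), and estimate the probabilistic risk and
    prevalence of chronic increased intracranial pressure in craniosynostosis
    phenotypes via a logistic classifier with Youden-index and
    high-specificity operating points. Includes a synthetic skull-phantom and
    cohort simulator with analytic ground truth so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
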