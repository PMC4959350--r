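Package: painrbm
Title: Discriminant Restricted Boltzmann Machines for Personalized
    Pain-State Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the probability of pain presence in
    non-communicative patients from flowsheet-style physiological records.
    Numeric readings are converted to personalized binary abnormality
    indicators against each patient's own Gaussian baseline, and the joint
    distribution of the abnormality bits together with the binary pain label
    is modelled with a binary restricted Boltzmann machine trained by
    contrastive divergence. Classification compares the free energies of the
    two label completions of a feature vector, which cancels the intractable
    partition function. Includes exact small-model enumeration oracles,
    linear comparators (a pooled-covariance linear discriminant and a
    principal-component projection feeding a linear support vector machine),
    ROC/AUC evaluation with minimum-distance operating-point selection, a
    synthetic flowsheet cohort generator with known ground truth, and an
    end-to-end experiment pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
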