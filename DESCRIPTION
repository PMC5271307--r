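Package: neotemplate
Title: Neonatal Bimodal MR-CT Head Template Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an unbiased neonatal head CT template in the stereotaxic
    space of an MR reference template, producing a fully co-registered
    bimodal MR-CT template. Provides CT preprocessing (head-mask extraction,
    background cleaning, a three-segment invertible intensity transform),
    coupled level-set extraction of the intracranial cavity across fontanel
    and suture gaps, intensity-based affine and symmetric diffeomorphic
    registration, groupwise unbiased template building, and
    mutual-information based validation. Includes a synthetic neonatal head
    phantom generator with ground-truth masks and transforms so the whole
    pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
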