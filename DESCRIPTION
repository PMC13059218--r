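Package: jemkit
Title: Psychosocial Job Exposure Matrices and an Occupational Job Strain Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds psychosocial job exposure matrices (JEMs) from ordinal
    survey microdata and derives an occupational job strain index in the
    Karasek demand-control tradition. Survey items are dichotomized at the
    pooled median, exposure shares are aggregated within occupation-group by
    gender cells, occupations are classified by a median-of-shares cut-off,
    and demand and control dimensions are combined into strain quadrants and a
    binary job strain flag. Also provides 4-digit occupational-code crosswalk
    application with explicit ambiguity policies, merging of occupation-level
    exposures onto individual-level register-style data, and a synthetic-data
    generator with known ground-truth exposure structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
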