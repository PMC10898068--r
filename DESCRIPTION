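Package: gdamine
Title: Rule-Based Mining of Gene-Disease Association Discovery Metadata
    from OMIM-Style Narrative Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts gene-disease association (GDA) discovery metadata
    from OMIM-dialect entry records: the publication that first
    established each association, the number of unrelated individuals or
    families studied, and the model organisms used as supporting
    evidence.  Implements the curation filtration ladder over phenotype
    mapping keys and label markers, a deterministic rule-based
    linguistic analyzer with dependency patterns for cohort and
    exclusion sentences, proximity-based citation resolution against
    numbered reference lists, a synthetic corpus generator with planted
    ground truth, and trend/benchmark analytics over the extracted
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
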