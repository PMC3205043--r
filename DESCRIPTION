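Package: cmlcheck
Title: Layered Validation for Chemical Markup Language Documents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A layered validator for Chemical Markup Language (CML) documents.
    Checks well-formedness, membership and content rules of the relaxed
    third-generation CML schema subset, deprecated constructs, and
    community conventions (simpleUnit, molecular, compchem, unit-dictionary)
    declared through the 'convention' attribute, with subtree scoping and
    QName/URI resolvability checks. Emits structured validation reports in
    the CML report namespace that aggregate to VALID, VALID_WITH_WARNINGS or
    INVALID, and implements the implicit chemistry semantics of CML molecule
    documents: recursive formal-charge aggregation, covalent-radius bond
    perception from Cartesian coordinates, and average bond length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
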