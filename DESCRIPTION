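Package: triadscope
Title: Triadic Analysis of Adolescent Friendship and Co-Drinking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the triadic analysis of classroom sociometric data:
    dichotomization of ordinal contact matrices into minimum, intermediate and
    maximum intensity networks; the 16-type Holland-Leinhardt MAN triad census
    with a transitive/intransitive partition in the Davis tradition;
    attribute-composition layers (same-gender subnetworks, stratified censuses,
    co-drinking nomination layers); AUDIT-based alcohol-risk classification,
    chi-square association tests, cross-layer Pearson correlations of
    transitive-triad participation profiles with exact statistical power; and a
    synthetic classroom-network generator with reciprocity, gender homophily,
    triadic closure and risk-linked co-drinking nominations, so the full
    pipeline is testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
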