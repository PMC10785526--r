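Package: clustagene
Title: Clustered Metagene Profiles from SAM Alignments
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds length-normalized per-feature coverage vectors from a SAM
    alignment and a GFF3/GTF annotation, groups them by k-means clustering
    with automatic selection of the number of clusters, and writes one
    metagene profile plus one membership list per cluster. Separating
    conflicting coverage trends avoids the destructive averaging that a
    single metagene plot performs when distinct signal shapes coexist in the
    data. Includes a synthetic read simulator that plants known per-feature
    coverage trends so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
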