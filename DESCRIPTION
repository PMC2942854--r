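Package: ilsom
Title: Self-Organizing Map Integration of Transcript and Metabolite
    Profiles from Introgression Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters genotype-indexed transcript and metabolite log-ratio
    profiles on a batch-trained two-dimensional self-organizing map with
    principal-component initialization, and provides the map-analysis layer
    used for introgression-line (IL) profiling: automatic sign-inverted
    duplicate patterns so that both direct and cross transcript-metabolite
    relations co-cluster, per-neuron composition classification with a
    pooling neighborhood, intracluster-variance cohesion, three-color
    per-genotype deviation maps, pseudo-zero (partially missing) pattern
    detection, chromosome subsetting, entity search, and annotation linkage
    through local lookup tables.  Reads and writes the plain-text '.data'
    matrix family, including expressed-IL validity markers and
    un-normalized companion files, and ships a synthetic-data generator
    with planted co-regulated groups for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
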