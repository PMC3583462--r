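Package: pmfinemap
Title: Fine-Mapping of a Recessive Dwarfing Locus from Progeny Tests,
    Cosegregation and Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, as a tested and reusable pipeline, the inference
    chain used to localize a recessive plant dwarfing gene: recombinant
    screening of an F2 population between flanking markers, progeny-test
    genotype calling at the trait locus from F3 family height distributions
    (median thresholds plus a 3:1 chi-square segregation test),
    cosegregation clustering of markers and trait placement with
    double-recombinant flagging, haplotype discrimination scanning across
    tall and dwarf inbred panels to delineate the candidate block, and
    MCscan-style collinear chaining of homologous gene-pair anchors to
    detect inversions and project the marker-bounded interval onto a
    reference genome.  Includes a synthetic-data generator (F2/F3
    populations under a Haldane map, two-component height mixtures,
    dual-genome gene-order tables with planted inversions) so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
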