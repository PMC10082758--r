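Package: trsirna
Title: Design of Transgene Regulator siRNAs with Minimal Endogenous Complementarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements an in silico design cascade for transgene regulator
    siRNAs: guide strands intended to silence only an artificial target site on
    a vector-delivered transgene while having minimal complementarity to any
    endogenous transcript. The cascade enumerates all 10-mer guide prefixes,
    removes those sharing a seed (positions 2-7) with mature miRNAs, retains
    the most quiescent quartile under a pluggable off-target propensity scorer,
    retains the lowest decile of seed-heptamer frequency over isoform-collapsed
    transcriptomes, ranks prefixes by exact complementary-match counts across
    species, and extends survivors into 23-mer guides scored with a
    position-weighted ungapped mismatch penalty. Also annotates canonical
    seed-matched 3'UTR sites (8mer, 7mer-m8, 7mer-A1), builds dual-luciferase
    reporter inserts, and generates seeded synthetic transcriptomes for
    end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
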