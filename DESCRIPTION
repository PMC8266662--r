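Package: combRFD
Title: Replication Fork Directionality Profiling from DNA Combing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts annotated single-molecule IdU/CldU replication tracks
    from DNA molecular combing into oriented replicated-DNA segments and
    discrete initiation/termination events, aggregates them into replication
    fork directionality (RFD), origin efficiency metric (OEM) and
    initiation-minus-termination density profiles, computes population RFD
    from strand-oriented Okazaki-fragment-style read intervals with
    subsampling ensembles and binned rank correlations, and evaluates
    closed-form fork-travel kinetics (S-phase duration, quarter-wise travel
    distances, fork meeting points and inter-zone reachability). A stochastic
    locus replication simulator with dual-pulse labelling, fibre extraction
    and oriented read emission makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
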