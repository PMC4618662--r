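Package: enhancerKinetics
Title: Classification and Kinetics of Pre-Existing and De Novo Myeloid Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative ChIP-seq and expression time-course pipeline for
    transcription-factor-induced transdifferentiation studies. Builds
    non-redundant binding-site universes from per-time-point peak calls,
    separates stable from transient sites, classifies distal sites into
    pre-existing and de novo enhancers from baseline histone marks
    (H3K4Me1/H3K27Ac/P300/H3K27Me3) and nearest-promoter state
    (H3K4Me3/H3K27Me3), infers pioneer-factor binding order from minute-scale
    time series, links enhancers to gene-expression kinetics by
    nearest-TSS/sliding-window association, profiles binned ChIP signal and
    median-subtracted MNase nucleosome occupancy around site centers, and
    tracks enhancer activity and factor occupancy across a hematopoietic
    lineage tree. Ships a deterministic synthetic-cohort generator with
    planted ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
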