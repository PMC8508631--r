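Package: horizTE
Title: Detection and Validation of Horizontally Transferred Transposable Elements
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Screens multi-species genome sequences for candidate horizontal
    transfer (HT) of transposable elements using a built-in seed-and-extend
    local similarity search, removes conserved and redundant sequences,
    establishes the vertical-inheritance baseline from third-codon-position
    identity of reciprocal-best-hit orthologs, reconstructs the relative
    activity history of TE paralog families from UPGMA node identities, and
    classifies donor and recipient species from activity histories combined
    with phylogenetic incongruence of homolog trees. Includes a
    ground-truth synthetic genome simulator (species phylogeny, native TE
    bursts, implanted HT events, ortholog CDS sets, conserved decoys) for
    end-to-end validation, plus reverse-transcriptase-domain profiling for
    LTR retrotransposon family composition reports.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
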