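Package: starrscout
Title: Genome-Wide Enhancer Discovery and Characterization from STARR-Seq
    Fragment Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate transcriptional enhancers from STARR-seq
    (self-transcribing active regulatory region sequencing) fragment libraries
    by binomial enrichment of cDNA reporter fragments over plasmid input,
    intersects per-replicate peaks into replicate-consensus enhancers, and
    characterizes the resulting enhancer compartment: genomic feature
    classification against a gene annotation, size- and locus-matched
    non-enhancer control sets, GC and perfect-microsatellite composition
    statistics with a ten-control Kruskal-Wallis/Mann-Whitney consensus
    procedure, position-weight-matrix transcription-factor-binding-site
    enrichment, and reciprocal-overlap comparison with external peak sets.
    Includes a deterministic synthetic-data generator (toy genome, annotation,
    planted enhancers, fragment libraries) so the whole pipeline is testable
    end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
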