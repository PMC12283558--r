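Package: TraDISect
Title: Transposon-Insertion (TraDIS) Gene Essentiality Analysis and Comparative Genomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of saturated transposon-insertion (TraDIS/Tn-seq)
    libraries in bacteria. Selects and trims transposon-tagged reads, maps
    them on small genomes, derives unique insertion sites and per-gene
    insertion indices, and classifies genes as essential, non-essential or
    unclear by a log2 likelihood ratio between an exponential (essential)
    and a gamma (non-essential) mode fitted to the bimodal insertion-index
    distribution. A sliding-window scan detects insertion-free essential
    domains inside otherwise tolerant genes. Downstream comparative tools
    cover reciprocal-best-hit ortholog detection with coverage and paralog
    filters joined to per-species essentiality calls, COG functional-class
    essentiality profiles, and phylogenetic profiling of ortholog-group
    presence/absence with complete-linkage clustering. A fully seeded
    synthetic-data generator emits genomes, annotations, insertion tables,
    reads, homology and annotation fixtures with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    fitdistrplus,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TraDISect-package.R'
    'annotation-io.R'
    'domain-scan.R'
    'essentiality.R'
    'exact-mapping.R'
    'insertion-stats.R'
    'methods.R'
    'orthologs.R'
    'pipeline.R'
    'profiles.R'
    'simulate.R'
    'tables-io.R'
    'tag-selection.R'
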