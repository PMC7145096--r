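Package: TERscreen
Title: Telomerase RNA Candidate Discovery from Immunoprecipitation RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies candidate telomerase RNA (TER) loci among transcripts
    assembled from telomerase immunoprecipitation RNA-seq. Enumerates all
    circular permutations of the plant telomere repeat (TTTAGGG) over a
    template-length range, scans transcript sequences for template domains on
    both strands, and applies a four-stage candidate funnel: mean-TPM
    expression filter, known-gene overlap discard, template-domain screen, and
    a cross-species conservation filter built from homology hit tables. Also
    provides a substrate-register model of telomerase product-length
    differences on the 0-6 quadrant scale with UPGMA clustering of species
    utilization profiles, a chi-squared likelihood-ratio helper for
    branch-sites selection tests, and a seeded synthetic-data generator with
    ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Sequencing, GeneExpression, Annotation
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TERscreen-package.R'
    'permutations.R'
    'scan.R'
    'conservation.R'
    'funnel.R'
    'synthetic.R'
    'pipeline.R'
    'substrate.R'
    'upgma.R'
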