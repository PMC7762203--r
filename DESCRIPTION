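Package: baculoPolyA
Title: Positional Modelling of Baculovirus mRNA 3'-End Processing Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and models the cis-acting elements that direct 3'-end
    cleavage and polyadenylation of baculovirus pre-mRNAs. Extracts downstream
    gene regions (-100..+350 around the stop codon) from annotated circular
    dsDNA genomes, scans them for USE, UGUA, PAS, cleavage-site, DSE and
    auxiliary DSE motifs under IUPAC semantics, assembles the hits into
    polyadenylation cassettes under explicit positional distance models,
    analyses the secondary-structure context of the cleavage site with a
    maximum base-pairing fold, and summarises element contexts as position
    frequency matrices and information-content profiles. A synthetic-genome
    simulator with planted signal cassettes and ground-truth tables makes the
    whole pipeline testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SequenceMatching, MotifDiscovery, Transcription
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'baculoPolyA-package.R'
    'coords.R'
    'genome-io.R'
    'motif-scan.R'
    'pas-model.R'
    'reporting.R'
    'structure.R'
    'synthetic-data.R'
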