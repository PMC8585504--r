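Package: bstaContext
Title: Gene-Neighborhood and Self-Immunity Element Analysis for BstA-Family Phage-Defense Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for prophage-encoded phage-defense
    gene families. Extracts the 40-kb gene neighborhood around focal homologs
    from GFF3 annotation, reduces HMMER3 domtblout domain hits to the best
    significant hit per ORF, classifies each homolog as prophage-associated
    (high or low confidence) or putatively prophage-independent from
    keyword or domain evidence, tallies co-occurring Pfam domains, computes
    Needle-convention global-alignment percent identities, and analyses
    anti-BstA (aba) self-immunity elements (upstream/coding partition,
    direct-repeat and terminal-repeat detection, point mutations, ORF
    scanning). Includes a deterministic synthetic-survey generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, Annotation, SequenceMatching, Alignment, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
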