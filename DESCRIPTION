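Package: methylace
Title: Base-Resolution Bisulfite Methylome Pipeline with Anchored Mate
    Rescue and Monoclonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for paired-end whole-genome bisulfite
    sequencing (BS-seq) analysis of wild-type and DNA-methyltransferase
    knockout methylomes. Implements three-letter (C-to-T / G-to-A)
    paired-end alignment with anchored cluster end-mapping, in which a
    uniquely aligned mate rescues its multi-mapping partner using the known
    sonication fragment-length range; PCR-amplification-bias removal by
    monoclonization (collapsing read pairs that share both fragment-end
    coordinates to one clone); per-cytosine methylation-rate calling with
    strand combination and CG-density annotation; strand-bias statistics
    (bias index, sense/antisense correlation); discovery of
    reduction-resistant methylation regions (RRMRs) as runs of consecutive
    CG sites with low deletion index, with repeat-element overlap and
    Fisher enrichment; binned methylation profiles of genes, LINEs and
    LTRs; and integration of promoter methylation with expression fold
    change. A synthetic-data module generates toy genomes, genotype-specific
    methylomes and bisulfite read pairs with configurable PCR bias so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
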