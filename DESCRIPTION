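Package: nmdcall
Title: Prediction of Nonsense-Mediated-Decay-Eliciting Somatic Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based prediction of somatic mutations that elicit
    nonsense-mediated decay (NMD). Reconstructs mutated spliced coding
    sequences from gene models (GTF/BED12 + FASTA) and TCGA-style MAF
    mutation catalogues, relocates the open reading frame, detects
    premature termination codons (PTCs), and classifies each mutation by
    three positional rules (multi-exon gene, PTC more than 50 bp upstream
    of the last exon-exon junction, PTC more than 200 bp downstream of the
    start codon). Includes rank-based expression validation statistics
    (relative expression of variant, gene-level U-statistic z-scores with
    NMD-sensitivity tiers), cohort-level hypermutation enrichment with
    Fisher/FDR, gene-set over-representation, tumour-suppressor burden and
    deletion co-occurrence analyses, and seeded synthetic-data generators
    with an independent brute-force classification oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
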