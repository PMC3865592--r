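Package: splicevar
Title: Somatic Splice-Site Mutation Discovery from Tumor/Normal Exomes with
    RNA-Seq Consequence Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering somatic point mutations at splice
    junctions from matched tumor/normal exome pileups, predicting loss of
    donor or acceptor splice sites by the consensus of three independent
    position-based scoring models, and quantifying the transcript-level
    consequence (exon skipping, intron retention, cryptic splice-site
    activation) from spliced RNA-seq alignments, with FPKM expression
    context. Includes a synthetic-data generator that builds end-to-end
    fixtures with known planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
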