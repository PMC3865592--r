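test_that("FASTA loading normalizes case and keeps records distinct", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 descr", "acgt"), fa)
  g <- load_fasta(fa)
  expect_equal(unname(g[["c1"]]), "ACGT")

  writeLines(c(">c1", "AC", "GT", ">c2", "NN"), fa)
  g <- load_fasta(fa)
  expect_equal(nchar(g[["c1"]]), 4L)
  expect_equal(nchar(g[["c2"]]), 2L)

  writeLines(c(">c1", "AC", ">c1", "GG"), fa)
  expect_error(load_fasta(fa), "duplicated contig")
})

test_that("GTF loading groups exons per transcript and computes CDS bounds", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "t1";'
  writeLines(c(
    paste("c1", "src", "exon", 10, 29, ".", "+", ".", attrs, sep = "\t"),
    paste("c1", "src", "exon", 50, 69, ".", "+", ".", attrs, sep = "\t"),
    paste("c1", "src", "exon", 90, 109, ".", "+", ".", attrs, sep = "\t"),
    paste("c1", "src", "CDS", 10, 29, ".", "+", "0", attrs, sep = "\t"),
    paste("c1", "src", "CDS", 50, 69, ".", "+", "0", attrs, sep = "\t"),
    paste("c1", "src", "CDS", 90, 109, ".", "+", "0", attrs, sep = "\t")),
    gtf)
  txs <- load_gene_models(gtf)
  expect_length(txs, 1L)
  tx <- txs[["t1"]]
  expect_equal(nrow(tx$exons), 3L)
  bnd <- splice_boundaries(tx)
  expect_equal(sum(bnd$kind == "donor"), 2L)
  expect_equal(sum(bnd$kind == "acceptor"), 2L)
  # plus strand: donors at exon ends, acceptors at internal exon starts
  expect_setequal(bnd$genomic_position[bnd$kind == "donor"], c(29, 69))
  expect_setequal(bnd$genomic_position[bnd$kind == "acceptor"], c(50, 90))
})

test_that("minus-strand donors/acceptors swap genomic sides", {
  # oracle: construct the reverse-complemented (+)-strand case and compare
  plus_tx <- tx_of(c(10, 50, 90), c(29, 69, 109))
  L <- 120L
  minus_tx <- new_transcript("t1", "g1", "c1", "-",
                             data.frame(start = L - c(29, 69, 109) + 1L,
                                        end = L - c(10, 50, 90) + 1L),
                             cds_start = L - 109 + 1L, cds_end = L - 10 + 1L)
  bp <- splice_boundaries(plus_tx)
  bm <- splice_boundaries(minus_tx)
  # every boundary maps to the mirrored coordinate with the same role
  for (i in seq_len(nrow(bp))) {
    mirrored <- L - bp$genomic_position[i] + 1L
    j <- which(bm$genomic_position == mirrored)
    expect_equal(bm$kind[j], bp$kind[i])
    expect_equal(bm$exon_index[j], bp$exon_index[i])
  }
})

test_that("transcripts without CDS load but cannot be c.-named", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "t1";'
  writeLines(c(
    paste("c1", "src", "exon", 10, 29, ".", "+", ".", attrs, sep = "\t"),
    paste("c1", "src", "exon", 50, 69, ".", "+", ".", attrs, sep = "\t")),
    gtf)
  tx <- load_gene_models(gtf)[["t1"]]
  expect_false(splicevar:::has_cds(tx))
  expect_error(cdna_coordinate(tx, 15), "no CDS")
})

test_that("invalid transcript models are rejected", {
  expect_error(tx_of(c(10, 25), c(30, 40)), "overlapping")
  expect_error(new_transcript("t", "g", "c1", "+",
                              data.frame(start = integer(), end = integer())),
               "zero exons")
  expect_error(tx_of(c(10, 50), c(29, 69), cds_start = 35, cds_end = 60),
               "not on an exonic base")
})

test_that("cdna coordinates reproduce hand-summed exon arithmetic", {
  # first CDS base -> c.1
  tx <- tx_of(c(10, 50), c(29, 69))
  expect_equal(cdna_coordinate(tx, 10),
               list(cds_offset = 1L, intron_offset = 0L, label = "c.1"))

  # cumulative CDS of 1312 at exon 2's end; +5 into the following intron
  tx2 <- tx_of(c(101, 1001, 2001), c(756, 1656, 2100))
  # exon lengths 656 + 656 = 1312 by hand
  cc <- cdna_coordinate(tx2, 1656 + 5)
  expect_equal(cc$label, "c.1312+5")

  # 1661 coding bases before an exon; 1 bp before its acceptor
  tx3 <- tx_of(c(101, 1001, 2001, 3001),
               c(654, 1554, 2553, 3100))
  # lengths 554 + 554 + 553 = 1661 by hand
  cc <- cdna_coordinate(tx3, 3001 - 1)
  expect_equal(cc$label, "c.1662-1")

  expect_error(cdna_coordinate(tx, 5), "outside the span")
})

test_that("exonic positions round-trip through cdna coordinates", {
  tx <- tx_of(c(10, 50, 90), c(29, 69, 109))
  for (g in c(10:29, 50:69, 90:109)) {
    cc <- cdna_coordinate(tx, g)
    expect_equal(genomic_coordinate(tx, cc$cds_offset, cc$intron_offset), g)
  }
  m <- mirror_minus(genome_of(strrep("A", 120)), tx)
  for (g in m$tx$exons$start[1]:m$tx$exons$end[1]) {
    cc <- cdna_coordinate(m$tx, g)
    expect_equal(genomic_coordinate(m$tx, cc$cds_offset, cc$intron_offset),
                 g)
  }
})

test_that("boundary windows read exon to intron in transcript orientation", {
  # plus-strand donor with context ...CAG|GTAAGT...
  seq <- paste0(strrep("T", 7), "CAG", "GTAAGT", strrep("T", 7))
  g <- genome_of(seq)
  tx <- tx_of(c(3, 20), c(10, 23), cds_start = 3, cds_end = 23)
  bnd <- splice_boundaries(tx)
  don <- bnd[bnd$kind == "donor", ]
  expect_equal(boundary_window(g, tx, don), "CAGGTAAGT")

  # minus-strand mirror returns the identical transcript-oriented window
  m <- mirror_minus(g, tx)
  bm <- splice_boundaries(m$tx)
  expect_equal(boundary_window(m$genome, m$tx, bm[bm$kind == "donor", ]),
               "CAGGTAAGT")

  # acceptor window ends with AG then 3 exonic bases
  aseq <- paste0("TT", strrep("C", 18), "AG", "GAG", strrep("T", 5))
  ga <- genome_of(aseq)
  txa <- tx_of(c(1, 23), c(1, 28), cds_start = 1, cds_end = 28)
  acc <- splice_boundaries(txa)
  acc <- acc[acc$kind == "acceptor", ]
  w <- boundary_window(ga, txa, acc)
  expect_equal(nchar(w), 23L)
  expect_equal(substr(w, 19, 23), "AGGAG")

  # window exceeding the contig errors
  expect_error(boundary_window(ga, tx_of(c(1, 10), c(3, 28),
                                         cds_start = 1, cds_end = 28),
                               data.frame(kind = "acceptor",
                                          genomic_position = 10)),
               "exceeds bounds")
})

test_that("donor windows always contain the boundary at the exonic offset", {
  # property over several geometries: bases 1..donor_exonic are exonic,
  # donor_exonic+1 .. end are intronic
  seq <- paste0(strrep("A", 30), "CAG", "GTAAGT", strrep("A", 30))
  g <- genome_of(seq)
  tx <- tx_of(c(25, 60), c(33, 65), cds_start = 25, cds_end = 65)
  don <- splice_boundaries(tx)
  don <- don[don$kind == "donor", ]
  for (ex in 1:3) {
    w <- boundary_window(g, tx, don, donor_exonic = ex, donor_intronic = 6)
    expect_equal(nchar(w), ex + 6L)
    expect_equal(substr(w, ex + 1L, ex + 2L), "GT")
  }
})
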