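sam_df <- function(...) {
  rows <- list(...)
  data.frame(qname = vapply(rows, `[[`, "", 1),
             flag = as.integer(vapply(rows, `[[`, "", 2)),
             rname = vapply(rows, `[[`, "", 3),
             pos = as.integer(vapply(rows, `[[`, "", 4)),
             mapq = 60L,
             cigar = vapply(rows, `[[`, "", 5),
             seq = vapply(rows, `[[`, "", 6),
             stringsAsFactors = FALSE)
}

rd <- function(qname, pos, cigar, seq = "*", flag = "0", rname = "c1") {
  c(qname, flag, rname, as.character(pos), cigar, seq)
}

test_that("junctions are extracted from CIGAR N operations", {
  # 20M100N20M starting at 1: junction (20, 121) by CIGAR arithmetic
  sam <- sam_df(rd("r1", 1, "20M100N20M"))
  j <- junctions_from_alignments(sam)
  expect_equal(j$donor_end, 20L)
  expect_equal(j$acceptor_start, 121L)
  expect_equal(j$count, 1L)

  # two reads over the same junction aggregate
  sam <- sam_df(rd("r1", 1, "20M100N20M"), rd("r2", 5, "16M100N30M"))
  j <- junctions_from_alignments(sam)
  expect_equal(j$count, 2L)

  # an unspliced read yields no junction
  sam <- sam_df(rd("r1", 1, "40M"))
  expect_equal(nrow(junctions_from_alignments(sam)), 0L)

  # unmapped and secondary records are ignored; bad CIGARs are skipped
  sam <- sam_df(rd("r1", 1, "20M100N20M"),
                rd("r2", 1, "20M100N20M", flag = "4"),
                rd("r3", 1, "20M100N20M", flag = "256"),
                rd("r4", 1, "BADCIGAR"))
  expect_warning(j <- junctions_from_alignments(sam), "malformed CIGAR")
  expect_equal(j$count, 1L)
  expect_equal(attr(j, "n_skipped"), 1L)
})

test_that("junction tables and SAM input are interchangeable", {
  sam <- sam_df(rd("r1", 1, "20M100N20M"), rd("r2", 1, "20M100N20M"),
                rd("r3", 50, "10M60N10M"))
  j <- junctions_from_alignments(sam)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_junction_table(j, f)
  expect_equal(read_junction_table(f)$count, j$count)
  expect_equal(read_junction_table(f)$donor_end, j$donor_end)
})

test_that("boundary-spanning reads require anchored contiguous coverage", {
  g <- genome_of(strrep("ACGT", 100))
  tx <- tx_of(c(11, 101), c(50, 150), contig = "c1")
  don <- splice_boundaries(tx)
  don <- don[don$kind == "donor", ]   # exon 1 ends at 50

  # 5 reads of 10M across the border with anchor 6: all counted
  sam <- do.call(sam_df, lapply(1:5, function(i) {
    rd(paste0("s", i), 45, "10M", substr(g[["c1"]], 45, 54))
  }))
  expect_equal(boundary_spanning_count(sam, tx, don, min_anchor = 4)$count,
               5L)

  # a read whose N starts exactly at the border is spliced, not spanning
  sam <- sam_df(rd("r1", 41, "10M50N10M"))
  expect_equal(boundary_spanning_count(sam, tx, don, min_anchor = 6)$count,
               0L)

  # anchor larger than the read overhang: not counted
  sam <- sam_df(rd("r1", 48, "6M", "AAAAAA"))
  expect_equal(boundary_spanning_count(sam, tx, don, min_anchor = 6)$count,
               0L)

  # per-read alleles are returned at a query position
  seqs <- c(substr(g[["c1"]], 45, 54), substr(g[["c1"]], 45, 54))
  substr(seqs[1], 6, 6) <- "A"   # position 50
  sam <- sam_df(rd("m1", 45, "10M", seqs[1]), rd("m2", 45, "10M", seqs[2]))
  res <- boundary_spanning_count(sam, tx, don, min_anchor = 4,
                                 query_position = 50)
  expect_equal(sort(res$alleles),
               sort(c("A", substr(g[["c1"]], 50, 50))))
})

test_that("published junction tables reproduce the published fractions", {
  # six-exon gene mutated at the exon-5 donor: 28 skip reads (ex4-ex6),
  # 5 + 3 canonical reads -> 78% skip, 22% wild type
  tx <- tx_of(seq(1, by = 200, length.out = 6),
              seq(100, by = 200, length.out = 6))
  ann <- data.frame(region = "splicing", side = "donor", exon_index = 5L,
                    stringsAsFactors = FALSE)
  jx <- data.frame(
    contig = "c1",
    donor_end = c(tx$exons$end[4], tx$exons$end[5], tx$exons$end[4]),
    acceptor_start = c(tx$exons$start[6], tx$exons$start[6],
                       tx$exons$start[5]),
    count = c(28L, 5L, 3L), stringsAsFactors = FALSE)
  ev <- classify_splice_event(ann, tx, jx)
  o <- ev$outcomes
  expect_equal(o$percent[o$kind == "exon_skip"], 78L)
  expect_equal(o$read_count[o$kind == "wild_type"], 8L)
  expect_equal(o$percent[o$kind == "wild_type"], 22L)

  # mutated acceptor with 7 canonical junction reads + 5 spanning reads:
  # 58% wild type, 42% intron retention
  tx2 <- tx_of(c(1, 201), c(100, 300))
  ann2 <- data.frame(region = "splicing", side = "acceptor",
                     exon_index = 2L, stringsAsFactors = FALSE)
  jx2 <- data.frame(contig = "c1", donor_end = 100L, acceptor_start = 201L,
                    count = 7L, stringsAsFactors = FALSE)
  ev2 <- classify_splice_event(ann2, tx2, jx2, spanning = 5L)
  o2 <- ev2$outcomes
  expect_equal(o2$percent[o2$kind == "wild_type"], 58L)
  expect_equal(o2$percent[o2$kind == "intron_retention"], 42L)

  # canonical + spanning + cryptic junction 5 bp within the exon:
  # 58% / 37% / 5%
  jx3 <- rbind(jx2,
               data.frame(contig = "c1", donor_end = 100L,
                          acceptor_start = 206L, count = 5L,
                          stringsAsFactors = FALSE))
  jx3$count[1] <- 58L
  ev3 <- classify_splice_event(ann2, tx2, jx3, spanning = 37L)
  o3 <- ev3$outcomes
  expect_equal(o3$percent[o3$kind == "wild_type"], 58L)
  expect_equal(o3$percent[o3$kind == "intron_retention"], 37L)
  expect_equal(o3$percent[o3$kind == "cryptic"], 5L)
  expect_equal(o3$detail[o3$kind == "cryptic"], "acceptor+5")

  # only canonical reads: 100% wild type
  ev4 <- classify_splice_event(ann2, tx2, jx2)
  expect_equal(ev4$outcomes$percent, 100L)

  # zero informative reads: explicit not-expressed status
  ev5 <- classify_splice_event(ann2, tx2, jx2[0, ])
  expect_equal(ev5$status, "not_expressed")
  expect_equal(nrow(ev5$outcomes), 0L)
})

test_that("event percentages always sum to 100 within rounding", {
  tx <- tx_of(c(1, 201, 401), c(100, 300, 500))
  ann <- data.frame(region = "splicing", side = "acceptor",
                    exon_index = 2L, stringsAsFactors = FALSE)
  withr::with_seed(3, {
    for (k in 1:25) {
      jx <- data.frame(
        contig = "c1",
        donor_end = c(100L, 300L, 100L),
        acceptor_start = c(201L, 401L, 401L),
        count = as.integer(sample(0:60, 3, replace = TRUE)),
        stringsAsFactors = FALSE)
      sp <- sample(0:40, 1)
      ev <- classify_splice_event(ann, tx, jx, spanning = sp)
      if (ev$status == "ok") {
        expect_lte(abs(sum(ev$outcomes$percent) - 100L), 1L)
        expect_equal(sum(ev$outcomes$read_count), ev$total)
      }
    }
  })
})

test_that("allele support distinguishes exclusive-mutant retention", {
  expect_equal(allele_support(rep("A", 5), "G", "A"),
               list(mut_count = 5L, wt_count = 0L, exclusive_mutant = TRUE))
  expect_equal(allele_support(c("A", "A", "A", "G", "G"), "G", "A"),
               list(mut_count = 3L, wt_count = 2L,
                    exclusive_mutant = FALSE))
  expect_equal(allele_support(character(0), "G", "A"),
               list(mut_count = 0L, wt_count = 0L,
                    exclusive_mutant = FALSE))
})

test_that("fpkm follows its defining formula and linearity", {
  expect_equal(fpkm(1000, 1000, 1e6), 1000)
  expect_equal(fpkm(2843, 2160, 4e7), 2843 / ((2160 / 1e3) * (4e7 / 1e6)))
  expect_equal(fpkm(0, 14087, 1e7), 0)
  expect_error(fpkm(10, 0, 1e6), "length")
  expect_error(fpkm(10, 100, 0), "total")
  # linear in count, inverse-linear in length and total
  base <- fpkm(100, 2000, 1e6)
  expect_equal(fpkm(300, 2000, 1e6), 3 * base)
  expect_equal(fpkm(100, 4000, 1e6), base / 2)
  expect_equal(fpkm(100, 2000, 2e6), base / 2)
})

test_that("percentile ranks count values at or below the query", {
  expect_equal(percentile_rank(10, 1:10), 100L)
  expect_equal(percentile_rank(9, 1:10), 90L)
  expect_equal(percentile_rank(1, 1:10), 10L)  # unique minimum: 100/n
  expect_equal(percentile_rank(0, 1:10), 0L)
})

test_that("fragment counting assigns pairs once and honors exon overlap", {
  g <- genome_of(strrep("ACGT", 200))
  tx <- tx_of(c(101, 301), c(200, 400))
  sam <- sam_df(rd("p1", 110, "30M", flag = "99"),
                rd("p1", 160, "30M", flag = "147"),  # same pair: counts once
                rd("p2", 150, "51M100N30M"),         # junction read
                rd("p3", 600, "30M"))                # off-gene
  expect_equal(count_fragments(sam, tx), 2L)
  expect_equal(exon_model_length(tx), 200L)
  expr <- expression_table(data.frame(gene_id = c("g1", "g2"),
                                      exon_model_length_bp = c(200L, 1000L),
                                      fragment_count = c(2L, 0L)),
                           total_mapped_fragments = 1e6)
  expect_equal(expr$fpkm, c(2 / (0.2 * 1), 0))
  expect_equal(expr$percentile, c(100L, 50L))
})
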