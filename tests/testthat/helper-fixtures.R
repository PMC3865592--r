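# Shared toy fixtures, built in code.

# quick transcript constructor from exon start/end vectors
tx_of <- function(starts, ends, strand = "+", contig = "c1",
                  cds_start = min(starts), cds_end = max(ends),
                  id = "tx1", gene = "g1") {
  new_transcript(id, gene, contig, strand,
                 data.frame(start = starts, end = ends),
                 cds_start = cds_start, cds_end = cds_end)
}

# a genome holding one contig built from explicit segment strings
genome_of <- function(seq, contig = "c1") {
  structure(stats::setNames(toupper(seq), contig), class = "sv_genome")
}

# mirror a (+)-strand genome/transcript pair to the (-) strand:
# reverse-complement the contig and flip exon coordinates
mirror_minus <- function(genome, tx) {
  L <- nchar(genome[[tx$contig]])
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genome[[tx$contig]])))
  ex <- tx$exons
  flipped <- data.frame(start = L - ex$end + 1L, end = L - ex$start + 1L)
  list(
    genome = genome_of(rc, tx$contig),
    tx = new_transcript(tx$transcript_id, tx$gene_id, tx$contig, "-",
                        flipped,
                        cds_start = L - tx$cds_end + 1L,
                        cds_end = L - tx$cds_start + 1L))
}

# pileup site with uniform quality
site_of <- function(contig, pos, ref, bases, qual = 40L,
                    strands = rep("+", length(bases))) {
  new_pileup_site(contig, pos, ref, bases, strands,
                  rep(qual, length.out = length(bases)))
}

# brute-force somatic filter, independent of call_site/cross_match:
# straight re-statement of the hard filters over decoded sites
brute_force_calls <- function(tumor_sites, normal_sites,
                              min_depth = 20, min_alt = 6, min_pct = 25,
                              min_q = 30, max_norm_pct = 10) {
  nkey <- vapply(normal_sites, function(s) paste0(s$contig, ":", s$position), "")
  hits <- integer(0)
  for (k in seq_along(tumor_sites)) {
    t <- tumor_sites[[k]]
    if (t$depth < min_depth) next
    ok <- t$quals >= min_q & t$bases %in% c("A", "C", "G", "T")
    bases <- t$bases[ok]
    alts <- setdiff(unique(bases), t$ref_base)
    if (!length(alts)) next
    counts <- vapply(alts, function(b) sum(bases == b), 0L)
    b <- alts[order(-counts, alts)][1]
    cnt <- max(counts)
    if (cnt < min_alt) next
    if (floor(100 * cnt / t$depth + 0.5) < min_pct) next
    i <- match(paste0(t$contig, ":", t$position), nkey)
    if (is.na(i)) next
    n <- normal_sites[[i]]
    if (n$depth < 1) next
    nok <- n$quals >= min_q & n$bases == b
    if (floor(100 * sum(nok) / n$depth + 0.5) > max_norm_pct) next
    hits <- c(hits, k)
  }
  hits
}

# toy training sets: canonical sites with mild variability away from the
# invariant dinucleotides
toy_donor_training <- function(n = 12) {
  base <- rep("CAGGTAAGT", n)
  substr(base[2], 1, 1) <- "A"
  substr(base[3], 6, 6) <- "G"
  substr(base[4], 9, 9) <- "C"
  substr(base[5], 1, 1) <- "T"
  substr(base[6], 7, 7) <- "C"
  base
}

toy_acceptor_training <- function(n = 12) {
  cons <- paste0(strrep("C", 18), "AG", "GAG")
  base <- rep(cons, n)
  substr(base[2], 1, 1) <- "T"
  substr(base[3], 5, 5) <- "T"
  substr(base[4], 23, 23) <- "T"
  substr(base[5], 10, 10) <- "A"
  base
}
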