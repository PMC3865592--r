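# Transcript-level consequence quantification from spliced RNA-seq
# alignments: junction extraction from CIGAR N operations, boundary-spanning
# (intron-retention) read counting, event classification into wild-type /
# exon-skip / intron-retention / cryptic fractions, per-read allele support
# in retained-intron reads, and FPKM expression with percentile ranks.

#' Read a SAM text file
#'
#' Parses the 11 mandatory columns; header lines are skipped.
#'
#' @param path SAM path.
#' @return `data.frame` with `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^@", lines)]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11L)
  if (length(bad)) stop("malformed SAM line ", bad[1], ": fewer than 11 fields")
  data.frame(qname = vapply(f, `[`, "", 1),
             flag = as.integer(vapply(f, `[`, "", 2)),
             rname = vapply(f, `[`, "", 3),
             pos = as.integer(vapply(f, `[`, "", 4)),
             mapq = as.integer(vapply(f, `[`, "", 5)),
             cigar = vapply(f, `[`, "", 6),
             seq = vapply(f, `[`, "", 10),
             stringsAsFactors = FALSE)
}

# primary mapped records only (drop unmapped 0x4, secondary 0x100,
# supplementary 0x800)
primary_mapped <- function(sam) {
  keep <- bitwAnd(sam$flag, 0x4L) == 0L &
    bitwAnd(sam$flag, 0x100L) == 0L &
    bitwAnd(sam$flag, 0x800L) == 0L &
    sam$rname != "*"
  sam[keep, , drop = FALSE]
}

valid_cigar <- function(cigar) {
  grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
}

#' Extract splice junctions from spliced alignments
#'
#' Every `N` CIGAR operation of a primary mapped record yields one junction:
#' `donor_end` is the last aligned reference base before the gap,
#' `acceptor_start` the first after it. Counts are aggregated over reads.
#' Records with malformed CIGAR strings are skipped; their number is
#' attached as attribute `n_skipped` (with a warning).
#'
#' @param sam SAM records ([read_sam()]).
#' @return `data.frame` with `contig`, `donor_end`, `acceptor_start`,
#'   `count`, sorted by coordinate.
#' @export
junctions_from_alignments <- function(sam) {
  sam <- primary_mapped(sam)
  ok <- valid_cigar(sam$cigar)
  n_skipped <- sum(!ok)
  if (n_skipped) {
    warning(n_skipped, " record(s) with malformed CIGAR skipped")
  }
  sam <- sam[ok, , drop = FALSE]
  empty <- data.frame(contig = character(), donor_end = integer(),
                      acceptor_start = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(sam)) return(structure(empty, n_skipped = n_skipped))
  gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    sam$cigar, pos = sam$pos, ops = "N")
  n_per <- lengths(gaps)
  if (sum(n_per) == 0L) return(structure(empty, n_skipped = n_skipped))
  flat <- unlist(gaps)
  j <- data.frame(contig = rep(sam$rname, n_per),
                  donor_end = IRanges::start(flat) - 1L,
                  acceptor_start = IRanges::end(flat) + 1L,
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(j))),
                          j, FUN = sum)
  agg <- agg[order(agg$contig, agg$donor_end, agg$acceptor_start), ,
             drop = FALSE]
  rownames(agg) <- NULL
  structure(agg[, c("contig", "donor_end", "acceptor_start", "count")],
            n_skipped = n_skipped)
}

#' Read/write a junction-count table
#'
#' TSV with columns contig, donor_end, acceptor_start, count — the
#' junction-table alternative to SAM input.
#'
#' @param path TSV path.
#' @return `data.frame` as [junctions_from_alignments()].
#' @export
read_junction_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    col.names = c("contig", "donor_end", "acceptor_start",
                                  "count"),
                    stringsAsFactors = FALSE)
}

#' @rdname read_junction_table
#' @param junctions Junction `data.frame`.
#' @export
write_junction_table <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# genomic base immediately left of the exon/intron junction point of a
# boundary (kind, genomic_position) on a transcript
border_left_base <- function(tx, kind, position) {
  plus <- tx$strand == "+"
  if (kind == "donor") {
    if (plus) position else position - 1L
  } else {
    if (plus) position - 1L else position
  }
}

#' Count reads continuously spanning an exon-intron boundary
#'
#' A read spans the boundary when one of its aligned reference blocks
#' (maximal stretches without an N gap) covers `min_anchor` bases on both
#' sides of the junction point. When `query_position` is given, the read
#' base aligned at that reference position is returned for every counted
#' read.
#'
#' @param sam SAM records ([read_sam()]).
#' @param tx Transcript owning the boundary.
#' @param boundary List/row with `kind` and `genomic_position` (as from
#'   [splice_boundaries()]).
#' @param min_anchor Required aligned bases on each side of the junction.
#' @param query_position Optional reference position whose per-read allele
#'   is extracted.
#' @return List with `count` and `alleles` (character vector, possibly
#'   empty).
#' @export
boundary_spanning_count <- function(sam, tx, boundary, min_anchor = 6L,
                                    query_position = NULL) {
  sam <- primary_mapped(sam)
  sam <- sam[sam$rname == tx$contig & valid_cigar(sam$cigar), ,
             drop = FALSE]
  b <- border_left_base(tx, boundary$kind, boundary$genomic_position)
  lo <- b - min_anchor + 1L
  hi <- b + min_anchor
  count <- 0L
  alleles <- character(0)
  if (nrow(sam)) {
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
      sam$cigar, pos = sam$pos)
    for (i in seq_len(nrow(sam))) {
      bl <- blocks[[i]]
      covered <- any(IRanges::start(bl) <= lo & IRanges::end(bl) >= hi)
      if (!covered) next
      count <- count + 1L
      if (!is.null(query_position)) {
        alleles <- c(alleles, read_base_at(sam$cigar[i], sam$pos[i],
                                           sam$seq[i], query_position))
      }
    }
  }
  list(count = count, alleles = alleles)
}

# base of one read aligned at reference position q (NA when q falls in a
# deletion/skip or outside the alignment)
read_base_at <- function(cigar, pos, seq, q) {
  ops <- strsplit(gsub("([MIDNSHP=X])", "\\1 ", cigar), " ")[[1]]
  rpos <- pos; qpos <- 1L
  for (op in ops) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", op))
    o <- sub("^[0-9]+", "", op)
    if (o %in% c("M", "=", "X")) {
      if (q >= rpos && q < rpos + n) {
        return(toupper(substr(seq, qpos + (q - rpos), qpos + (q - rpos))))
      }
      rpos <- rpos + n; qpos <- qpos + n
    } else if (o %in% c("I", "S")) {
      qpos <- qpos + n
    } else if (o %in% c("D", "N")) {
      if (o == "D" && q >= rpos && q < rpos + n) return(NA_character_)
      rpos <- rpos + n
    }
  }
  NA_character_
}

# map a junction's genomic ends onto transcript exon indices; NA when an
# end does not coincide with an annotated exon edge
junction_exons <- function(tx, donor_end, acceptor_start) {
  ex <- tx$exons
  gl <- match(donor_end, ex$end)       # genomic-left exon
  gr <- match(acceptor_start, ex$start)
  if (is.na(gl) || is.na(gr)) return(c(NA_integer_, NA_integer_))
  # transcript orientation: 5' exon first
  tl <- tx_exon_index(tx, gl); tr <- tx_exon_index(tx, gr)
  sort(c(tl, tr))
}

#' Classify the splicing outcome at a mutated boundary
#'
#' Partitions the informative reads at the event locality into outcome
#' kinds: `wild_type` (canonical junctions of the introns flanking the
#' affected exon), `exon_skip` (junction joining the exons flanking the
#' affected exon), `intron_retention` (reads continuously spanning the
#' mutated boundary), and `cryptic` (a junction sharing one end with a
#' canonical boundary of the mutated intron whose other end lies within
#' `cryptic_window` of — but not at — the other canonical boundary).
#' Percentages are integer percents of the total informative reads.
#'
#' @param annotation One splicing annotation row ([classify_variants()]).
#' @param tx The annotated transcript.
#' @param junctions Junction table ([junctions_from_alignments()] or
#'   [read_junction_table()]).
#' @param spanning Boundary-spanning read count at the mutated boundary
#'   ([boundary_spanning_count()]).
#' @param cryptic_window Maximal shift (bases) of a cryptic junction end
#'   from the canonical boundary.
#' @return List of class `sv_splice_event`: `status` (`"ok"` or
#'   `"not_expressed"`), `total` informative reads, and `outcomes` — a
#'   `data.frame` with `kind`, `detail`, `read_count`, `percent`.
#' @export
classify_splice_event <- function(annotation, tx, junctions, spanning = 0L,
                                  cryptic_window = 50L) {
  stopifnot(annotation$region == "splicing")
  A <- annotation$exon_index        # affected exon, transcript orientation
  n <- n_exons(tx)
  jx <- junctions[junctions$contig == tx$contig, , drop = FALSE]
  out <- data.frame(kind = character(), detail = character(),
                    read_count = integer(), stringsAsFactors = FALSE)
  add <- function(kind, detail, count) {
    if (count > 0) {
      out <<- rbind(out, data.frame(kind = kind, detail = detail,
                                    read_count = as.integer(count),
                                    stringsAsFactors = FALSE))
    }
  }
  canonical_count <- function(a, b) {
    if (a < 1L || b > n) return(0L)
    s <- 0L
    for (i in seq_len(nrow(jx))) {
      pair <- junction_exons(tx, jx$donor_end[i], jx$acceptor_start[i])
      if (!anyNA(pair) && pair[1] == a && pair[2] == b) {
        s <- s + jx$count[i]
      }
    }
    s
  }
  # wild type: canonical junctions of introns flanking the affected exon
  wt <- canonical_count(A - 1L, A) + canonical_count(A, A + 1L)
  add("wild_type", "", wt)
  # exon skip: flanking exons joined directly
  add("exon_skip", paste0("exon", A), canonical_count(A - 1L, A + 1L))
  # intron retention at the mutated boundary
  add("intron_retention",
      paste0("intron", if (annotation$side == "donor") A else A - 1L),
      spanning)
  # cryptic: mutated intron between transcript exons u and u+1
  u <- if (annotation$side == "donor") A else A - 1L
  if (u >= 1L && u + 1L <= n) {
    bnd <- splice_boundaries(tx)
    don <- bnd$genomic_position[bnd$kind == "donor" & bnd$exon_index == u]
    acc <- bnd$genomic_position[bnd$kind == "acceptor" &
                                  bnd$exon_index == u + 1L]
    for (i in seq_len(nrow(jx))) {
      de <- jx$donor_end[i]; as_ <- jx$acceptor_start[i]
      ends <- if (tx$strand == "+") c(de, as_) else c(as_, de)
      # ends[1] aligns with the donor boundary, ends[2] with the acceptor
      shift_t <- function(g, canon) {
        if (tx$strand == "+") g - canon else canon - g
      }
      if (ends[1] == don && ends[2] != acc &&
          abs(ends[2] - acc) <= cryptic_window) {
        add("cryptic", sprintf("acceptor%+d", shift_t(ends[2], acc)),
            jx$count[i])
      } else if (ends[2] == acc && ends[1] != don &&
                 abs(ends[1] - don) <= cryptic_window) {
        add("cryptic", sprintf("donor%+d", shift_t(ends[1], don)),
            jx$count[i])
      }
    }
  }
  total <- sum(out$read_count)
  if (total == 0L) {
    return(structure(list(status = "not_expressed", total = 0L,
                          outcomes = cbind(out, percent = integer(0))),
                     class = "sv_splice_event"))
  }
  out$percent <- integer_percent(out$read_count, total)
  structure(list(status = "ok", total = total, outcomes = out),
            class = "sv_splice_event")
}

#' @export
print.sv_splice_event <- function(x, ...) {
  if (x$status != "ok") {
    cat("<splice event> not expressed (0 informative reads)\n")
    return(invisible(x))
  }
  cat("<splice event> ", x$total, " informative reads\n", sep = "")
  for (i in seq_len(nrow(x$outcomes))) {
    o <- x$outcomes[i, ]
    cat(sprintf("  %-16s %-12s %4d reads  %3d%%\n",
                o$kind, o$detail, o$read_count, o$percent))
  }
  invisible(x)
}

#' Allele support among boundary-spanning reads
#'
#' @param alleles Per-read bases at the variant position (genomic strand),
#'   as returned by [boundary_spanning_count()].
#' @param ref_base,alt_base Genomic-strand variant alleles.
#' @return List with `mut_count`, `wt_count` and `exclusive_mutant`
#'   (mutant support with zero wild-type reads).
#' @export
allele_support <- function(alleles, ref_base, alt_base) {
  alleles <- alleles[!is.na(alleles)]
  mut <- sum(alleles == toupper(alt_base))
  wt <- sum(alleles == toupper(ref_base))
  list(mut_count = as.integer(mut), wt_count = as.integer(wt),
       exclusive_mutant = mut >= 1L && wt == 0L)
}

#' Fragments per kilobase of exon model per million mapped fragments
#'
#' @param fragment_count Fragments assigned to the gene.
#' @param exon_model_length_bp Length of the gene's exon-union model.
#' @param total_mapped_fragments Library size (mapped fragments).
#' @return FPKM (double).
#' @export
fpkm <- function(fragment_count, exon_model_length_bp,
                 total_mapped_fragments) {
  if (any(exon_model_length_bp <= 0)) stop("exon model length must be > 0")
  if (any(total_mapped_fragments <= 0)) stop("total fragments must be > 0")
  fragment_count /
    ((exon_model_length_bp / 1e3) * (total_mapped_fragments / 1e6))
}

#' Percentile rank of a value within a dataset
#'
#' Fraction of dataset values less than or equal to the value, times 100,
#' rounded to integer.
#'
#' @param value Query value.
#' @param dataset_values Non-empty numeric vector.
#' @return Integer percent.
#' @export
percentile_rank <- function(value, dataset_values) {
  if (!length(dataset_values)) stop("dataset is empty")
  as.integer(floor(100 * mean(dataset_values <= value) + 0.5))
}

#' Exon-union model length of a gene
#'
#' @param transcripts Transcript list (one or more isoforms of the gene).
#' @return Total bases in the union of all exons.
#' @export
exon_model_length <- function(transcripts) {
  if (inherits(transcripts, "sv_transcript")) transcripts <- list(transcripts)
  ex <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  ir <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
  sum(IRanges::width(ir))
}

#' Count fragments assigned to a gene
#'
#' Counts unique fragment names (a read pair counts once, an orphan read
#' once) among primary mapped records whose aligned blocks overlap any exon
#' of the gene, junction reads included.
#'
#' @param sam SAM records ([read_sam()]).
#' @param tx Transcript (gene model).
#' @return Integer fragment count.
#' @export
count_fragments <- function(sam, tx) {
  sam <- primary_mapped(sam)
  sam <- sam[sam$rname == tx$contig & valid_cigar(sam$cigar), ,
             drop = FALSE]
  if (!nrow(sam)) return(0L)
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    sam$cigar, pos = sam$pos)
  exr <- IRanges::IRanges(tx$exons$start, tx$exons$end)
  hit <- vapply(seq_len(nrow(sam)), function(i) {
    length(IRanges::findOverlaps(blocks[[i]], exr)) > 0L
  }, NA)
  length(unique(sam$qname[hit]))
}

#' Build a gene expression table with FPKM and percentile ranks
#'
#' @param counts `data.frame` with `gene_id`, `exon_model_length_bp`,
#'   `fragment_count`.
#' @param total_mapped_fragments Library size; defaults to the sum of the
#'   table's fragment counts.
#' @return Input plus `fpkm` and `percentile` (rank among all genes in the
#'   table, zero-FPKM genes included).
#' @export
expression_table <- function(counts, total_mapped_fragments = NULL) {
  if (is.null(total_mapped_fragments)) {
    total_mapped_fragments <- sum(counts$fragment_count)
  }
  counts$fpkm <- fpkm(counts$fragment_count, counts$exon_model_length_bp,
                      total_mapped_fragments)
  counts$percentile <- vapply(counts$fpkm, percentile_rank, 0L,
                              dataset_values = counts$fpkm)
  counts
}
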