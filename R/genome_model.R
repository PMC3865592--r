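# ---- reference genome ------------------------------------------------------

#' Load a reference genome from FASTA
#'
#' Reads a (multi-record) FASTA file into an in-memory genome object.
#' Sequences are uppercase-normalized and restricted to the A/C/G/T/N
#' alphabet; contig names are taken from the first whitespace-delimited
#' word of each header and must be unique.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return An object of class `sv_genome`: a named character vector of
#'   contig sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", ">c2", "NN"), fa)
#' g <- load_fasta(fa)
#' g[["c1"]]
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicated contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  names(x) <- nm
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("contig ", nm[bad][1], " contains characters outside A/C/G/T/N")
  }
  structure(x, class = "sv_genome")
}

#' @export
print.sv_genome <- function(x, ...) {
  cat("<sv_genome> ", length(x), " contig(s): ",
      paste0(names(x), " (", nchar(x), " bp)", collapse = ", "), "\n", sep = "")
  invisible(x)
}

contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  genome[[contig]]
}

#' Extract a genomic subsequence
#'
#' @param genome An `sv_genome`.
#' @param contig Contig name.
#' @param start,end 1-based inclusive genomic bounds.
#' @return Character scalar (plus-strand sequence).
#' @export
genome_slice <- function(genome, contig, start, end) {
  s <- contig_seq(genome, contig)
  if (start < 1L || end > nchar(s) || start > end) {
    stop("window [", start, ",", end, "] exceeds bounds of contig ",
         contig, " (length ", nchar(s), ")")
  }
  substr(s, start, end)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", toupper(b))
}

# ---- transcript model ------------------------------------------------------

#' Construct a transcript model
#'
#' A transcript is a strand-aware list of 1-based inclusive exon intervals
#' on one contig, with optional CDS bounds. Exons must be sorted by genomic
#' coordinate and non-overlapping; CDS bounds, when present, must each fall
#' on an exonic base.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (genomic order).
#' @param cds_start,cds_end Genomic positions bounding the coding region
#'   (`cds_start <= cds_end` regardless of strand), or `NA`.
#' @return An object of class `sv_transcript`.
#' @export
new_transcript <- function(transcript_id, gene_id, contig, strand, exons,
                           cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, " has zero exons")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end)) {
    stop("transcript ", transcript_id, " has an exon with start > end")
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("transcript ", transcript_id, " has overlapping exons")
  }
  tx <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    contig = contig, strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  ), class = "sv_transcript")
  if (!is.na(tx$cds_start) || !is.na(tx$cds_end)) {
    if (is.na(tx$cds_start) || is.na(tx$cds_end) || tx$cds_start > tx$cds_end) {
      stop("transcript ", transcript_id, ": invalid CDS bounds")
    }
    for (p in c(tx$cds_start, tx$cds_end)) {
      if (!any(p >= exons$start & p <= exons$end)) {
        stop("transcript ", transcript_id,
             ": CDS bound ", p, " is not on an exonic base")
      }
    }
  }
  tx
}

#' @export
print.sv_transcript <- function(x, ...) {
  cat("<sv_transcript> ", x$transcript_id, " (", x$gene_id, ") ",
      x$contig, ":", min(x$exons$start), "-", max(x$exons$end),
      " strand ", x$strand, ", ", nrow(x$exons), " exon(s)\n", sep = "")
  invisible(x)
}

has_cds <- function(tx) !is.na(tx$cds_start) && !is.na(tx$cds_end)

tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

n_exons <- function(tx) nrow(tx$exons)

# exon index in transcript orientation for genomic-order index j
tx_exon_index <- function(tx, j) {
  if (tx$strand == "+") j else n_exons(tx) + 1L - j
}

#' Load transcript models from a GTF file
#'
#' Honors `exon` and `CDS` features carrying `transcript_id` and `gene_id`
#' attributes; all other feature types are ignored. Exons are grouped per
#' transcript and sorted; CDS bounds are the min/max genomic coordinates of
#' the transcript's CDS features (absent when the transcript has no CDS
#' rows, in which case coding-coordinate naming is unavailable).
#'
#' @param path Path to a GTF file.
#' @return Named list of [new_transcript()] objects.
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("GTF file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GTF line ", which(nf < 9L)[1], ": fewer than 9 fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  keep <- m[, 3] %in% c("exon", "CDS")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("GTF contains no exon/CDS features: ", path)
  attr_get <- function(attrs, key) {
    pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
    hit <- regmatches(attrs, regexec(pat, attrs))
    vapply(hit, function(h) if (length(h) == 2L) h[2] else NA_character_, "")
  }
  tid <- attr_get(m[, 9], "transcript_id")
  gid <- attr_get(m[, 9], "gene_id")
  if (anyNA(tid)) stop("GTF exon/CDS feature without transcript_id attribute")
  out <- list()
  for (t in unique(tid)) {
    rows <- tid == t
    ex <- m[rows & m[, 3] == "exon", , drop = FALSE]
    cds <- m[rows & m[, 3] == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) {
      stop("transcript ", t, " has CDS features but zero exons")
    }
    strand <- unique(ex[, 7])
    contig <- unique(ex[, 1])
    if (length(strand) != 1L || length(contig) != 1L) {
      stop("transcript ", t, " spans multiple contigs or strands")
    }
    cs <- if (nrow(cds)) min(as.integer(cds[, 4])) else NA_integer_
    ce <- if (nrow(cds)) max(as.integer(cds[, 5])) else NA_integer_
    out[[t]] <- new_transcript(
      transcript_id = t, gene_id = gid[rows][1],
      contig = contig, strand = strand,
      exons = data.frame(start = as.integer(ex[, 4]),
                         end = as.integer(ex[, 5])),
      cds_start = cs, cds_end = ce
    )
  }
  out
}

# ---- splice boundaries -----------------------------------------------------

#' Enumerate donor/acceptor splice boundaries of a transcript
#'
#' A donor boundary is the last exonic base of a non-terminal exon (in
#' transcript orientation); an acceptor boundary is the first exonic base of
#' a non-initial exon.
#'
#' @param tx An `sv_transcript`.
#' @return `data.frame` with columns `transcript_id`, `exon_index` (1-based,
#'   transcript orientation; the exon owning the boundary), `kind`
#'   (`"donor"`/`"acceptor"`), `genomic_position`.
#' @export
splice_boundaries <- function(tx) {
  n <- n_exons(tx)
  if (n == 1L) {
    return(data.frame(transcript_id = character(), exon_index = integer(),
                      kind = character(), genomic_position = integer()))
  }
  ex <- tx$exons
  if (tx$strand == "+") {
    don <- data.frame(exon_index = seq_len(n - 1L), kind = "donor",
                      genomic_position = ex$end[seq_len(n - 1L)])
    acc <- data.frame(exon_index = 2:n, kind = "acceptor",
                      genomic_position = ex$start[2:n])
  } else {
    # transcript exon t corresponds to genomic exon j = n + 1 - t
    don <- data.frame(exon_index = seq_len(n - 1L), kind = "donor",
                      genomic_position = ex$start[n + 1L - seq_len(n - 1L)])
    acc <- data.frame(exon_index = 2:n, kind = "acceptor",
                      genomic_position = ex$end[n + 1L - (2:n)])
  }
  out <- rbind(don, acc)
  out <- data.frame(transcript_id = tx$transcript_id, out)
  out[order(out$exon_index, out$kind), ]
}

# ---- coding coordinates ----------------------------------------------------

coding_intervals <- function(tx) {
  if (!has_cds(tx)) stop("transcript ", tx$transcript_id, " has no CDS bounds")
  ex <- tx$exons
  s <- pmax(ex$start, tx$cds_start)
  e <- pmin(ex$end, tx$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

# cds coordinate (1-based from the CDS 5' end, transcript orientation) of a
# genomic position that lies on a coding exonic base
cds_offset_of <- function(tx, g) {
  ci <- coding_intervals(tx)
  on <- g >= ci$start & g <= ci$end
  if (!any(on)) stop("position ", g, " is not a coding exonic base of ",
                     tx$transcript_id)
  if (tx$strand == "+") {
    sum(pmax(0L, pmin(ci$end, g) - ci$start + 1L))
  } else {
    sum(pmax(0L, ci$end - pmax(ci$start, g) + 1L))
  }
}

#' Map a genomic position to coding (c.) coordinates
#'
#' Exonic positions inside the CDS map to `cds_offset = n, intron_offset = 0`
#' (written `c.n`). Intronic positions map to the coding offset of the
#' nearest exon edge, with a signed `intron_offset`: `+k` for the k-th base
#' past a donor, `-k` for the k-th base before an acceptor, in transcript
#' orientation. Ties between the two edges go to the donor side.
#'
#' @param tx An `sv_transcript` with CDS bounds.
#' @param genomic_position 1-based genomic position within the transcript
#'   span.
#' @return List with `cds_offset`, `intron_offset` and a formatted `label`
#'   such as `"c.1312+5"`.
#' @export
cdna_coordinate <- function(tx, genomic_position) {
  g <- as.integer(genomic_position)
  sp <- tx_span(tx)
  if (g < sp[1] || g > sp[2]) {
    stop("position ", g, " is outside the span of ", tx$transcript_id,
         " (", sp[1], "-", sp[2], ")")
  }
  ex <- tx$exons
  in_exon <- which(g >= ex$start & g <= ex$end)
  if (length(in_exon)) {
    n <- cds_offset_of(tx, g)  # errors for UTR positions (unsupported)
    return(list(cds_offset = n, intron_offset = 0L,
                label = paste0("c.", n)))
  }
  # intronic: find flanking genomic exons j, j+1
  j <- max(which(ex$end < g))
  if (tx$strand == "+") {
    donor_pos <- ex$end[j]; acceptor_pos <- ex$start[j + 1L]
    d_don <- g - donor_pos; d_acc <- acceptor_pos - g
  } else {
    donor_pos <- ex$start[j + 1L]; acceptor_pos <- ex$end[j]
    d_don <- donor_pos - g; d_acc <- g - acceptor_pos
  }
  if (d_don <= d_acc) {
    n <- cds_offset_of(tx, donor_pos)
    list(cds_offset = n, intron_offset = d_don,
         label = paste0("c.", n, "+", d_don))
  } else {
    n <- cds_offset_of(tx, acceptor_pos)
    list(cds_offset = n, intron_offset = -d_acc,
         label = paste0("c.", n, "-", d_acc))
  }
}

#' Map coding (c.) coordinates back to a genomic position
#'
#' Inverse of [cdna_coordinate()].
#'
#' @param tx An `sv_transcript` with CDS bounds.
#' @param cds_offset 1-based coding offset.
#' @param intron_offset Signed intronic offset (0 for exonic positions).
#' @return Genomic position (integer).
#' @export
genomic_coordinate <- function(tx, cds_offset, intron_offset = 0L) {
  ci <- coding_intervals(tx)
  if (tx$strand == "-") ci <- ci[rev(seq_len(nrow(ci))), , drop = FALSE]
  lens <- ci$end - ci$start + 1L
  cum <- cumsum(lens)
  if (cds_offset < 1L || cds_offset > sum(lens)) {
    stop("cds_offset ", cds_offset, " outside CDS of ", tx$transcript_id)
  }
  k <- which(cds_offset <= cum)[1]
  into <- cds_offset - c(0L, cum)[k] - 1L
  g <- if (tx$strand == "+") ci$start[k] + into else ci$end[k] - into
  step <- if (tx$strand == "+") 1L else -1L
  as.integer(g + step * intron_offset)
}

# ---- scoring windows -------------------------------------------------------

#' Extract the nucleotide window around a splice boundary
#'
#' Returns the window sequence in transcript orientation (minus-strand
#' transcripts are reverse-complemented). Donor windows read exon to intron:
#' `donor_exonic` exonic bases then `donor_intronic` intronic bases.
#' Acceptor windows read intron to exon: `acceptor_intronic` intronic bases
#' then `acceptor_exonic` exonic bases.
#'
#' @param genome An `sv_genome`.
#' @param tx The transcript owning the boundary.
#' @param boundary One row of [splice_boundaries()] (or a list with `kind`
#'   and `genomic_position`).
#' @param donor_exonic,donor_intronic,acceptor_intronic,acceptor_exonic
#'   Window geometry in bases.
#' @return Character scalar window sequence.
#' @export
boundary_window <- function(genome, tx, boundary,
                            donor_exonic = 3L, donor_intronic = 6L,
                            acceptor_intronic = 20L, acceptor_exonic = 3L) {
  p <- as.integer(boundary$genomic_position)
  kind <- boundary$kind
  plus <- tx$strand == "+"
  rng <- if (kind == "donor") {
    if (plus) c(p - donor_exonic + 1L, p + donor_intronic)
    else c(p - donor_intronic, p + donor_exonic - 1L)
  } else if (kind == "acceptor") {
    if (plus) c(p - acceptor_intronic, p + acceptor_exonic - 1L)
    else c(p - acceptor_exonic + 1L, p + acceptor_intronic)
  } else stop("boundary kind must be 'donor' or 'acceptor'")
  s <- genome_slice(genome, tx$contig, rng[1], rng[2])
  if (plus) s else revcomp(s)
}
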