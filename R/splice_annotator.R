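# Selection and annotation of somatic variants near splice junctions:
# region class (exonic / splicing / intronic / intergenic), donor/acceptor
# side with signed intronic offset in transcript orientation, coding-style
# c. naming, and exclusion filters (known variants, segmental duplications)
# plus conservation annotation.

#' Annotator parameters
#'
#' @param splice_window_bp Intronic distance (bases, inclusive at both ends)
#'   from an exon-intron boundary within which a variant is classed
#'   `splicing`.
#' @param require_absent_from_known Drop variants present in the known
#'   (dbSNP-style) set.
#' @param exclude_segdup Drop variants overlapping segmental-duplication
#'   intervals.
#' @param annotate_conservation Set the `conserved` flag from conservation
#'   intervals (annotation only unless `conservation_hard_filter`).
#' @param conservation_hard_filter Also drop non-conserved variants
#'   (off by default: conservation is preferred, not required).
#' @return List of class `sv_annotator_params`.
#' @export
annotator_params <- function(splice_window_bp = 20L,
                             require_absent_from_known = TRUE,
                             exclude_segdup = TRUE,
                             annotate_conservation = TRUE,
                             conservation_hard_filter = FALSE) {
  stopifnot(splice_window_bp >= 1L)
  structure(list(splice_window_bp = as.integer(splice_window_bp),
                 require_absent_from_known = require_absent_from_known,
                 exclude_segdup = exclude_segdup,
                 annotate_conservation = annotate_conservation,
                 conservation_hard_filter = conservation_hard_filter),
            class = "sv_annotator_params")
}

annotation_row <- function(variant, transcript_id = NA_character_,
                           gene_id = NA_character_, strand = NA_character_,
                           region = "intergenic", side = "none",
                           offset = NA_integer_,
                           boundary_position = NA_integer_,
                           exon_index = NA_integer_,
                           hgvs_c = NA_character_) {
  cbind(variant,
        data.frame(transcript_id = transcript_id, gene_id = gene_id,
                   strand = strand, region = region, side = side,
                   offset = offset, boundary_position = boundary_position,
                   exon_index = exon_index, hgvs_c = hgvs_c,
                   conserved = NA, in_segdup = NA, known = NA,
                   stringsAsFactors = FALSE))
}

#' Classify somatic variants against transcript models
#'
#' Emits one annotation per transcript overlapping each variant (by genomic
#' span): `exonic` when the position is on an exonic base, `splicing` when
#' intronic within `splice_window_bp` of the nearest exon-intron boundary
#' (side and signed offset in transcript orientation: `+k` past a donor,
#' `-k` before an acceptor; the nearest boundary wins, ties to the donor),
#' `intronic` otherwise, and a single `intergenic` row when no transcript
#' overlaps. The c. name is attached for splicing variants of transcripts
#' with CDS bounds.
#'
#' @param variants Somatic variant `data.frame` (from [cross_match()]).
#' @param transcripts List of transcripts ([load_gene_models()]).
#' @param params [annotator_params()].
#' @return Annotation `data.frame`.
#' @export
classify_variants <- function(variants, transcripts,
                              params = annotator_params()) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    hit <- FALSE
    for (tx in transcripts) {
      sp <- tx_span(tx)
      if (v$contig != tx$contig || v$position < sp[1] || v$position > sp[2]) {
        next
      }
      hit <- TRUE
      rows[[length(rows) + 1L]] <- classify_one(v, tx, params)
    }
    if (!hit) rows[[length(rows) + 1L]] <- annotation_row(v)
  }
  if (!length(rows)) {
    extra <- data.frame(
      transcript_id = character(), gene_id = character(),
      strand = character(), region = character(), side = character(),
      offset = integer(), boundary_position = integer(),
      exon_index = integer(), hgvs_c = character(), conserved = logical(),
      in_segdup = logical(), known = logical(), stringsAsFactors = FALSE)
    return(cbind(variants[0, , drop = FALSE], extra))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

classify_one <- function(v, tx, params) {
  g <- v$position
  ex <- tx$exons
  if (any(g >= ex$start & g <= ex$end)) {
    return(annotation_row(v, tx$transcript_id, tx$gene_id, tx$strand,
                          region = "exonic"))
  }
  j <- max(which(ex$end < g))
  if (tx$strand == "+") {
    donor_pos <- ex$end[j]; acceptor_pos <- ex$start[j + 1L]
    d_don <- g - donor_pos; d_acc <- acceptor_pos - g
    donor_exon <- tx_exon_index(tx, j)
    acceptor_exon <- tx_exon_index(tx, j + 1L)
  } else {
    donor_pos <- ex$start[j + 1L]; acceptor_pos <- ex$end[j]
    d_don <- donor_pos - g; d_acc <- g - acceptor_pos
    donor_exon <- tx_exon_index(tx, j + 1L)
    acceptor_exon <- tx_exon_index(tx, j)
  }
  if (d_don <= d_acc) {
    side <- "donor"; off <- d_don; bpos <- donor_pos; exi <- donor_exon
  } else {
    side <- "acceptor"; off <- -d_acc; bpos <- acceptor_pos
    exi <- acceptor_exon
  }
  if (abs(off) > params$splice_window_bp) {
    return(annotation_row(v, tx$transcript_id, tx$gene_id, tx$strand,
                          region = "intronic"))
  }
  ann <- annotation_row(v, tx$transcript_id, tx$gene_id, tx$strand,
                        region = "splicing", side = side, offset = off,
                        boundary_position = bpos, exon_index = exi)
  if (has_cds(tx)) ann$hgvs_c <- hgvs_string(ann, tx)
  ann
}

#' Format the HGVS-like c. name of a splice-region variant
#'
#' `c.{n}{+k|-k}{REF}>{ALT}` where `n` is the coding offset of the exon edge
#' and `k` the intronic offset. Under the default `genomic` allele
#' convention the plus-strand alleles are printed even for minus-strand
#' transcripts; `transcript` prints strand-corrected (complemented) alleles.
#'
#' @param annotation One annotation row (region `splicing` or `exonic`).
#' @param tx The annotated transcript (CDS bounds required).
#' @param allele_convention `"genomic"` (default) or `"transcript"`.
#' @return Character scalar.
#' @export
hgvs_string <- function(annotation, tx,
                        allele_convention = c("genomic", "transcript")) {
  allele_convention <- match.arg(allele_convention)
  if (!has_cds(tx)) {
    stop("cannot name variant: transcript ", tx$transcript_id,
         " has no CDS bounds")
  }
  cc <- cdna_coordinate(tx, annotation$position)
  ref <- annotation$ref_base
  alt <- annotation$alt_base
  if (allele_convention == "transcript" && tx$strand == "-") {
    ref <- complement_base(ref)
    alt <- complement_base(alt)
  }
  paste0(cc$label, ref, ">", alt)
}

# ---- interval / known-set inputs ------------------------------------------

#' Read a BED file of genomic intervals
#'
#' 0-based half-open BED converted to 1-based inclusive coordinates.
#'
#' @param path BED path (first three columns honored).
#' @return `data.frame` with `contig`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  st <- suppressWarnings(as.integer(vapply(f, `[`, "", 2)))
  en <- suppressWarnings(as.integer(vapply(f, `[`, "", 3)))
  if (anyNA(st) || anyNA(en)) {
    stop("malformed BED line ", which(is.na(st) | is.na(en))[1],
         ": non-numeric coordinates")
  }
  data.frame(contig = vapply(f, `[`, "", 1), start = st + 1L, end = en,
             stringsAsFactors = FALSE)
}

#' Read a known-variant set (VCF or 4-column TSV)
#'
#' VCF input (`.vcf`): CHROM/POS/REF/ALT columns. TSV input: columns
#' contig, position, ref, alt.
#'
#' @param path Input path.
#' @return `data.frame` with `contig`, `position`, `ref`, `alt`.
#' @export
read_known_variants <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), position = integer(),
                      ref = character(), alt = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path)
  ref_i <- if (is_vcf) 4L else 3L
  alt_i <- if (is_vcf) 5L else 4L
  need <- max(2L, ref_i, alt_i)
  bad <- which(lengths(f) < need)
  if (length(bad)) stop("malformed known-variant line ", bad[1])
  data.frame(contig = vapply(f, `[`, "", 1),
             position = as.integer(vapply(f, `[`, "", 2)),
             ref = toupper(vapply(f, `[`, "", ref_i)),
             alt = toupper(vapply(f, `[`, "", alt_i)),
             stringsAsFactors = FALSE)
}

in_intervals <- function(contig, position, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(FALSE, length(position)))
  }
  vapply(seq_along(position), function(i) {
    any(intervals$contig == contig[i] &
          intervals$start <= position[i] & intervals$end >= position[i])
  }, NA)
}

#' Apply exclusion filters and conservation annotation
#'
#' Drops variants present in the known set and variants inside segmental
#' duplication intervals (when the respective parameter flags are set) and
#' annotates conservation; non-conserved variants are retained (flag only)
#' unless the conservation hard filter is enabled.
#'
#' @param annotations Annotation `data.frame` (or any frame with `contig`,
#'   `position`, `ref_base`, `alt_base`).
#' @param known Known-variant `data.frame` ([read_known_variants()]) or
#'   `NULL`.
#' @param segdup,conserved Interval `data.frame`s ([read_bed()]) or `NULL`.
#' @param params [annotator_params()].
#' @return Filtered, flag-annotated `data.frame`.
#' @export
apply_exclusions <- function(annotations, known = NULL, segdup = NULL,
                             conserved = NULL, params = annotator_params()) {
  if (!nrow(annotations)) return(annotations)
  a <- annotations
  is_known <- if (is.null(known) || !nrow(known)) rep(FALSE, nrow(a)) else {
    vapply(seq_len(nrow(a)), function(i) {
      any(known$contig == a$contig[i] & known$position == a$position[i] &
            known$ref == a$ref_base[i] & known$alt == a$alt_base[i])
    }, NA)
  }
  in_sd <- in_intervals(a$contig, a$position, segdup)
  cons <- in_intervals(a$contig, a$position, conserved)
  a$known <- is_known
  a$in_segdup <- in_sd
  if (params$annotate_conservation) a$conserved <- cons
  keep <- rep(TRUE, nrow(a))
  if (params$require_absent_from_known) keep <- keep & !is_known
  if (params$exclude_segdup) keep <- keep & !in_sd
  if (params$conservation_hard_filter) keep <- keep & cons
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write splice annotations as TSV
#'
#' @param annotations Annotation `data.frame`.
#' @param path Output path.
#' @export
write_annotations_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back an annotations TSV written by [write_annotations_tsv()]
#'
#' @param path TSV path.
#' @return Annotation `data.frame`.
#' @export
read_annotations_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(contig = "character",
                                   transcript_id = "character"))
}
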