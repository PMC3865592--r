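# Hard-filter somatic substitution caller over matched tumor/normal pileups.
# A site is called when the tumor carries a well-supported non-reference
# allele that the matched normal lacks (or carries at a tolerated trace).

#' Caller parameters
#'
#' Defaults encode the pipeline's hard filters: tumor coverage >= 20,
#' alternate read count >= 6, alternate fraction >= 25% (integer percent),
#' base quality Phred >= 30, and a matched-normal alternate fraction
#' tolerated up to 10%.
#'
#' @param min_tumor_depth Minimum tumor read coverage.
#' @param min_alt_count Minimum alternate-allele read count in the tumor.
#' @param min_alt_percent Minimum tumor alternate integer percent.
#' @param min_base_quality Minimum Phred base quality for a read call to
#'   count toward an allele.
#' @param max_normal_alt_percent Maximum tolerated alternate integer percent
#'   in the matched normal.
#' @param min_normal_depth Minimum normal coverage for a site to be
#'   callable; with the default of 1, sites absent from the normal pileup
#'   are never called.
#' @return List of class `sv_caller_params`.
#' @export
caller_params <- function(min_tumor_depth = 20L, min_alt_count = 6L,
                          min_alt_percent = 25L, min_base_quality = 30L,
                          max_normal_alt_percent = 10L,
                          min_normal_depth = 1L) {
  p <- list(min_tumor_depth = min_tumor_depth,
            min_alt_count = min_alt_count,
            min_alt_percent = min_alt_percent,
            min_base_quality = min_base_quality,
            max_normal_alt_percent = max_normal_alt_percent,
            min_normal_depth = min_normal_depth)
  stopifnot(all(unlist(p) >= 0),
            min_alt_percent <= 100, max_normal_alt_percent <= 100)
  structure(p, class = "sv_caller_params")
}

#' Quality-filtered allele counts at a pileup site
#'
#' Counts per-read base calls with Phred quality at or above the threshold.
#' Reference matches are counted under the reference base; deletion
#' placeholders (`*`) never count.
#'
#' @param site A pileup site.
#' @param min_base_quality Phred threshold.
#' @return Named integer vector of counts over bases seen.
#' @export
allele_counts <- function(site, min_base_quality = 30L) {
  keep <- site$quals >= min_base_quality & site$bases %in%
    c("A", "C", "G", "T", "N")
  b <- site$bases[keep]
  if (!length(b)) return(integer(0))
  tab <- table(b)
  stats::setNames(as.integer(tab), names(tab))
}

#' Integer mutation percent
#'
#' `round(100 * count / depth)` with halves rounded away from zero, the
#' rounding under which the printed depth/count pairs of the source tables
#' reproduce their printed fractions.
#'
#' @param count Alternate read count.
#' @param depth Total read depth (> 0).
#' @return Integer in `[0, 100]`.
#' @export
integer_percent <- function(count, depth) {
  if (any(depth <= 0)) stop("integer_percent undefined at depth 0")
  stopifnot(all(count >= 0), all(count <= depth))
  as.integer(floor(100 * count / depth + 0.5))
}

#' Call one tumor/normal site pair
#'
#' Emits the highest-count non-reference tumor allele when every hard filter
#' in `params` passes. Ties between equally supported alternate alleles go
#' to the lexicographically smaller base and flag the site multi-allelic.
#'
#' @param tumor Tumor pileup site.
#' @param normal Matched normal pileup site at the same coordinate, or
#'   `NULL` when the normal pileup lacks the site.
#' @param params [caller_params()].
#' @return One-row `data.frame` (a somatic variant) or `NULL`.
#' @export
call_site <- function(tumor, normal = NULL, params = caller_params()) {
  if (!is.null(normal) &&
      (tumor$contig != normal$contig || tumor$position != normal$position)) {
    stop("tumor/normal pairing error: ", tumor$contig, ":", tumor$position,
         " vs ", normal$contig, ":", normal$position)
  }
  if (tumor$depth < params$min_tumor_depth) return(NULL)
  cnt <- allele_counts(tumor, params$min_base_quality)
  alt <- cnt[setdiff(names(cnt), c(tumor$ref_base, "N"))]
  if (!length(alt)) return(NULL)
  best <- max(alt)
  cand <- sort(names(alt)[alt == best])
  alt_base <- cand[1]
  multi <- length(cand) > 1L
  if (best < params$min_alt_count) return(NULL)
  t_pct <- integer_percent(best, tumor$depth)
  if (t_pct < params$min_alt_percent) return(NULL)
  if (is.null(normal) || normal$depth < params$min_normal_depth) return(NULL)
  n_cnt <- allele_counts(normal, params$min_base_quality)
  n_alt <- if (alt_base %in% names(n_cnt)) n_cnt[[alt_base]] else 0L
  n_pct <- integer_percent(n_alt, normal$depth)
  if (n_pct > params$max_normal_alt_percent) return(NULL)
  data.frame(contig = tumor$contig, position = tumor$position,
             ref_base = tumor$ref_base, alt_base = alt_base,
             tumor_depth = tumor$depth, tumor_alt_count = as.integer(best),
             tumor_percent = t_pct,
             normal_depth = normal$depth,
             normal_alt_count = as.integer(n_alt), normal_percent = n_pct,
             multi_allelic = multi,
             stringsAsFactors = FALSE)
}

check_sorted <- function(sites, label) {
  if (length(sites) < 2L) return(invisible())
  ctg <- vapply(sites, `[[`, "", "contig")
  pos <- vapply(sites, `[[`, 0L, "position")
  blocks <- rle(ctg)$values
  if (anyDuplicated(blocks)) {
    stop(label, " pileup is not sorted: contig blocks repeat")
  }
  for (ct in blocks) {
    p <- pos[ctg == ct]
    if (is.unsorted(p, strictly = TRUE)) {
      stop(label, " pileup is not sorted at contig ", ct)
    }
  }
  invisible()
}

#' Cross-match tumor and normal pileups for somatic variants
#'
#' One-pass merge-join over coordinate-sorted pileups; every emitted variant
#' satisfies [call_site()] under `params`, in coordinate order.
#'
#' @param tumor_sites,normal_sites Lists of pileup sites (sorted by contig
#'   then position).
#' @param params [caller_params()].
#' @return `data.frame` of somatic variants (zero rows when none pass).
#' @export
cross_match <- function(tumor_sites, normal_sites,
                        params = caller_params()) {
  check_sorted(tumor_sites, "tumor")
  check_sorted(normal_sites, "normal")
  key <- function(s) paste0(s$contig, ":", s$position)
  nkeys <- vapply(normal_sites, key, "")
  rows <- list()
  for (t in tumor_sites) {
    i <- match(key(t), nkeys)
    v <- call_site(t, if (is.na(i)) NULL else normal_sites[[i]], params)
    if (!is.null(v)) rows[[length(rows) + 1L]] <- v
  }
  if (!length(rows)) return(empty_variants())
  do.call(rbind, rows)
}

empty_variants <- function() {
  data.frame(contig = character(), position = integer(),
             ref_base = character(), alt_base = character(),
             tumor_depth = integer(), tumor_alt_count = integer(),
             tumor_percent = integer(), normal_depth = integer(),
             normal_alt_count = integer(), normal_percent = integer(),
             multi_allelic = logical(), stringsAsFactors = FALSE)
}

#' Format the two-number locus string of a variant
#'
#' `"contig,pos-1,pos,1,REF/ALT"` — a 0-based/1-based coordinate pair
#' bracketing the mutated base.
#'
#' @param variants Somatic variant `data.frame`.
#' @return Character vector.
#' @export
variant_locus <- function(variants) {
  paste(variants$contig, variants$position - 1L, variants$position, 1L,
        paste0(variants$ref_base, "/", variants$alt_base), sep = ",")
}

#' Write somatic variants as a summary TSV
#'
#' Columns mirror the tumor/normal reporting layout: locus, alleles, depths,
#' alternate counts and integer percents for both samples.
#'
#' @param variants Somatic variant `data.frame`.
#' @param path Output path.
#' @export
write_variants_tsv <- function(variants, path) {
  out <- data.frame(
    locus = if (nrow(variants)) variant_locus(variants) else character(),
    contig = variants$contig, position = variants$position,
    ref = variants$ref_base, alt = variants$alt_base,
    coverage_t = variants$tumor_depth, coverage_n = variants$normal_depth,
    alt_count_t = variants$tumor_alt_count,
    alt_count_n = variants$normal_alt_count,
    fraction_t = variants$tumor_percent, fraction_n = variants$normal_percent,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write somatic variants as VCF 4.2
#'
#' Single-record-per-variant sites-only VCF; tumor/normal depths, counts and
#' percents travel in INFO.
#'
#' @param variants Somatic variant `data.frame`.
#' @param path Output path.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TDP,Number=1,Type=Integer,Description=\"Tumor depth\">",
           "##INFO=<ID=TAC,Number=1,Type=Integer,Description=\"Tumor alt count\">",
           "##INFO=<ID=TPC,Number=1,Type=Integer,Description=\"Tumor alt percent\">",
           "##INFO=<ID=NDP,Number=1,Type=Integer,Description=\"Normal depth\">",
           "##INFO=<ID=NAC,Number=1,Type=Integer,Description=\"Normal alt count\">",
           "##INFO=<ID=NPC,Number=1,Type=Integer,Description=\"Normal alt percent\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) {
    paste(variants$contig, variants$position, ".", variants$ref_base,
          variants$alt_base, ".", "PASS",
          sprintf("TDP=%d;TAC=%d;TPC=%d;NDP=%d;NAC=%d;NPC=%d",
                  variants$tumor_depth, variants$tumor_alt_count,
                  variants$tumor_percent, variants$normal_depth,
                  variants$normal_alt_count, variants$normal_percent),
          sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read back a variants TSV written by [write_variants_tsv()]
#'
#' @param path TSV path.
#' @return Somatic variant `data.frame`.
#' @export
read_variants_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(locus = "character"))
  data.frame(contig = as.character(d$contig), position = d$position,
             ref_base = d$ref, alt_base = d$alt,
             tumor_depth = d$coverage_t, tumor_alt_count = d$alt_count_t,
             tumor_percent = d$fraction_t, normal_depth = d$coverage_n,
             normal_alt_count = d$alt_count_n,
             normal_percent = d$fraction_n,
             multi_allelic = FALSE, stringsAsFactors = FALSE)
}
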