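# Self-contained fixture generator: toy genome + gene model + tumor/normal
# pileups + spliced RNA-seq SAM + exclusion BEDs + truth JSON for named
# worked-example scenarios and randomized planted scenarios. Wild-type
# splice sites are planted as the training-set consensus windows, so the
# bundled models recognize every constitutive boundary; scenario introns
# are long enough that donor and acceptor windows never collide.

SCENARIO_NAMES <- c("gnaq_skip", "hook1_retention", "abcc3_cryptic",
                    "apc_homozygous", "klhdc1_low_expression",
                    "dnah9_not_expressed", "negative_control")

# per-scenario plan: exon lengths are fully coding, so cumulative exon
# lengths reproduce the intended c. coordinates at the mutated boundary
scenario_plan <- function(name) {
  switch(name,
    gnaq_skip = list(
      gene = "GNAQ", strand = "-",
      exon_lens = c(150L, 150L, 150L, 150L, 135L, 200L),
      side = "donor", affected_exon = 5L, offset = 1L, alt_tx = "A",
      tumor_depth = 23L, tumor_alt = 8L, normal_depth = 65L, normal_alt = 0L,
      junctions = list(c(4L, 6L, 28L), c(5L, 6L, 5L), c(4L, 5L, 3L)),
      spanning = 0L, spanning_mutant = FALSE, cryptic = NULL),
    hook1_retention = list(
      gene = "HOOK1", strand = "+",
      exon_lens = c(554L, 554L, 553L, 300L),
      side = "acceptor", affected_exon = 4L, offset = -1L, alt_tx = "A",
      tumor_depth = 186L, tumor_alt = 87L,
      normal_depth = 153L, normal_alt = 0L,
      junctions = list(c(3L, 4L, 7L)),
      spanning = 5L, spanning_mutant = TRUE, cryptic = NULL),
    abcc3_cryptic = list(
      gene = "ABCC3", strand = "+",
      exon_lens = c(891L, 891L, 250L, 250L),
      side = "acceptor", affected_exon = 3L, offset = -1L, alt_tx = "A",
      tumor_depth = 59L, tumor_alt = 30L, normal_depth = 36L, normal_alt = 0L,
      junctions = list(c(2L, 3L, 58L)),
      spanning = 37L, spanning_mutant = FALSE,
      cryptic = list(shift = 5L, count = 5L)),
    apc_homozygous = list(
      gene = "APC", strand = "+",
      exon_lens = c(656L, 656L, 300L),
      side = "donor", affected_exon = 2L, offset = 5L, alt_tx = "A",
      tumor_depth = 90L, tumor_alt = 73L, normal_depth = 63L, normal_alt = 0L,
      junctions = list(), spanning = 0L, spanning_mutant = FALSE,
      cryptic = NULL),
    klhdc1_low_expression = list(
      gene = "KLHDC1", strand = "+",
      exon_lens = c(567L, 300L, 200L),
      side = "acceptor", affected_exon = 2L, offset = -2L, alt_tx = "G",
      tumor_depth = 93L, tumor_alt = 48L, normal_depth = 14L, normal_alt = 1L,
      junctions = list(c(1L, 2L, 2L), c(2L, 3L, 1L)),
      spanning = 0L, spanning_mutant = FALSE, cryptic = NULL),
    dnah9_not_expressed = list(
      gene = "DNAH9", strand = "+",
      exon_lens = c(5121L, 5121L, 400L),
      side = "donor", affected_exon = 2L, offset = 5L, alt_tx = "A",
      tumor_depth = 37L, tumor_alt = 19L, normal_depth = 43L, normal_alt = 0L,
      junctions = list(), spanning = 0L, spanning_mutant = FALSE,
      cryptic = NULL),
    negative_control = list(
      gene = "CTRL", strand = "+",
      exon_lens = c(300L, 300L, 300L),
      side = NA, affected_exon = NA_integer_, offset = NA_integer_,
      alt_tx = NA_character_,
      tumor_depth = 0L, tumor_alt = 0L, normal_depth = 0L, normal_alt = 0L,
      junctions = list(c(1L, 2L, 10L), c(2L, 3L, 12L)),
      spanning = 0L, spanning_mutant = FALSE, cryptic = NULL),
    stop("unknown scenario '", name, "'; valid names: ",
         paste(SCENARIO_NAMES, collapse = ", "))
  )
}

random_dna <- function(n) {
  paste0(sample(BASES, n, replace = TRUE), collapse = "")
}

# build a contig carrying one transcript whose boundaries are all planted
# consensus splice sites; returns list(genome, tx)
build_toy_gene <- function(gene, strand, exon_lens, contig = "chrS",
                           intron_len = 60L, flank = 80L, seed = 1L) {
  n <- length(exon_lens)
  glens <- if (strand == "+") exon_lens else rev(exon_lens)
  starts <- integer(n); ends <- integer(n)
  cur <- flank + 1L
  for (j in seq_len(n)) {
    starts[j] <- cur
    ends[j] <- cur + glens[j] - 1L
    cur <- ends[j] + intron_len + 1L
  }
  total <- ends[n] + flank
  chars <- withr::with_seed(seed, strsplit(random_dna(total), "")[[1]])
  tx <- new_transcript(paste0(gene, "-t1"), gene, contig, strand,
                       data.frame(start = starts, end = ends),
                       cds_start = starts[1], cds_end = ends[n])
  bnd <- splice_boundaries(tx)
  for (i in seq_len(nrow(bnd))) {
    b <- bnd[i, ]
    plus <- strand == "+"
    if (b$kind == "donor") {
      w <- DONOR_CONSENSUS
      rng <- if (plus) c(b$genomic_position - 2L, b$genomic_position + 6L)
        else c(b$genomic_position - 6L, b$genomic_position + 2L)
    } else {
      w <- ACCEPTOR_CONSENSUS
      rng <- if (plus) c(b$genomic_position - 20L, b$genomic_position + 2L)
        else c(b$genomic_position - 2L, b$genomic_position + 20L)
    }
    if (!plus) w <- revcomp(w)
    chars[rng[1]:rng[2]] <- strsplit(w, "")[[1]]
  }
  genome <- structure(stats::setNames(paste0(chars, collapse = ""), contig),
                      class = "sv_genome")
  list(genome = genome, tx = tx)
}

# genomic position of an intronic offset relative to a boundary
offset_position <- function(tx, boundary, offset) {
  step <- if (tx$strand == "+") 1L else -1L
  if (boundary$kind == "donor") {
    boundary$genomic_position + step * offset
  } else {
    boundary$genomic_position + step * offset
  }
}

# genomic (donor_end, acceptor_start) pair of the junction joining
# transcript exons a -> b (a < b in transcript orientation)
junction_genomic <- function(tx, a, b) {
  gi <- sort(c(
    if (tx$strand == "+") a else n_exons(tx) + 1L - a,
    if (tx$strand == "+") b else n_exons(tx) + 1L - b))
  c(donor_end = tx$exons$end[gi[1]], acceptor_start = tx$exons$start[gi[2]])
}

write_fasta_file <- function(genome, path, width = 70L) {
  out <- character(0)
  for (nm in names(genome)) {
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, paste0(">", nm),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

write_gtf_file <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                     tx$gene_id, tx$transcript_id)
    for (i in seq_len(nrow(tx$exons))) {
      lines <- c(lines, paste(tx$contig, "toy", "exon",
                              tx$exons$start[i], tx$exons$end[i],
                              ".", tx$strand, ".", attrs, sep = "\t"))
      if (has_cds(tx)) {
        cs <- max(tx$exons$start[i], tx$cds_start)
        ce <- min(tx$exons$end[i], tx$cds_end)
        if (cs <= ce) {
          lines <- c(lines, paste(tx$contig, "toy", "CDS", cs, ce,
                                  ".", tx$strand, "0", attrs, sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

make_site <- function(contig, pos, ref, alt = NULL, depth, alt_count = 0L,
                      qual = 40L) {
  bases <- c(rep(if (is.null(alt)) ref else alt, alt_count),
             rep(ref, depth - alt_count))
  new_pileup_site(contig, pos, ref, bases,
                  rep(c("+", "-"), length.out = depth),
                  rep(qual, depth))
}

sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", names(genome), "\tLN:", nchar(genome)))
}

sam_line <- function(qname, contig, pos, cigar, seq) {
  paste(qname, 0L, contig, pos, 60L, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}

# one spliced read per count crossing the junction with `anchor` matched
# bases each side; sequence taken from the genome
junction_reads <- function(genome, contig, donor_end, acceptor_start,
                           count, anchor = 20L, tag = "jx") {
  gap <- acceptor_start - donor_end - 1L
  seq <- paste0(
    genome_slice(genome, contig, donor_end - anchor + 1L, donor_end),
    genome_slice(genome, contig, acceptor_start,
                 acceptor_start + anchor - 1L))
  cigar <- paste0(anchor, "M", gap, "N", anchor, "M")
  vapply(seq_len(count), function(k) {
    sam_line(paste0(tag, "_", donor_end, "_", acceptor_start, "_", k),
             contig, donor_end - anchor + 1L, cigar, seq)
  }, "")
}

# contiguous reads spanning an exon/intron border; optionally carrying a
# substituted allele at one position
spanning_reads <- function(genome, contig, border_left, count,
                           half = 20L, sub_pos = NULL, sub_base = NULL,
                           tag = "span") {
  start <- border_left - half + 1L
  seq <- genome_slice(genome, contig, start, border_left + half)
  if (!is.null(sub_pos) && sub_pos >= start &&
      sub_pos <= border_left + half) {
    i <- sub_pos - start + 1L
    substr(seq, i, i) <- sub_base
  }
  cigar <- paste0(2L * half, "M")
  vapply(seq_len(count), function(k) {
    sam_line(paste0(tag, "_", border_left, "_", k), contig, start,
             cigar, seq)
  }, "")
}

scenario_paths <- function(dir) {
  list(genome = file.path(dir, "genome.fa"),
       gtf = file.path(dir, "genes.gtf"),
       tumor = file.path(dir, "tumor.pileup"),
       normal = file.path(dir, "normal.pileup"),
       sam = file.path(dir, "rna.sam"),
       segdup = file.path(dir, "segdup.bed"),
       conserved = file.path(dir, "conserved.bed"),
       known = file.path(dir, "known.tsv"),
       truth = file.path(dir, "truth.json"))
}

#' Build a named worked-example scenario on disk
#'
#' Writes a complete fixture set — FASTA genome, GTF gene model,
#' tumor/normal pileups, spliced RNA-seq SAM, exclusion BEDs, known-variant
#' TSV and a truth JSON — for one of the named scenarios. Each scenario
#' plants one splice-region somatic variant (except `negative_control`)
#' with fixed depths/alternate counts and junction/spanning read counts,
#' and records the expected downstream results (call statistics, c. name,
#' loss side, outcome percentages) in `truth.json`.
#'
#' @param name One of `r paste(SCENARIO_NAMES, collapse = ", ")`.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the background genome sequence.
#' @return Invisible list: `name`, `dir`, `paths`, `genome`, `transcripts`,
#'   `truth`.
#' @export
build_scenario <- function(name, dir = tempfile("scenario_"), seed = 1L) {
  plan <- scenario_plan(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- scenario_paths(dir)
  toy <- build_toy_gene(plan$gene, plan$strand, plan$exon_lens, seed = seed)
  genome <- toy$genome; tx <- toy$tx
  contig <- tx$contig
  write_fasta_file(genome, paths$genome)
  write_gtf_file(list(tx), paths$gtf)

  truth <- list(name = name, seed = seed)
  sam <- sam_header(genome)

  if (!is.null(plan$side) && !is.na(plan$side)) {
    bnd <- splice_boundaries(tx)
    b <- bnd[bnd$kind == plan$side & bnd$exon_index == plan$affected_exon, ]
    stopifnot(nrow(b) == 1L)
    vpos <- offset_position(tx, b, plan$offset)
    ref <- substr(genome[[contig]], vpos, vpos)
    alt <- if (tx$strand == "-") complement_base(plan$alt_tx) else plan$alt_tx
    stopifnot(ref != alt)

    flank_sites <- function(depth) list(
      make_site(contig, vpos - 7L, substr(genome[[contig]], vpos - 7L,
                                          vpos - 7L), depth = depth),
      make_site(contig, vpos + 9L, substr(genome[[contig]], vpos + 9L,
                                          vpos + 9L), depth = depth))
    tumor <- c(flank_sites(30L)[1],
               list(make_site(contig, vpos, ref, alt, plan$tumor_depth,
                              plan$tumor_alt)),
               flank_sites(30L)[2])
    normal <- c(flank_sites(32L)[1],
                list(make_site(contig, vpos, ref, alt, plan$normal_depth,
                               plan$normal_alt)),
                flank_sites(32L)[2])
    write_pileup(tumor, paths$tumor)
    write_pileup(normal, paths$normal)

    # expected call statistics, derived by direct arithmetic
    pct <- function(c, d) as.integer(floor(100 * c / d + 0.5))
    cum <- cumsum(plan$exon_lens)
    cds_at_edge <- if (plan$side == "donor") {
      cum[plan$affected_exon]
    } else {
      cum[plan$affected_exon - 1L] + 1L
    }
    hgvs <- paste0("c.", cds_at_edge,
                   if (plan$offset > 0) paste0("+", plan$offset)
                   else as.character(plan$offset),
                   ref, ">", alt)
    truth$variant <- list(
      contig = contig, position = vpos, ref = ref, alt = alt,
      tumor_depth = plan$tumor_depth, tumor_alt_count = plan$tumor_alt,
      tumor_percent = pct(plan$tumor_alt, plan$tumor_depth),
      normal_depth = plan$normal_depth,
      normal_alt_count = plan$normal_alt,
      normal_percent = pct(plan$normal_alt, plan$normal_depth),
      callable = TRUE)
    truth$annotation <- list(
      transcript_id = tx$transcript_id, side = plan$side,
      offset = plan$offset, hgvs_c = hgvs,
      expected_effect = paste0(plan$side, "_lost"))
  } else {
    # negative control: identical tumor and normal pileups, no somatic
    # signal (one shared germline-like site stays below somatic filters)
    mid <- round(mean(tx_span(tx)))
    sites <- list(
      make_site(contig, mid - 10L,
                substr(genome[[contig]], mid - 10L, mid - 10L), depth = 40L),
      make_site(contig, mid, substr(genome[[contig]], mid, mid),
                alt = "A", depth = 50L,
                alt_count = if (substr(genome[[contig]], mid, mid) == "A")
                  0L else 4L),
      make_site(contig, mid + 10L,
                substr(genome[[contig]], mid + 10L, mid + 10L), depth = 40L))
    write_pileup(sites, paths$tumor)
    write_pileup(sites, paths$normal)
    truth$variant <- NULL
    truth$annotation <- NULL
  }

  # RNA-seq reads
  outcomes <- list()
  for (j in plan$junctions) {
    je <- junction_genomic(tx, j[1], j[2])
    sam <- c(sam, junction_reads(genome, contig, je["donor_end"],
                                 je["acceptor_start"], j[3]))
  }
  if (!is.null(plan$cryptic)) {
    # acceptor-side cryptic site: junction from the canonical donor of the
    # mutated intron to a shifted acceptor within the affected exon
    u <- plan$affected_exon - 1L
    je <- junction_genomic(tx, u, plan$affected_exon)
    shift <- if (tx$strand == "+") plan$cryptic$shift else -plan$cryptic$shift
    sam <- c(sam, junction_reads(genome, contig, je["donor_end"],
                                 je["acceptor_start"] + shift,
                                 plan$cryptic$count, tag = "cryptic"))
  }
  if (plan$spanning > 0L) {
    bnd <- splice_boundaries(tx)
    b <- bnd[bnd$kind == plan$side & bnd$exon_index == plan$affected_exon, ]
    bl <- border_left_base(tx, b$kind, b$genomic_position)
    sam <- c(sam, spanning_reads(
      genome, contig, bl, plan$spanning,
      sub_pos = if (plan$spanning_mutant) truth$variant$position else NULL,
      sub_base = if (plan$spanning_mutant) truth$variant$alt else NULL))
  }
  writeLines(sam, paths$sam)

  # expected outcome fractions (direct arithmetic on planted counts)
  counts <- c(
    wild_type = sum(vapply(plan$junctions, function(j) {
      if (is.na(plan$affected_exon)) return(0L)
      if ((j[2] - j[1]) == 1L &&
          (j[1] == plan$affected_exon || j[2] == plan$affected_exon)) {
        j[3]
      } else 0L
    }, 0L)),
    exon_skip = sum(vapply(plan$junctions, function(j) {
      if (is.na(plan$affected_exon)) return(0L)
      if ((j[2] - j[1]) == 2L && j[1] == plan$affected_exon - 1L) j[3]
      else 0L
    }, 0L)),
    intron_retention = plan$spanning,
    cryptic = if (is.null(plan$cryptic)) 0L else plan$cryptic$count)
  total <- sum(counts)
  truth$event <- if (!is.null(plan$side) && !is.na(plan$side)) {
    if (total == 0L) {
      list(status = "not_expressed")
    } else {
      pc <- as.integer(floor(100 * counts / total + 0.5))
      list(status = "ok", total = total,
           counts = as.list(counts[counts > 0]),
           percents = as.list(stats::setNames(pc, names(counts))[counts > 0]),
           exclusive_mutant = isTRUE(plan$spanning_mutant))
    }
  } else NULL

  # exclusion annotations: conserved region around the gene, decoy segdup
  # and known-variant entries far from the planted variant
  sp <- tx_span(tx)
  writeLines(paste(contig, sp[1] - 1L, sp[2], sep = "\t"), paths$conserved)
  writeLines(paste(contig, 0L, 20L, sep = "\t"), paths$segdup)
  writeLines(paste(contig, 5L, "A", "C", sep = "\t"), paths$known)

  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(name = name, dir = dir, paths = paths, genome = genome,
                 transcripts = stats::setNames(list(tx), tx$transcript_id),
                 truth = truth))
}

#' Build a randomized planted-variant scenario
#'
#' Plants `n_variants` substitution sites with depths and alternate
#' fractions drawn uniformly from the given ranges (tumor), and a clean or
#' lightly contaminated matched normal. The truth JSON records every
#' planted site's expected callable status under default [caller_params()],
#' computed by an independent brute-force filter check at generation time.
#' Output is byte-identical for a fixed seed.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_variants Number of planted sites.
#' @param depth_range Tumor/normal depth range (uniform integer draw).
#' @param fraction_range Tumor alternate-percent range.
#' @param dir Output directory.
#' @return Invisible list: `dir`, `paths`, `truth` (per-site data frame).
#' @export
random_scenario <- function(seed, n_variants = 50L,
                            depth_range = c(10L, 120L),
                            fraction_range = c(0L, 90L),
                            dir = tempfile("rscenario_")) {
  stopifnot(depth_range[1] >= 1L, depth_range[2] >= depth_range[1],
            fraction_range[1] >= 0L, fraction_range[2] <= 100L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                tumor = file.path(dir, "tumor.pileup"),
                normal = file.path(dir, "normal.pileup"),
                truth = file.path(dir, "truth.json"))
  res <- withr::with_seed(seed, {
    glen <- max(1000L, n_variants * 20L + 200L)
    gseq <- random_dna(glen)
    pos <- sort(sample(seq(50L, glen - 50L), n_variants))
    t_depth <- sample(depth_range[1]:depth_range[2], n_variants,
                      replace = TRUE)
    t_frac <- sample(fraction_range[1]:fraction_range[2], n_variants,
                     replace = TRUE)
    t_alt <- pmin(t_depth, as.integer(round(t_depth * t_frac / 100)))
    n_depth <- sample(depth_range[1]:depth_range[2], n_variants,
                      replace = TRUE)
    # most normals clean; some carry trace or germline-level support
    n_alt <- ifelse(stats::runif(n_variants) < 0.7, 0L,
                    as.integer(round(n_depth *
                                       sample(0:30, n_variants,
                                              replace = TRUE) / 100)))
    qual <- ifelse(stats::runif(n_variants) < 0.9, 40L, 20L)
    list(gseq = gseq, pos = pos, t_depth = t_depth, t_alt = t_alt,
         n_depth = n_depth, n_alt = n_alt, qual = qual)
  })
  contig <- "chrR"
  genome <- structure(stats::setNames(res$gseq, contig),
                      class = "sv_genome")
  write_fasta_file(genome, paths$genome)
  ref <- substring(res$gseq, res$pos, res$pos)
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  tumor <- lapply(seq_along(res$pos), function(i) {
    make_site(contig, res$pos[i], ref[i], alt[i], res$t_depth[i],
              res$t_alt[i], qual = res$qual[i])
  })
  normal <- lapply(seq_along(res$pos), function(i) {
    make_site(contig, res$pos[i], ref[i], alt[i], res$n_depth[i],
              res$n_alt[i], qual = 40L)
  })
  write_pileup(tumor, paths$tumor)
  write_pileup(normal, paths$normal)
  # independent brute-force pass/fail under default parameters: alternate
  # calls only count at Phred >= 30
  p <- caller_params()
  eff_alt <- ifelse(res$qual >= p$min_base_quality, res$t_alt, 0L)
  pct <- function(c, d) as.integer(floor(100 * c / d + 0.5))
  callable <- res$t_depth >= p$min_tumor_depth &
    eff_alt >= p$min_alt_count &
    ifelse(res$t_depth > 0, pct(eff_alt, res$t_depth), 0L) >=
      p$min_alt_percent &
    res$n_depth >= p$min_normal_depth &
    pct(res$n_alt, res$n_depth) <= p$max_normal_alt_percent
  truth <- data.frame(contig = contig, position = res$pos, ref = ref,
                      alt = alt, tumor_depth = res$t_depth,
                      tumor_alt_count = res$t_alt,
                      base_quality = res$qual,
                      normal_depth = res$n_depth,
                      normal_alt_count = res$n_alt,
                      callable = callable,
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  jsonlite::write_json(list(seed = seed, sites = truth), paths$truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, paths = paths, truth = truth))
}
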