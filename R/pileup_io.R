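# Parser/writer for the 6-column samtools text pileup dialect:
#   contig  pos  ref  depth  base-string  quality-string
# Base-string grammar: "."/"," ref match (fwd/rev); ACGTN/acgtn mismatch
# (fwd/rev); "^X" read start (X = mapping quality, discarded); "$" read end;
# "+n<seq>"/"-n<seq>" indel text (parsed past, never called); "*" deletion
# placeholder (a call that never counts as a substitution).

#' Construct a pileup site
#'
#' @param contig Contig name.
#' @param pos 1-based position.
#' @param ref Reference base.
#' @param bases Decoded per-read base calls (uppercase; `*` for deletion
#'   placeholders).
#' @param strands Per-read strand (`"+"`/`"-"`).
#' @param quals Per-read Phred scores, in `[0, 93]`.
#' @return Object of class `sv_pileup_site`.
#' @export
new_pileup_site <- function(contig, pos, ref, bases, strands, quals) {
  stopifnot(length(bases) == length(quals), length(bases) == length(strands))
  if (length(quals) && (any(quals < 0L) || any(quals > 93L))) {
    stop("Phred score outside [0, 93] at ", contig, ":", pos)
  }
  structure(list(contig = contig, position = as.integer(pos),
                 ref_base = toupper(ref), depth = length(bases),
                 bases = bases, strands = strands, quals = as.integer(quals)),
            class = "sv_pileup_site")
}

#' @export
print.sv_pileup_site <- function(x, ...) {
  cat("<pileup> ", x$contig, ":", x$position, " ref=", x$ref_base,
      " depth=", x$depth, "\n", sep = "")
  invisible(x)
}

decode_base_string <- function(bs, ref, line = NA) {
  chars <- strsplit(bs, "", fixed = TRUE)[[1]]
  bases <- character(0); strands <- character(0)
  i <- 1L; n <- length(chars)
  ref <- toupper(ref)
  while (i <= n) {
    c0 <- chars[i]
    if (c0 == "^") {
      i <- i + 2L                       # skip mapping-quality char
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                      # skip inserted/deleted sequence
    } else if (c0 == "." || c0 == ",") {
      bases <- c(bases, ref)
      strands <- c(strands, if (c0 == ".") "+" else "-")
      i <- i + 1L
    } else if (grepl("[ACGTNacgtn]", c0)) {
      bases <- c(bases, toupper(c0))
      strands <- c(strands, if (c0 %in% c("A","C","G","T","N")) "+" else "-")
      i <- i + 1L
    } else if (c0 == "*") {
      bases <- c(bases, "*")
      strands <- c(strands, "+")
      i <- i + 1L
    } else {
      stop("unrecognized pileup base-string character '", c0, "'",
           if (!is.na(line)) paste0(" at line ", line))
    }
  }
  list(bases = bases, strands = strands)
}

#' Parse a samtools text pileup file
#'
#' @param path Path to a 6-column pileup file (gzip transparent). Lines with
#'   depth 0 may have empty or absent call/quality columns.
#' @return List of pileup site objects, one per line, in file order.
#' @export
parse_pileup <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      stop("pileup parse error at line ", k, ": fewer than 4 columns")
    }
    depth <- as.integer(f[4])
    if (is.na(depth)) stop("pileup parse error at line ", k, ": bad depth")
    if (depth == 0L) {
      out[[k]] <- new_pileup_site(f[1], as.integer(f[2]), f[3],
                                  character(0), character(0), integer(0))
      next
    }
    if (length(f) < 6L) {
      stop("pileup parse error at line ", k,
           ": depth ", depth, " but missing call/quality columns")
    }
    dec <- decode_base_string(f[5], f[3], line = k)
    quals <- utf8ToInt(f[6]) - 33L
    if (length(dec$bases) != depth || length(quals) != depth) {
      stop("pileup parse error at line ", k, ": decoded ",
           length(dec$bases), " calls / ", length(quals),
           " qualities but depth is ", depth)
    }
    out[[k]] <- new_pileup_site(f[1], as.integer(f[2]), f[3],
                                dec$bases, dec$strands, quals)
  }
  out
}

encode_base_string <- function(site) {
  ref <- site$ref_base
  vapply(seq_len(site$depth), function(i) {
    b <- site$bases[i]; fwd <- site$strands[i] == "+"
    if (b == "*") "*"
    else if (b == ref) (if (fwd) "." else ",")
    else (if (fwd) b else tolower(b))
  }, "")
}

#' Write pileup sites in canonical 6-column encoding
#'
#' Reference matches are re-encoded as `.`/`,` and mismatches as
#' upper/lowercase bases by read strand, so `parse_pileup(write_pileup(x))`
#' reproduces `x` for substitution-only sites.
#'
#' @param sites List of pileup site objects.
#' @param path Output path.
#' @export
write_pileup <- function(sites, path) {
  lines <- vapply(sites, function(s) {
    if (s$depth == 0L) {
      paste(s$contig, s$position, s$ref_base, 0L, "", "", sep = "\t")
    } else {
      paste(s$contig, s$position, s$ref_base, s$depth,
            paste0(encode_base_string(s), collapse = ""),
            intToUtf8(s$quals + 33L),
            sep = "\t")
    }
  }, "")
  writeLines(lines, path)
  invisible(path)
}
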