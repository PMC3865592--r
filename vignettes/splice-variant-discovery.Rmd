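---
title: "Discovering somatic splice-site mutations and quantifying their transcript consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering somatic splice-site mutations and quantifying their transcript consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicevar)
```

## The problem

Whole-exome capture reaches well into the first and last dozens of bases
of introns, so exome data carry the evidence for point mutations at the
donor (`exon|GT…`) and acceptor (`…AG|exon`) sites that the spliceosome
uses to excise introns. A substitution at the invariant GT/AG
dinucleotides, or at strongly constrained nearby positions such as donor
+5, can abolish the constitutive site; the cell then skips the upstream
exon, retains the intron, or falls back on a cryptic site a few bases
away. `splicevar` chains the four analyses needed to go from raw
tumor/normal pileups to a quantified splicing consequence, and ships a
synthetic-data generator that exercises every stage against a known
planted truth.

## Somatic calling by hard filters

The caller is deliberately a hard-filter design, not a probabilistic
genotyper: it is meant to feed a splice-site screen, where specificity at
well-covered sites matters more than sensitivity at marginal ones. A
tumor site is called when

* tumor read coverage is at least 20;
* the strongest non-reference allele has at least 6 reads at base
  quality Phred ≥ 30 (error probability ≤ 0.001);
* its integer percent, ⌊100·count/depth + ½⌋, is at least 25; and
* the matched normal covers the site and carries that allele at an
  integer percent of at most 10.

The integer-percent rounding (half away from zero) is part of the
contract: all published worked-example depth/count pairs used in the
tests reproduce their printed fractions only under this rule. A site
absent from the normal pileup is not callable by default
(`min_normal_depth = 1`): without normal coverage the somatic/germline
distinction is unavailable, and the filters have nothing to tolerate
against. Ties between two equally supported alternate alleles go to the
lexicographically smaller base and flag the call multi-allelic, so output
order never depends on hash or input order. Deletion placeholders (`*`)
and indel text in the pileup base string are parsed past but never
counted: the screen targets substitutions.

## Splice-region annotation

A variant is `splicing` when it lies in an intron within
`splice_window_bp = 20` bases (inclusive) of an exon–intron boundary of
an overlapping transcript. The window is wide by design — wide enough to
include the weakly constrained positions that the predictor will then
reject — and the scored model footprint (below) is narrower. Offsets are
signed in transcript orientation: `+k` for the k-th intronic base past a
donor, `-k` for the k-th base before an acceptor; a variant nearer two
boundaries than half a (tiny) intron takes the nearest, with ties going
to the donor. Exonic variants are classed `exonic` and never receive a
side or offset.

Coding-coordinate names follow the clinical `c.N+k` / `c.N−k`
convention, computed on the transcript strand. Reported alleles,
however, default to the genomic (plus) strand — the convention used in
the tumor-sequencing literature this package's reports are modeled on —
so a minus-strand donor +1 variant prints as `c.735+1C>T`; a flag
switches to strict transcript-strand alleles (`c.735+1G>A`). UTR-aware
naming (`c.*`, `c.-`) is out of scope; annotation is per transcript with
no isoform collapse.

Exclusion filters drop variants found in a user-supplied known-variant
set (dbSNP-style; VCF or 4-column TSV) or inside segmental-duplication
intervals, where capture artifacts concentrate. Conservation intervals
only set a flag by default: a non-conserved position weakens but does
not refute a splice hypothesis, so hard-filtering on conservation is
opt-in.

## Three-model consensus loss prediction

The predictor asks one question per method: *is the constitutive site
still recognized in the mutant sequence?* Three transparent models score
a fixed window — donor 9-mer (3 exonic + 6 intronic), acceptor 23-mer
(20 intronic + 3 exonic), both in transcript orientation:

* **wmm** — position weight matrix; log-odds of per-position base
  probabilities (additive pseudocount 0.1) against a uniform background;
* **wam** — weight array model; first-order Markov log-odds using
  conditional probabilities between adjacent positions, capturing
  dinucleotide structure the wmm ignores;
* **consensus_ic** — information-content score; each position
  contributes its information content (2 + Σp·log₂p bits) when the base
  matches the training-set modal base, zero otherwise.

Raw scores are min-max normalized to [0, 1] over each model's attainable
range (for the wam, the attainable extremes are computed by dynamic
programming over base paths), so all methods report on one scale and
`-` in a report always means "below the recognition threshold". A
variant is a loss only when **all three** methods recognize the
wild-type window and none recognizes the mutant — the consensus rule
guards against any single model's artifacts. A combined probability,
`1 − Π(mutant/wild-type score ratios)`, is reported; it is monotone in
the score drop and bounded in [0, 1] but is this package's own summary,
not comparable to external classifiers' probabilities, and it is not
thresholded by default.

### The recognition threshold

The default `recognition_threshold = 0.9` is a property of the
normalization, chosen so that canonical sites pass and GT/AG- or donor
+5-destroying mutants fail on the bundled training sets. Under min-max
normalization a single-base change can remove at most its own position's
share of the total attainable range; with two invariant positions (GT or
AG) that share never exceeds half, so destroyed sites land around
0.72–0.83 while consensus-like wild-type windows score 0.95–1.0
(measured across all three methods on the bundled models). The threshold
sits in that gap. A much lower threshold cannot separate the two classes
under this normalization, no matter the training set; users who retrain
models with different pseudocounts or window geometries should re-check
the gap with `score_site` before trusting the default.

The bundled training sets are 48 synthetic donor and acceptor windows
(not genomic extracts) with canonical per-position frequencies: invariant
GT/AG, strongly conserved donor +5, a pyrimidine-enriched tract upstream
of the acceptor AG, and every base represented at the weakly constrained
positions so that no non-critical position dominates the attainable
range. Variants whose intronic offset falls outside the scored footprint
(donor +7…+20, acceptor −21…−20 side positions) cannot change the window
and are reported unevaluated rather than scored as "no effect".

## RNA-seq consequence quantification

Junctions come from CIGAR `N` operations of primary mapped records
(donor end = last aligned base before the gap, acceptor start = first
after). Around a mutated boundary the informative reads are partitioned
into:

* **wild type** — reads on the canonical junctions of the introns
  flanking the affected exon (both flanking junctions count: for a
  skipped exon, either flanking junction is evidence of the normal
  isoform);
* **exon skip** — the junction joining the two exons flanking the
  affected exon;
* **intron retention** — reads continuously covering the mutated
  boundary with at least `min_anchor = 6` aligned bases on each side and
  no gap across it (reads whose splice gap starts exactly at the
  boundary are spliced, not spanning);
* **cryptic** — a junction sharing one end with a canonical boundary of
  the mutated intron whose other end lies within `cryptic_window = 50`
  bases of, but not at, the other canonical boundary.

Percentages are integer percents of the total informative reads at the
event; reads elsewhere in the gene are ignored. Zero informative reads
yield an explicit `not_expressed` status rather than percentages. For
retained-intron reads the per-read base at the variant position supports
an allele check: `exclusive_mutant` is true when at least one read
carries the alternate and none carries the reference — evidence that the
retention is driven by the mutated allele — but the package only reports
this; it never infers causality from it.

Expression context uses FPKM, `count / ((length/10³) · (total/10⁶))`,
over the exon-union model of each gene, counting a read pair once and a
junction read at the gene it spans. Percentile ranks are computed over
all genes in the expression table, zero-FPKM genes included — the most
conservative choice when the gene universe is not specified.

## The synthetic-data generator

`build_scenario` writes a complete, parseable fixture set for seven
named scenarios: an exon-skip event on a minus-strand gene (tumor 23×
with 8 alternate reads, normal 65× clean; junction counts 28/5/3), an
intron-retention event (186×/87; 153× clean; 7 canonical + 5 spanning
reads all carrying the mutation), a cryptic-site activation
(59×/30; junction counts 58 canonical, 37 spanning, 5 shifted 5 bases
into the exon), a homozygous-level donor +5 variant (90×/73), a
low-expression gene, a not-expressed gene, and a negative control with
identical tumor and normal pileups. Exon lengths are chosen so that
cumulative coding lengths reproduce the published c. coordinates
(735, 1312, 1662, 1783, 568, 1004-class arithmetic) without reproducing
real gene structures; every splice boundary is planted as the
training-set consensus window so the bundled models recognize all
wild-type sites; pileup qualities default to Phred 40 so quality
filtering is inert unless a scenario plants low-quality calls.

What the generator emulates: planted read counts, strand geometry,
junction/spanning evidence, allele content of retention reads. What it
does not: sequencing error, mapping ambiguity, coverage variation along
the exon, multi-isoform genes, indels. Passing tests therefore
demonstrate the arithmetic and decision logic of the pipeline, not
robustness to real-data noise.

`random_scenario` plants configurable numbers of substitution sites with
uniform depth and fraction draws and records each site's expected
callable status, computed by an independent brute-force restatement of
the filters at generation time; outputs are byte-identical under a fixed
seed. Test and acceptance runs use 20–100 sites per fixture — small
enough to run in seconds, large enough to exercise every filter branch.

## Numerical and degenerate-input choices

* Integer percents round half away from zero everywhere (calls, event
  fractions, percentile ranks).
* `integer_percent` and FPKM refuse zero denominators rather than
  returning NaN.
* Depth-0 pileup sites parse and re-encode with empty call/quality
  columns.
* Probability rows of trained models must sum to 1 within 1e-9;
  training rejects ragged or non-ACGT input.
* `N` bases in scored windows contribute background (zero log-odds).
* Identical wild-type and mutant windows are a caught error
  (`predict_splice_loss`), not a silent no-op.
* Unsorted pileups are rejected up front; the merge-join never guesses.

## Limitations

The predictor's scores are calibrated for site *loss* at constitutive
boundaries; it does not score gain-of-function cryptic sites from DNA
(cryptic use is detected from RNA evidence instead). The annotation is
per transcript: a variant splicing in one isoform and exonic in another
yields two rows, and no attempt is made to pick a canonical isoform.
Event fractions are read proportions, not isoform concentrations — no
length normalization or NMD modeling is applied to the aberrant
transcripts.
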