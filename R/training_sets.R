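# Built-in aligned training windows for the bundled splice-site models.
# Donor windows are 9-mers (3 exonic + 6 intronic bases, exon -> intron);
# acceptor windows are 23-mers (20 intronic + 3 exonic, intron -> exon).
# Per-position base frequencies follow the canonical mammalian site
# profiles: an invariant GT at donor +1/+2 and AG at acceptor -2/-1, a
# strongly conserved donor +5 G, a pyrimidine-enriched tract upstream of
# the acceptor AG, and weakly informative positions elsewhere with every
# base represented (so no non-critical position dominates the attainable
# score range). These are synthetic sequences, not genomic extracts.

DONOR_TRAINING <- c(
  "ACGGTACGT", "AGAGTAAGC", "CCGGTATGT", "GAGGTAGGC", "CAGGTAAGG",
  "ATGGTCGGT", "ACGGTATGA", "AAGGTAGGG", "GGGGTAAGG", "GAAGTTACG",
  "TAGGTGAGT", "GGGGTTAGT", "AAAGTGAGA", "TAGGTAAGC", "ACGGTACGG",
  "CAAGTGGGG", "CCGGTAAGA", "CAGGTAAGC", "TAGGTATGG", "CAAGTAAGC",
  "CAGGTGAGT", "TCGGTGCGA", "CCGGTAAGT", "GAAGTAAGT", "CTTGTAAGT",
  "TAGGTAAGT", "GCGGTCCGC", "AACGTCAGT", "CCGGTGAGA", "CAGGTGAGT",
  "CAGGTGAGT", "CACGTAGGG", "CACGTCACC", "CGGGTACGT", "AAAGTACGT",
  "AACGTGAGA", "CAGGTGCGC", "CAGGTACGC", "CAGGTGCGT", "GGGGTAAGC",
  "AAGGTGGGC", "AAGGTACGT", "ATGGTATGA", "TGAGTAAGC", "GATGTAAGC",
  "CAGGTAAGC", "ATGGTATGA", "CCGGTATGT")

ACCEPTOR_TRAINING <- c(
  "CCCTCCACTTTTTCACTAAGGTG", "TACCTGAGCATACCTCATAGGCA",
  "TGTGCTAATTCCCATGCCAGGAC", "TTGGGAGACCCAGTTCACAGGTA",
  "CCCATGAATATTGTTCCCAGACG", "GGTCACTGCTCTTTCCACAGGCA",
  "TGCGATCTCCACCGTGTCAGAGG", "ATCCACCTCATTGCTTCCAGGAC",
  "CGGCCAGAACCCAGCCCAAGGTA", "GTTGCGATTTTTTTCCGAAGGAT",
  "TCCTGATGCTTTCTACTCAGCAT", "ACTGTTTCTCCCTTTCTGAGGTA",
  "GTACGCCTGCGTTCCCCTAGAAG", "CCGGTGCCTCTCCCCTGCAGGGG",
  "CCCTTGTTCCGATCAATCAGGTG", "TCCAGGGCCTTATTGCCTAGCAG",
  "TAGAACGAGCTCTATTCGAGTTG", "GCCTGTCCAGCCTACTCGAGAAC",
  "AATATATGGTCGCCCCCCAGACC", "CCCCGCTTATCGCTCCTTAGGGC",
  "CATTCGCCCGCAATCTCCAGGTG", "CAAACACCTCTTAAATCGAGGGC",
  "CCTCAGCTTTATTCTATTAGTCC", "GTATCGTCCCACCTCCCCAGAAG",
  "GCATTCACTGGCTGTTTTAGGAT", "GTACCAGTCATATTCTTCAGCAT",
  "GAGTGATTTCTCCGCTATAGGTA", "TTCCGTTCATCCCCATCCAGAGG",
  "TTCCCCCAGTTTCTTTGCAGATC", "TGGTCTTACCCCCTCTCCAGGAG",
  "GTTTACATTACCGTTGTCAGAGG", "AGTGCCGTAGCCGCTTTCAGGAT",
  "TGACCTACGATTTCGTTCAGTAG", "ATTCTTGGTGAGTTCCCAAGGAG",
  "ACATCTTCGGGTTCTCCTAGGGG", "TAAGTTGACTTCTCGTCCAGACT",
  "AGCAACGCTTCCCACACTAGGGC", "CATTATCTCTGGCTGCCCAGGTT",
  "GTTATCGCCCCTCCCTCTAGGAT", "ATGAAGCTCTTTCTTCCTAGGCG",
  "CACCATCGCTCTCCAGCTAGATA", "TAATTTTGTCGTACTCTCAGGTG",
  "ACTGTATATTTGATTCGCAGAAC", "ATTGTCAAATCCTAGCCCAGTCC",
  "CTGCGAAGCCTGTCTCTCAGCAA", "TGGACTCGTCATAGGATCAGGAG",
  "CGGAGATTTCACCCCCTCAGGAG", "CCATTCCGTCCTGGCCCCAGGAC")

# Modal (consensus) windows of the training sets; the synthetic-data
# generator plants these as the wild-type splice sites it writes into toy
# genomes.
DONOR_CONSENSUS <- "CAGGTAAGT"
ACCEPTOR_CONSENSUS <- "CCCCCCCCCCCCCCCCCCAGGAG"
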