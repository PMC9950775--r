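# Internal sequence helpers. Transcribed synthetic sequence is kept free of
# T outside planted elements (ATG, stops, GT donor dinucleotides), so the
# only in-frame stop codons in any isoform and any reading frame are the
# planted ones.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.rand_bases <- function(n, alphabet, prob = NULL) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# T-free filler for anything that can end up inside an mRNA
.tfree <- function(n) .rand_bases(n, c("A", "C", "G"), c(0.34, 0.33, 0.33))

# unconstrained filler for never-transcribed sequence (spacers, constitutive
# intron interiors)
.dna <- function(n) .rand_bases(n, c("A", "C", "G", "T"))

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.gc_frac <- function(x) {
  b <- strsplit(x, "")[[1]]
  mean(b %in% c("G", "C", "g", "c"))
}

# round to the nearest positive multiple of 3
.r3 <- function(x) pmax(3L, as.integer(3 * round(x / 3)))

.substr_set <- function(x, at, value) {
  substr(x, at, at + nchar(value) - 1L) <- value
  x
}

# first in-frame stop codon at or after cds_start; returns the 1-based
# position of the codon's first nucleotide, or NA if none before the end
.first_stop <- function(seq, cds_start) {
  n <- nchar(seq)
  starts <- seq.int(cds_start, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit)) starts[hit[1L]] else NA_integer_
}

# sample each position from a consensus base with probability p, otherwise
# uniformly from `alphabet`
.consensusish <- function(consensus, p, alphabet = c("A", "C", "G", "T")) {
  paste(vapply(consensus, function(b) {
    if (stats::runif(1) < p) b else sample(alphabet, 1L)
  }, character(1)), collapse = "")
}
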