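# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding); all printed
# integer statistics use this convention.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Reverse complement for plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

# Validate a DNA string over {A,C,G,T,N}; returns TRUE/FALSE.
is_dna <- function(x) {
  !grepl("[^ACGTN]", x)
}

# All k-length windows of one sequence as a character vector (empty if too
# short). Windows containing N are dropped.
kmer_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, seq_len(n - k + 1L), k:n)
  if (grepl("N", seq, fixed = TRUE)) w <- w[!grepl("N", w, fixed = TRUE)]
  w
}

# Canonical form: lexicographic min of a k-mer and its reverse complement.
canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(character(0))
  rc <- revcomp_chr(kmers)
  pmin(kmers, rc)
}
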