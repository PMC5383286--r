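# Internal string/sequence helpers shared across modules.

# Uppercase and validate a nucleotide string over {A,C,G,T,N}.
clean_seq <- function(seq, allow_gap = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(gsub("\\s", "", seq))
  alpha <- if (allow_gap) "ACGTN-" else "ACGTN"
  bad <- gsub(sprintf("[%s]", alpha), "", s)
  if (nzchar(bad)) {
    stop("sequence contains disallowed characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  s
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Split a coding-sense nucleotide string into codons (drops trailing 1-2 nt).
codon_split <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
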