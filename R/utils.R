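# Shared sequence helpers.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  cpp_revcomp(as.character(x))
}

#' Translate nucleotide sequences
#'
#' Translates in frame from the first position. Codons containing N (or any
#' ambiguity that does not resolve) are translated as `X`; stop codons as `*`.
#' Trailing bases short of a full codon are ignored.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(x) {
  code <- Biostrings::GENETIC_CODE
  cpp_translate(as.character(x), names(code), unname(code))
}

has_stop <- function(aa) {
  grepl("*", aa, fixed = TRUE)
}

#' Mean Phred score of quality strings
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return numeric vector of mean Phred scores.
#' @export
mean_phred <- function(qual) {
  cpp_mean_phred(as.character(qual))
}

phred_string <- function(phreds) {
  intToUtf8(pmin(pmax(round(phreds), 0L) + 33L, 126L))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Random in-frame codon sequence free of stop codons.
random_codons <- function(n_codons) {
  sense <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste,
                 collapse = "")
  sense <- setdiff(sense, STOP_CODONS)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Random DNA containing no stop-codon triplet in any frame (used for D
# segments, which can land in any junction frame).
random_dna_no_stop_any_frame <- function(n, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    triples <- substring(s, seq_len(max(0L, n - 2L)),
                         seq_len(max(0L, n - 2L)) + 2L)
    if (!any(triples %in% STOP_CODONS)) return(s)
  }
  stop("could not generate a stop-free segment of length ", n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: keeps derived seeds valid 32-bit ints.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 104729) %% 2147483647)
}
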