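# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## base characters <-> integer codes (A=1 C=2 G=3 T=4, anything else 0)
.base_code_table <- local({
  tab <- integer(256)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("a")] <- 1L
  tab[utf8ToInt("C")] <- 2L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("g")] <- 3L
  tab[utf8ToInt("T")] <- 4L; tab[utf8ToInt("t")] <- 4L
  tab
})

base_codes <- function(s) .base_code_table[utf8ToInt(s)]

codes_to_string <- function(codes) {
  chars <- c("N", DNA_BASES)[codes + 1L]
  paste(chars, collapse = "")
}

phred_to_int <- function(q) utf8ToInt(q) - 33L

int_to_phred <- function(q) intToUtf8(as.integer(q) + 33L)

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## Mutate a set of equal-length sequences (character matrix of single bases)
## with i.i.d. substitution probability p; returns the matrix.
mutate_base_matrix <- function(mat, p) {
  if (p <= 0) return(mat)
  hit <- which(stats::runif(length(mat)) < p & mat %in% DNA_BASES)
  if (length(hit)) {
    cur <- mat[hit]
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    mat[hit] <- repl
  }
  mat
}

## Apply substitutions at rate p to a single sequence string.
mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- strsplit(seq, NULL)[[1]]
  hit <- which(stats::runif(length(ch)) < p & ch %in% DNA_BASES)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Read a (single-record or multi-record) FASTA into named character vector.
#' Read sequences from a FASTA file
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
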