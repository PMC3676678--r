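#' Read sets and FASTQ input/output
#'
#' Reads are held in memory as a `read_set`: a list with character vectors
#' `id`, `seq` and `qual` (qualities as Phred+33 strings, matching FASTQ).
#' A mate pair of files becomes a `read_pairs` object: `list(mate1, mate2)`
#' with equal record counts and matching ids.
#'
#' @param id,seq,qual parallel character vectors.
#' @return a `read_set` object.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality strings must have equal lengths")
  structure(list(id = unname(as.character(id)), seq = unname(toupper(seq)),
                 qual = unname(qual)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads\n")
  invisible(x)
}

subset_read_set <- function(x, i) read_set(x$id[i], x$seq[i], x$qual[i])

#' Pair two read sets
#' @param mate1,mate2 `read_set` objects with identical record counts.
#' @return a `read_pairs` object.
#' @export
read_pairs <- function(mate1, mate2) {
  stopifnot(inherits(mate1, "read_set"), inherits(mate2, "read_set"),
            length(mate1) == length(mate2))
  structure(list(mate1 = mate1, mate2 = mate2), class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$mate1)

subset_read_pairs <- function(x, i)
  read_pairs(subset_read_set(x$mate1, i), subset_read_set(x$mate2, i))

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ path (optionally gzipped).
#' @return a `read_set`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  read_set(names(x), as.character(x), q)
}

#' Write a read set as FASTQ (Phred+33)
#' @param reads a `read_set`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
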