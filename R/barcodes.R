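#' Design a barcode set with a minimum pairwise Hamming distance
#'
#' Constructs a set of DNA barcodes of fixed length in which every pair of
#' codes differs in at least `min_distance` positions, so that sequencing
#' errors of fewer than `min_distance` substitutions can never convert one
#' barcode into another. The construction is a seeded greedy pass over a
#' randomly permuted enumeration of all length-`length` words; for barcode
#' lengths of 6 nt and above, homopolymers and words of extreme GC content
#' (fewer than 2 or more than `length - 2` G/C for 7-mers) are excluded
#' first, as is standard practice for inline sample indices.
#'
#' @param length barcode length in nucleotides (default 7).
#' @param min_distance minimum pairwise Hamming distance (default 3).
#' @param n_requested number of barcodes wanted, or `NULL` to return the
#'   full greedy capacity.
#' @param seed integer seed for the enumeration order (reproducible design).
#' @param composition_filter apply the homopolymer/GC composition filters
#'   (default: GC filter for lengths >= 6; homopolymers always excluded).
#'   Set `FALSE` to keep all non-homopolymer words.
#' @return an object of class `barcode_set`: list with `codes`, `length`,
#'   `min_distance`.
#' @examples
#' bs <- design_barcodes(7, 3, n_requested = 96, seed = 1)
#' length(bs$codes)
#' @export
design_barcodes <- function(length = 7L, min_distance = 3L, n_requested = NULL,
                            seed = NULL, composition_filter = TRUE) {
  length <- as.integer(length)
  min_distance <- as.integer(min_distance)
  if (length < 2L || length > 10L) stop("barcode length must be in [2, 10]")
  if (min_distance < 1L || min_distance > length)
    stop("min_distance must be in [1, length]")
  set_seed_if_given(seed)

  words <- enumerate_words(length)
  keep <- rowSums(words != words[, 1L]) > 0L          # drop homopolymers
  if (composition_filter && length >= 6L) {
    gc <- rowSums(words == 2L | words == 3L)          # C or G
    keep <- keep & gc >= 2L & gc <= length - 2L
  }
  words <- words[keep, , drop = FALSE]
  words <- words[sample.int(nrow(words)), , drop = FALSE]

  target <- if (is.null(n_requested)) Inf else as.integer(n_requested)
  acc <- matrix(integer(0), ncol = length)
  for (i in seq_len(nrow(words))) {
    w <- words[i, ]
    if (nrow(acc) == 0L ||
        all(rowSums(acc != rep(w, each = nrow(acc))) >= min_distance)) {
      acc <- rbind(acc, w)
      if (nrow(acc) >= target) break
    }
  }
  if (is.finite(target) && nrow(acc) < target)
    stop(sprintf(
      "cannot construct %d barcodes of length %d at distance %d: achieved %d",
      target, length, min_distance, nrow(acc)))
  codes <- apply(acc, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
  structure(list(codes = unname(codes), length = length,
                 min_distance = min_distance),
            class = "barcode_set")
}

## all 4^L words as integer matrix (codes 1..4), rows = words
enumerate_words <- function(len) {
  g <- do.call(expand.grid, rep(list(1:4), len))
  as.matrix(g)[, len:1, drop = FALSE]
}

#' Hamming distance between two equal-length strings
#' @param a,b character scalars of equal nchar.
#' @return integer number of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, NULL)[[1]] != strsplit(b, NULL)[[1]])
}

#' Verify the pairwise-distance property of a barcode set
#'
#' Independent O(n^2 L) checker: computes every pairwise Hamming distance
#' directly and reports whether all pairs satisfy the minimum.
#'
#' @param codes character vector of equal-length barcodes.
#' @param min_distance required minimum pairwise distance.
#' @return list with `ok` (logical), `min_observed`, `n_pairs_checked`.
#' @export
verify_barcode_set <- function(codes, min_distance) {
  n <- length(codes)
  if (n < 2L) return(list(ok = TRUE, min_observed = NA_integer_,
                          n_pairs_checked = 0L))
  if (length(unique(nchar(codes))) != 1L) stop("codes differ in length")
  dmin <- Inf
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- hamming_distance(codes[i], codes[j])
      dmin <- min(dmin, d)
      npairs <- npairs + 1L
    }
  }
  list(ok = dmin >= min_distance, min_observed = as.integer(dmin),
       n_pairs_checked = npairs)
}

#' Demultiplex paired reads by exact barcode match
#'
#' Assigns each read pair to a sample if and only if the barcode field --
#' by default the first `nchar(barcode)` bases of mate 2, where the inline
#' index attached to the fragment 3' end is sequenced -- matches one of the
#' sample barcodes exactly. Perfect matches are required; a single mismatch
#' leaves the pair unassigned. The barcode bases (and their qualities) are
#' stripped from assigned reads.
#'
#' @param pairs a `read_pairs` object.
#' @param barcode_map named character vector, sample name -> barcode.
#' @param barcode_mate which mate carries the barcode (1 or 2; default 2).
#' @return list with `samples` (named list of `read_pairs`), `unassigned`
#'   (`read_pairs`), and `counts` (named integer vector including
#'   `"unassigned"`).
#' @export
demultiplex <- function(pairs, barcode_map, barcode_mate = 2L) {
  stopifnot(inherits(pairs, "read_pairs"))
  codes <- unname(barcode_map)
  if (anyDuplicated(codes)) stop("duplicate barcode in map")
  if (length(unique(nchar(codes))) > 1L) stop("barcodes differ in length")
  bl <- nchar(codes[1L])
  mate <- if (barcode_mate == 2L) pairs$mate2 else pairs$mate1
  observed <- substr(mate$seq, 1L, bl)
  idx <- match(observed, codes)

  strip <- function(rp, which_rows) {
    sub <- subset_read_pairs(rp, which_rows)
    m <- if (barcode_mate == 2L) "mate2" else "mate1"
    sub[[m]]$seq <- substring(sub[[m]]$seq, bl + 1L)
    sub[[m]]$qual <- substring(sub[[m]]$qual, bl + 1L)
    sub
  }

  samples <- lapply(seq_along(codes), function(s) strip(pairs, which(idx == s)))
  names(samples) <- names(barcode_map)
  unassigned <- subset_read_pairs(pairs, which(is.na(idx)))
  counts <- c(vapply(samples, length, integer(1)),
              unassigned = length(unassigned))
  stopifnot(sum(counts) == length(pairs))   # read-count conservation
  list(samples = samples, unassigned = unassigned, counts = counts)
}
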