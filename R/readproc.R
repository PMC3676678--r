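#' Quality filter for reads
#'
#' A read is discarded when more than `max_low` of its bases have a Phred
#' quality below `q_min` (defaults: more than 5 bases below Q15).
#'
#' @param qual character vector of Phred+33 quality strings.
#' @param max_low maximum tolerated number of low-quality bases (default 5).
#' @param q_min quality threshold (default 15).
#' @return logical vector: `TRUE` = keep.
#' @export
quality_filter <- function(qual, max_low = 5L, q_min = 15L) {
  vapply(qual, function(q) sum(phred_to_int(q) < q_min) <= max_low,
         logical(1), USE.NAMES = FALSE)
}

#' Quality-filter read pairs
#'
#' A pair is discarded when either mate fails [quality_filter()].
#'
#' @param pairs a `read_pairs` object.
#' @inheritParams quality_filter
#' @return list with `kept` (`read_pairs`), `n_in`, `n_kept`.
#' @export
filter_read_pairs <- function(pairs, max_low = 5L, q_min = 15L) {
  keep <- quality_filter(pairs$mate1$qual, max_low, q_min) &
          quality_filter(pairs$mate2$qual, max_low, q_min)
  list(kept = subset_read_pairs(pairs, which(keep)),
       n_in = length(pairs), n_kept = sum(keep))
}

## Core single-pair merge on integer-coded sequences.
## Returns NULL (unmerged) or list(codes, qual, overlap).
merge_one <- function(s1, q1, s2rc, q2rc, min_overlap, max_mismatch_frac,
                      qual_cap) {
  len1 <- length(s1); len2 <- length(s2rc)
  if (len1 == 0L || len2 == 0L) return(NULL)
  ## d = position of rc(mate2)[1] in mate1 coordinates (1-based, may be <= 0)
  d_range <- (min_overlap + 1L - len2):(len1 - min_overlap + 1L)
  if (length(d_range) == 0L) return(NULL)
  best <- -Inf; best_d <- NA_integer_; tie <- FALSE
  best_ov <- 0L; best_mm <- 0L
  for (d in d_range) {
    i_lo <- max(1L, d); i_hi <- min(len1, d + len2 - 1L)
    ov <- i_hi - i_lo + 1L
    if (ov < min_overlap) next
    a <- s1[i_lo:i_hi]; b <- s2rc[(i_lo - d + 1L):(i_hi - d + 1L)]
    m <- sum(a == b & a > 0L)
    mm <- ov - m
    sc <- m - mm
    if (sc > best) {
      best <- sc; best_d <- d; tie <- FALSE; best_ov <- ov; best_mm <- mm
    } else if (sc == best) tie <- TRUE
  }
  if (!is.finite(best) || tie) return(NULL)         # ambiguous tie: unmerged
  if (best_mm > max_mismatch_frac * best_ov) return(NULL)
  d <- best_d
  ## merged fragment spans mate1 coordinate 1 .. end of rc(mate2); bases
  ## beyond either end are adapter read-through and are removed.
  lo <- 1L; hi <- d + len2 - 1L
  out_b <- integer(hi - lo + 1L); out_q <- integer(hi - lo + 1L)
  for (pos in lo:hi) {
    has1 <- pos >= 1L && pos <= len1
    j <- pos - d + 1L
    has2 <- j >= 1L && j <= len2
    if (has1 && has2) {
      b1 <- s1[pos]; b2 <- s2rc[j]; qa <- q1[pos]; qb <- q2rc[j]
      if (b1 == b2) {
        out_b[pos] <- b1; out_q[pos] <- min(qa + qb, qual_cap)
      } else if (b1 == 0L) { out_b[pos] <- b2; out_q[pos] <- qb
      } else if (b2 == 0L) { out_b[pos] <- b1; out_q[pos] <- qa
      } else if (qa >= qb) { out_b[pos] <- b1; out_q[pos] <- qa - qb
      } else              { out_b[pos] <- b2; out_q[pos] <- qb - qa }
    } else if (has1) { out_b[pos] <- s1[pos]; out_q[pos] <- q1[pos]
    } else           { out_b[pos] <- s2rc[j]; out_q[pos] <- q2rc[j] }
  }
  list(codes = out_b, qual = out_q, overlap = best_ov)
}

#' Merge mate pairs into single fragments
#'
#' For each pair, the best-scoring ungapped overlap between mate 1 and the
#' reverse complement of mate 2 is found (score = matches minus
#' mismatches over all relative shifts). Pairs whose best overlap is
#' shorter than `min_overlap` (default 11 nt), has more than
#' `max_mismatch_frac` mismatches, or is tied between two distinct shifts
#' are left unmerged and excluded downstream. In the overlap, agreeing
#' bases receive the sum of the two qualities (capped at `qual_cap`);
#' disagreeing bases receive the higher-quality base with quality equal to
#' the absolute quality difference (mate 1 wins an exact quality tie).
#' Adapter bases beyond the fragment ends are removed.
#'
#' @param pairs a `read_pairs` object (already quality filtered).
#' @param min_overlap minimum acceptable overlap in nt (default 11).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap
#'   (default 0.1).
#' @param qual_cap cap on summed qualities (default 60).
#' @return object of class `merged_fragments`: list with `id`, `seq`,
#'   `qual` (Phred+33 strings), `overlap_length`, plus `unmerged_ids` and a
#'   `stats` list (n_in, n_merged, n_unmerged, length table).
#' @export
merge_pairs <- function(pairs, min_overlap = 11L, max_mismatch_frac = 0.1,
                        qual_cap = 60L) {
  n <- length(pairs)
  ids <- character(0); seqs <- character(0); quals <- character(0)
  ovl <- integer(0); unmerged <- character(0)
  for (i in seq_len(n)) {
    s1 <- base_codes(pairs$mate1$seq[i])
    q1 <- phred_to_int(pairs$mate1$qual[i])
    s2 <- base_codes(pairs$mate2$seq[i])
    q2 <- phred_to_int(pairs$mate2$qual[i])
    s2rc <- rev(ifelse(s2 == 0L, 0L, 5L - s2))
    q2rc <- rev(q2)
    m <- merge_one(s1, q1, s2rc, q2rc, as.integer(min_overlap),
                   max_mismatch_frac, as.integer(qual_cap))
    if (is.null(m)) {
      unmerged <- c(unmerged, pairs$mate1$id[i])
    } else {
      ids <- c(ids, pairs$mate1$id[i])
      seqs <- c(seqs, codes_to_string(m$codes))
      quals <- c(quals, int_to_phred(m$qual))
      ovl <- c(ovl, m$overlap)
    }
  }
  structure(list(
    id = ids, seq = seqs, qual = quals, overlap_length = ovl,
    unmerged_ids = unmerged,
    stats = list(n_in = n, n_merged = length(ids),
                 n_unmerged = length(unmerged),
                 length_table = table(nchar(seqs)))
  ), class = "merged_fragments")
}

#' @export
print.merged_fragments <- function(x, ...) {
  cat(sprintf("merged_fragments: %d merged, %d unmerged\n",
              x$stats$n_merged, x$stats$n_unmerged))
  invisible(x)
}

#' Construct a merged-fragments object directly from sequences
#'
#' Convenience constructor used when fragments originate elsewhere than
#' [merge_pairs()] (e.g. simulations feeding the mapper directly).
#'
#' @param id,seq character vectors; `qual` optional Phred+33 strings
#'   (defaults to Q40 everywhere).
#' @param qual optional quality strings.
#' @return a `merged_fragments` object.
#' @export
fragments_from_seqs <- function(id, seq, qual = NULL) {
  if (is.null(qual))
    qual <- vapply(nchar(seq), function(L) int_to_phred(rep(40L, L)),
                   character(1))
  structure(list(id = as.character(id), seq = toupper(seq), qual = qual,
                 overlap_length = rep(NA_integer_, length(id)),
                 unmerged_ids = character(0),
                 stats = list(n_in = length(id), n_merged = length(id),
                              n_unmerged = 0L,
                              length_table = table(nchar(seq)))),
            class = "merged_fragments")
}
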