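#' Alignment scoring parameters
#'
#' Scoring used by the fragment mapper: match +5, mismatch -4, gap open -8,
#' gap extend -2, with an acceptance threshold of `accept_frac` times the
#' maximum attainable score for the fragment length.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @param accept_frac acceptance threshold as a fraction of the maximal
#'   (all-match) score (default 0.8).
#' @return list of scoring parameters.
#' @export
alignment_scoring <- function(match = 5, mismatch = -4, gap_open = -8,
                              gap_extend = -2, accept_frac = 0.8) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, accept_frac = accept_frac)
}

## k-mer index of a sequence: environment mapping k-mer -> integer positions
build_seed_index <- function(seq, k) {
  L <- nchar(seq)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  if (L < k) return(idx)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ord <- order(kmers)
  kmers_s <- kmers[ord]
  runs <- rle(kmers_s)
  ends <- cumsum(runs$lengths)
  begins <- c(1L, utils::head(ends, -1L) + 1L)
  for (i in seq_along(runs$values))
    assign(runs$values[i], ord[begins[i]:ends[i]], envir = idx)
  idx
}

#' Map merged fragments to a (circular) reference
#'
#' Seed-and-extend mapping: exact k-mer seeds anchor candidate diagonals on
#' the doubled reference (so fragments spanning the circular origin map as a
#' single contiguous hit), candidates are scored by ungapped extension over
#' the full fragment on both strands, and a fragment is accepted when its
#' best score reaches `accept_frac` of the maximal score. Ties between two
#' distinct best loci leave the fragment unmapped (ambiguous). When
#' `rescue = TRUE`, fragments without a seeded candidate are aligned with a
#' full local (gapped) alignment against the doubled reference via
#' [Biostrings::pairwiseAlignment()]; rescue hits contribute scores (used by
#' competitive classification) but are skipped by the pileup when gapped.
#'
#' @param fragments a `merged_fragments` object.
#' @param reference reference sequence (single character string).
#' @param scoring see [alignment_scoring()].
#' @param circular treat the reference as circular (default TRUE).
#' @param k seed k-mer length (default 13).
#' @param n_seeds number of evenly spaced seed positions per fragment.
#' @param rescue gapped rescue for seedless fragments (default FALSE).
#' @return data.frame of class `fragment_alignments`: columns `id`, `start`
#'   (0-based on the unrolled reference, reduced modulo length), `end`
#'   (= start + fragment length; may exceed the reference length for
#'   origin-spanning hits), `strand`, `score`, `seq` (fragment oriented to
#'   the reference forward strand), `qual`. Attribute `ref_length`.
#' @export
map_fragments <- function(fragments, reference, scoring = alignment_scoring(),
                          circular = TRUE, k = 13L, n_seeds = 4L,
                          rescue = FALSE) {
  reference <- toupper(reference)
  L <- nchar(reference)
  if (L == 0L) stop("reference is empty")
  refx <- if (circular) paste0(reference, reference) else reference
  Lx <- nchar(refx)
  ref_codes <- base_codes(refx)
  idx <- build_seed_index(refx, k)
  match_s <- scoring$match; mism_s <- scoring$mismatch

  n <- length(fragments$id)
  rvc_all <- if (n) revcomp(fragments$seq) else character(0)
  out <- vector("list", n)
  need_rescue <- integer(0)

  for (i in seq_len(n)) {
    fseq <- fragments$seq[i]
    flen <- nchar(fseq)
    if (flen < k) next
    fwd <- fseq
    rvc <- rvc_all[i]
    max_sc <- match_s * flen
    thr <- scoring$accept_frac * max_sc
    seed_pos <- unique(round(seq(1L, flen - k + 1L,
                                 length.out = min(n_seeds, flen - k + 1L))))
    cand <- list()   # per strand: candidate start positions on refx (1-based)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rvc
      starts <- integer(0)
      for (sp in seed_pos) {
        kmer <- substr(s, sp, sp + k - 1L)
        hits <- idx[[kmer]]
        if (!is.null(hits)) starts <- c(starts, hits - sp + 1L)
      }
      starts <- unique(starts)
      starts <- starts[starts >= 1L & starts + flen - 1L <= Lx]
      if (circular) {
        ## collapse the two copies of the same circular locus
        locus <- (starts - 1L) %% L
        starts <- starts[!duplicated(locus)]
      }
      cand[[strand]] <- starts
    }

    if (rescue && length(cand[["+"]]) == 0L && length(cand[["-"]]) == 0L) {
      need_rescue <- c(need_rescue, i)
      next
    }
    best_sc <- -Inf; best_strand <- NA_character_; best_start <- NA_integer_
    n_best <- 0L
    for (strand in c("+", "-")) {
      s_codes <- base_codes(if (strand == "+") fwd else rvc)
      for (st in cand[[strand]]) {
        seg <- ref_codes[st:(st + flen - 1L)]
        m <- sum(seg == s_codes & s_codes > 0L)
        sc <- m * match_s + (flen - m) * mism_s
        if (sc > best_sc) {
          best_sc <- sc; best_strand <- strand; best_start <- st; n_best <- 1L
        } else if (sc == best_sc) n_best <- n_best + 1L
      }
    }

    if (!is.finite(best_sc) || best_sc < thr || n_best > 1L) next
    start0 <- (best_start - 1L) %% L
    oriented_seq <- if (best_strand == "+") fwd else rvc
    oriented_qual <- if (best_strand == "+") fragments$qual[i] else
      intToUtf8(base::rev(utf8ToInt(fragments$qual[i])))
    out[[i]] <- list(id = fragments$id[i], start = start0,
                     end = start0 + flen, strand = best_strand,
                     score = best_sc, seq = oriented_seq,
                     qual = oriented_qual)
  }

  if (length(need_rescue)) {
    ## batched full local (gapped) alignment for fragments without any seed
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match_s, mismatch = mism_s, baseOnly = TRUE)
    subj <- Biostrings::DNAString(refx)
    fwd_set <- Biostrings::DNAStringSet(fragments$seq[need_rescue])
    rvc_set <- Biostrings::reverseComplement(fwd_set)
    score_strand <- function(set) {
      al <- Biostrings::pairwiseAlignment(
        set, subj, type = "local", substitutionMatrix = submat,
        gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
        scoreOnly = FALSE)
      list(score = BiocGenerics::score(al),
           start = BiocGenerics::start(Biostrings::subject(al)) -
             (BiocGenerics::start(Biostrings::pattern(al)) - 1L))
    }
    rf <- score_strand(fwd_set)
    rr <- score_strand(rvc_set)
    for (j in seq_along(need_rescue)) {
      i <- need_rescue[j]
      flen <- nchar(fragments$seq[i])
      thr <- scoring$accept_frac * match_s * flen
      if (rf$score[j] == rr$score[j]) next            # ambiguous strand tie
      use_fwd <- rf$score[j] > rr$score[j]
      best_sc <- if (use_fwd) rf$score[j] else rr$score[j]
      if (best_sc < thr) next
      best_start <- if (use_fwd) rf$start[j] else rr$start[j]
      start0 <- (best_start - 1L) %% L
      oriented_seq <- if (use_fwd) fragments$seq[i] else rvc_all[i]
      oriented_qual <- if (use_fwd) fragments$qual[i] else
        intToUtf8(base::rev(utf8ToInt(fragments$qual[i])))
      out[[i]] <- list(id = fragments$id[i], start = start0,
                       end = start0 + flen, strand = if (use_fwd) "+" else "-",
                       score = best_sc, seq = oriented_seq,
                       qual = oriented_qual)
    }
  }

  out <- out[!vapply(out, is.null, logical(1))]
  res <- data.frame(
    id = vapply(out, `[[`, character(1), "id"),
    start = vapply(out, `[[`, numeric(1), "start"),
    end = vapply(out, `[[`, numeric(1), "end"),
    strand = vapply(out, `[[`, character(1), "strand"),
    score = vapply(out, `[[`, numeric(1), "score"),
    seq = vapply(out, `[[`, character(1), "seq"),
    qual = vapply(out, `[[`, character(1), "qual"),
    stringsAsFactors = FALSE)
  attr(res, "ref_length") <- L
  attr(res, "n_input") <- n
  class(res) <- c("fragment_alignments", "data.frame")
  res
}

#' Collapse duplicate alignments
#'
#' Alignments with the same orientation and start whose end coordinates lie
#' within `end_tolerance` of each other (single-linkage chaining on sorted
#' ends) are collapsed to one representative: the alignment with the
#' highest summed base quality. This mirrors unique-read filtering by
#' "same orientation, start, and compatible end coordinates".
#'
#' @param alignments a `fragment_alignments` data.frame.
#' @param end_tolerance maximum end difference within a duplicate group
#'   (default 2 nt).
#' @return deduplicated `fragment_alignments` (attributes preserved, plus
#'   `n_duplicates_removed`).
#' @export
dedup <- function(alignments, end_tolerance = 2L) {
  if (nrow(alignments) == 0L) {
    attr(alignments, "n_duplicates_removed") <- 0L
    return(alignments)
  }
  qsum <- vapply(alignments$qual, function(q) sum(phred_to_int(q)),
                 numeric(1), USE.NAMES = FALSE)
  keep <- logical(nrow(alignments))
  groups <- split(seq_len(nrow(alignments)),
                  paste(alignments$strand, alignments$start))
  for (g in groups) {
    ends <- alignments$end[g]
    o <- order(ends)
    g <- g[o]; ends <- ends[o]
    cluster_break <- c(TRUE, diff(ends) > end_tolerance)
    cl <- cumsum(cluster_break)
    for (c_id in unique(cl)) {
      members <- g[cl == c_id]
      keep[members[which.max(qsum[members])]] <- TRUE
    }
  }
  out <- alignments[keep, , drop = FALSE]
  attr(out, "ref_length") <- attr(alignments, "ref_length")
  attr(out, "n_input") <- attr(alignments, "n_input")
  attr(out, "n_duplicates_removed") <- sum(!keep)
  class(out) <- class(alignments)
  out
}

#' Build a pileup from unique alignments
#'
#' Per reference position, counts of A/C/G/T observations contributed by
#' unique (deduplicated) fragments; each fragment contributes at most one
#' observation per position. Origin-spanning alignments wrap modulo the
#' reference length.
#'
#' @param alignments deduplicated `fragment_alignments`.
#' @param ref_length reference length (defaults to the stored attribute).
#' @return object of class `pileup`: list with `counts` (4 x L integer
#'   matrix, rows A,C,G,T), `coverage` (unique-fragment coverage per
#'   position, including N observations), `ref_length`.
#' @export
build_pileup <- function(alignments, ref_length = attr(alignments, "ref_length")) {
  L <- as.integer(ref_length)
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(DNA_BASES, NULL))
  coverage <- integer(L)
  if (nrow(alignments)) {
    pos_l <- vector("list", nrow(alignments))
    base_l <- vector("list", nrow(alignments))
    for (i in seq_len(nrow(alignments))) {
      flen <- alignments$end[i] - alignments$start[i]
      pos_l[[i]] <- (alignments$start[i] + 0:(flen - 1L)) %% L
      base_l[[i]] <- base_codes(alignments$seq[i])
    }
    all_pos <- unlist(pos_l); all_base <- unlist(base_l)
    coverage <- tabulate(all_pos + 1L, nbins = L)
    ok <- all_base > 0L
    tab <- tabulate((all_pos[ok]) * 4L + all_base[ok], nbins = 4L * L)
    counts[] <- matrix(tab, nrow = 4L)
  }
  structure(list(counts = counts, coverage = coverage, ref_length = L),
            class = "pileup")
}

#' Call a consensus genome from a pileup
#'
#' A position is called with its majority base when the unique coverage is
#' at least `min_coverage`, the majority base is supported by at least
#' `min_coverage` fragments, and the majority fraction is at least
#' `majority_frac`. Positions with coverage below `min_coverage` are N
#' (`low_coverage_N`); covered positions without a qualifying majority are
#' N (`ambiguous_N`).
#'
#' @param pileup a `pileup` object.
#' @param min_coverage minimum unique coverage to call (default 2).
#' @param majority_frac required majority-base fraction (default 2/3).
#' @return object of class `consensus_genome`: list with `seq` (character
#'   string over A,C,G,T,N), `coverage`, `status` (factor: `called`,
#'   `low_coverage_N`, `ambiguous_N`).
#' @export
call_consensus <- function(pileup, min_coverage = 2L, majority_frac = 2 / 3) {
  counts <- pileup$counts
  L <- pileup$ref_length
  tot <- colSums(counts)
  maxc <- apply(counts, 2L, max)
  nmax <- colSums(counts == rep(maxc, each = 4L)) # ties at the maximum
  top <- apply(counts, 2L, which.max)
  cov <- pileup$coverage
  called <- cov >= min_coverage & maxc >= min_coverage & nmax == 1L &
    tot > 0L & maxc / pmax(tot, 1L) >= majority_frac
  status <- ifelse(cov < min_coverage, "low_coverage_N",
                   ifelse(called, "called", "ambiguous_N"))
  bases <- rep("N", L)
  bases[called] <- DNA_BASES[top[called]]
  structure(list(seq = paste(bases, collapse = ""), coverage = cov,
                 status = factor(status,
                                 levels = c("called", "low_coverage_N",
                                            "ambiguous_N"))),
            class = "consensus_genome")
}

#' @export
print.consensus_genome <- function(x, ...) {
  cat(sprintf("consensus_genome: %d positions, %d called, %d low-coverage N, %d ambiguous N\n",
              nchar(x$seq), sum(x$status == "called"),
              sum(x$status == "low_coverage_N"),
              sum(x$status == "ambiguous_N")))
  invisible(x)
}

#' Iterative reference-guided assembly
#'
#' Repeats map -> deduplicate -> consensus, using the previous round's
#' consensus as the next mapping reference (N positions are back-filled
#' with the previous reference base for mapping only), until the called
#' sequence no longer changes or `max_iter` is reached. A period-2
#' oscillation stops the iteration with a flag.
#'
#' @param fragments a `merged_fragments` object.
#' @param reference starting reference sequence (character string).
#' @param max_iter iteration cap (default 10).
#' @param scoring see [alignment_scoring()].
#' @param min_coverage,majority_frac consensus-calling parameters.
#' @param end_tolerance duplicate end tolerance, see [dedup()].
#' @param circular treat the reference as circular.
#' @return object of class `assembly_result`: list with `consensus`
#'   (`consensus_genome`), `n_iterations`, `oscillated`, `alignments`
#'   (final deduplicated alignments), `pileup`, `n_fragments_in`,
#'   `n_mapped`, `n_unique`.
#' @export
iterate_assembly <- function(fragments, reference, max_iter = 10L,
                             scoring = alignment_scoring(),
                             min_coverage = 2L, majority_frac = 2 / 3,
                             end_tolerance = 2L, circular = TRUE) {
  reference <- toupper(reference)
  L <- nchar(reference)
  map_ref <- reference
  prev_ref <- NULL
  oscillated <- FALSE
  iter <- 0L
  aln <- NULL; pl <- NULL; cons <- NULL
  n_mapped <- 0L
  repeat {
    iter <- iter + 1L
    aln_raw <- map_fragments(fragments, map_ref, scoring = scoring,
                             circular = circular)
    n_mapped <- nrow(aln_raw)
    aln <- dedup(aln_raw, end_tolerance = end_tolerance)
    pl <- build_pileup(aln, L)
    cons <- call_consensus(pl, min_coverage = min_coverage,
                           majority_frac = majority_frac)
    ## next mapping reference: consensus with Ns back-filled from the
    ## current reference (mapping only); convergence when it is unchanged
    cc <- strsplit(cons$seq, NULL)[[1]]
    rr <- strsplit(map_ref, NULL)[[1]]
    cc[cc == "N"] <- rr[cc == "N"]
    next_ref <- paste(cc, collapse = "")
    if (next_ref == map_ref) break                       # fixed point
    if (!is.null(prev_ref) && next_ref == prev_ref) {    # period-2 cycle
      oscillated <- TRUE
      break
    }
    if (iter >= max_iter) break
    prev_ref <- map_ref
    map_ref <- next_ref
  }
  structure(list(consensus = cons, n_iterations = iter,
                 oscillated = oscillated, alignments = aln, pileup = pl,
                 n_fragments_in = length(fragments$id),
                 n_mapped = n_mapped,
                 n_unique = nrow(aln)),
            class = "assembly_result")
}

#' Coverage and GC statistics along the reference
#'
#' Per-window unique coverage and GC content, with the Pearson correlation
#' between them. The correlation is flagged undefined when the coverage
#' (or GC) variance is zero.
#'
#' @param pileup a `pileup` object.
#' @param reference reference sequence used for GC content.
#' @param window window size in nt (default 100).
#' @return list with `median_cov`, `mean_cov`, `gc_cov_pearson_r`,
#'   `p_value`, `undefined` flag, and the per-window table.
#' @export
coverage_stats <- function(pileup, reference, window = 100L) {
  L <- pileup$ref_length
  nwin <- max(1L, L %/% window)
  win_id <- pmin(((seq_len(L) - 1L) %/% window) + 1L, nwin)
  cov_w <- tapply(pileup$coverage, win_id, mean)
  ref_ch <- strsplit(toupper(reference), NULL)[[1]][seq_len(L)]
  gc_w <- tapply(ref_ch %in% c("G", "C"), win_id, mean)
  undefined <- stats::var(cov_w) == 0 || stats::var(gc_w) == 0
  if (undefined) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(gc_w, cov_w, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(median_cov = stats::median(pileup$coverage),
       mean_cov = mean(pileup$coverage),
       gc_cov_pearson_r = r, p_value = p, undefined = undefined,
       windows = data.frame(window = seq_len(nwin), gc = as.numeric(gc_w),
                            coverage = as.numeric(cov_w)))
}

#' Export alignments as SAM
#'
#' Writes ungapped alignments as SAM records (FLAG 0/16, full-length match
#' CIGAR). Origin-spanning hits are reported at their modular start.
#'
#' @param alignments a `fragment_alignments` data.frame.
#' @param ref_name reference sequence name.
#' @param path output path.
#' @export
write_sam <- function(alignments, ref_name, path) {
  L <- attr(alignments, "ref_length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, L)), con)
  for (i in seq_len(nrow(alignments))) {
    flen <- alignments$end[i] - alignments$start[i]
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                       alignments$id[i],
                       if (alignments$strand[i] == "-") 16L else 0L,
                       ref_name, alignments$start[i] + 1L, flen,
                       alignments$seq[i], alignments$qual[i]), con)
  }
  invisible(path)
}

#' Write a consensus genome as FASTA plus per-position TSV
#'
#' @param consensus a `consensus_genome`.
#' @param name sequence name for the FASTA header.
#' @param fasta_path,tsv_path output paths (either may be `NULL` to skip).
#' @export
write_consensus <- function(consensus, name, fasta_path = NULL,
                            tsv_path = NULL) {
  if (!is.null(fasta_path))
    write_fasta_seqs(stats::setNames(consensus$seq, name), fasta_path)
  if (!is.null(tsv_path))
    utils::write.table(
      data.frame(position = seq_len(nchar(consensus$seq)) - 1L,
                 coverage = consensus$coverage,
                 status = as.character(consensus$status)),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(consensus)
}
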