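#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Per-site consensus error rate implied by a read-level contamination rate
#'
#' With a minimum unique coverage of `min_coverage` for consensus calling,
#' a position is miscalled from contaminant reads only if all supporting
#' reads are contaminant, so the per-site error is `p_cont ^ min_coverage`
#' (e.g. 0.023^2 = 5.3e-4 at 2-fold coverage).
#'
#' @param p_cont proportion of contaminant reads among informative reads.
#' @param min_coverage minimum unique coverage required to call (default 2).
#' @return per-nucleotide error probability (unrounded; use `signif(x, 2)`
#'   for reporting at 2 significant figures).
#' @export
per_site_error <- function(p_cont, min_coverage = 2) {
  if (p_cont < 0 || p_cont > 1) stop("p_cont must be in [0, 1]")
  p_cont^min_coverage
}

#' Closed-form numt misincorporation model
#'
#' Expected consensus error rate from nuclear copies of mitochondrial DNA
#' (numts), built from the lineage-private numt content of a related
#' reference genome: the mean numt length is `total_numt_length / n_total_numts`,
#' the expected lineage-private numt content is `n_private_numts` times that
#' mean, the probability that a random mitochondrion-like fragment derives
#' from a private numt is `nuc_mt_ratio * private_total / genome_size`
#' (the nuclear-to-mitochondrial fragment ratio scales nuclear
#' representation), and the consensus error rate at `min_coverage`-fold
#' calling is that probability raised to `min_coverage`.
#'
#' @param n_private_numts numts private to the focal lineage (default 101).
#' @param n_total_numts total numts in the reference genome (default 434).
#' @param total_numt_length summed numt length in bp (default 261600).
#' @param nuc_mt_ratio nuclear-to-mitochondrial fragment ratio in degraded
#'   samples (default 200).
#' @param genome_size nuclear genome size in bp (default 3e9).
#' @param min_coverage minimum unique coverage for consensus calls (default 2).
#' @return object of class `numt_model`: all inputs plus `mean_numt_length`,
#'   `expected_private_total`, `per_fragment_prob`, `error_rate` (all
#'   computed from unrounded intermediates).
#' @export
numt_error_model <- function(n_private_numts = 101, n_total_numts = 434,
                             total_numt_length = 261600, nuc_mt_ratio = 200,
                             genome_size = 3e9, min_coverage = 2) {
  args <- c(n_private_numts, n_total_numts, total_numt_length, nuc_mt_ratio,
            genome_size, min_coverage)
  if (any(args <= 0)) stop("all model inputs must be positive")
  mean_len <- total_numt_length / n_total_numts
  private_total <- n_private_numts * mean_len
  per_frag <- nuc_mt_ratio * private_total / genome_size
  if (per_frag >= 1) stop("per-fragment probability must be < 1")
  structure(list(
    n_private_numts = n_private_numts, n_total_numts = n_total_numts,
    total_numt_length = total_numt_length, nuc_mt_ratio = nuc_mt_ratio,
    genome_size = genome_size, min_coverage = min_coverage,
    mean_numt_length = mean_len,
    expected_private_total = private_total,
    per_fragment_prob = per_frag,
    error_rate = per_frag^min_coverage
  ), class = "numt_model")
}

#' @export
print.numt_model <- function(x, ...) {
  cat("numt misincorporation model\n")
  cat(sprintf("  mean numt length:        %.1f bp\n", x$mean_numt_length))
  cat(sprintf("  expected private total:  %.1f kb\n",
              x$expected_private_total / 1e3))
  cat(sprintf("  per-fragment probability: %.3g\n", x$per_fragment_prob))
  cat(sprintf("  error rate at %d-fold:    %.2g\n",
              x$min_coverage, signif(x$error_rate, 2)))
  invisible(x)
}

#' Competitive-alignment contamination classification
#'
#' Two-pass competitive mapping: fragments are first mapped against the
#' ingroup references alone (defining the mapped set), then against the
#' ingroup references plus the candidate contaminant. A mapped fragment is
#' called endogenous if its best ingroup alignment score exceeds its best
#' contaminant score, contaminant if the contaminant score is higher, and
#' noninformative on a tie. Classification uses the same alignment scoring
#' as the assembly mapper but a permissive acceptance threshold, because
#' the competitive score difference -- not the absolute score -- carries
#' the signal.
#'
#' @param fragments a `merged_fragments` object (see [merge_pairs()]), or a
#'   list with `id` and `seq` character vectors.
#' @param ingroup_refs named character vector (or list) of ingroup
#'   reference sequences.
#' @param contaminant_ref contaminant reference sequence (single string).
#' @param scoring alignment scoring, as [alignment_scoring()]; the
#'   acceptance fraction is overridden by `accept_frac`.
#' @param accept_frac permissive acceptance threshold for classification
#'   mapping (default 0.5 of the maximum attainable score).
#' @param circular_refs treat references as circular (default TRUE,
#'   appropriate for mitogenomes).
#' @param level confidence level for the Clopper-Pearson interval.
#' @return object of class `contamination_report` with counts
#'   (`n_endogenous`, `n_noninformative`, `n_contaminant`, `n_unmapped`),
#'   `p_cont` (informative denominator: contaminant / (contaminant +
#'   endogenous)), `p_cont_mapped` (all-mapped denominator), `ci95`, and
#'   `per_site_error` at 2-fold coverage.
#' @export
classify_fragments <- function(fragments, ingroup_refs, contaminant_ref,
                               scoring = alignment_scoring(),
                               accept_frac = 0.5, circular_refs = TRUE,
                               level = 0.95) {
  if (length(ingroup_refs) < 1L) stop("at least one ingroup reference required")
  scoring$accept_frac <- accept_frac
  ids <- fragments$id
  n <- length(ids)

  best_scores <- function(ref, rescue) {
    hits <- map_fragments(fragments, ref, scoring = scoring,
                          circular = circular_refs, rescue = rescue)
    s <- rep(-Inf, n)
    s[match(hits$id, ids)] <- hits$score
    s
  }
  ingroup_mat <- vapply(as.character(unlist(ingroup_refs)),
                        best_scores, numeric(n), rescue = TRUE)
  ingroup_best <- if (n == 0L) numeric(0) else
    apply(matrix(ingroup_mat, nrow = n), 1L, max)
  cont_best <- best_scores(as.character(contaminant_ref), rescue = FALSE)

  mapped1 <- is.finite(ingroup_best)          # pass 1: ingroup refs only
  endo <- mapped1 & ingroup_best > cont_best
  cont <- mapped1 & cont_best > ingroup_best
  noninf <- mapped1 & ingroup_best == cont_best

  n_endo <- sum(endo); n_cont <- sum(cont); n_noninf <- sum(noninf)
  n_unmapped <- n - n_endo - n_cont - n_noninf
  denom_inf <- n_endo + n_cont
  p_cont <- if (denom_inf > 0) n_cont / denom_inf else NA_real_
  p_mapped <- if (sum(mapped1) > 0) n_cont / sum(mapped1) else NA_real_
  ci <- if (denom_inf > 0) binomial_ci(n_cont, denom_inf, level) else
    c(lo = NA_real_, hi = NA_real_)
  structure(list(
    n_endogenous = n_endo, n_noninformative = n_noninf,
    n_contaminant = n_cont, n_unmapped = n_unmapped,
    p_cont = p_cont, p_cont_mapped = p_mapped, ci95 = ci,
    per_site_error = if (is.na(p_cont)) NA_real_ else per_site_error(p_cont),
    classification = ifelse(endo, "endogenous",
                     ifelse(cont, "contaminant",
                     ifelse(noninf, "noninformative", "unmapped")))
  ), class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("contamination report\n")
  cat(sprintf("  endogenous:     %d\n", x$n_endogenous))
  cat(sprintf("  contaminant:    %d\n", x$n_contaminant))
  cat(sprintf("  noninformative: %d\n", x$n_noninformative))
  cat(sprintf("  unmapped:       %d\n", x$n_unmapped))
  if (!is.na(x$p_cont))
    cat(sprintf("  p_cont = %.4f  (95%% CI %.4f-%.4f)\n",
                x$p_cont, x$ci95[["lo"]], x$ci95[["hi"]]))
  invisible(x)
}
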