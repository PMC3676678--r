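test_that("an exact substring maps to its source coordinates on the + strand", {
  ref <- make_ref(1000, seed = 31)
  frag <- fragments_from_seqs("f1", substr(ref, 101, 158))
  aln <- map_fragments(frag, ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 100)
  expect_equal(aln$end, 158)
  expect_equal(aln$strand, "+")
  expect_equal(aln$score, 58 * 5)
})

test_that("reverse-strand fragments are mapped and reported ref-oriented", {
  ref <- make_ref(1000, seed = 32)
  frag <- fragments_from_seqs("f1", revcomp(substr(ref, 201, 260)))
  aln <- map_fragments(frag, ref)
  expect_equal(aln$strand, "-")
  expect_equal(aln$start, 200)
  expect_identical(aln$seq, substr(ref, 201, 260))
})

test_that("fragments spanning the circular origin wrap modulo the length", {
  ref <- make_ref(500, seed = 33)
  spanning <- paste0(substr(ref, 481, 500), substr(ref, 1, 30))
  aln <- map_fragments(fragments_from_seqs("f1", spanning), ref)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 480)
  expect_equal(aln$end, 530)          # start + length; wraps modulo 500
  pl <- build_pileup(aln, 500)
  expect_equal(sum(pl$coverage), 50)
  expect_true(all(pl$coverage[c(481:500, 1:30)] == 1))
})

test_that("a random fragment unrelated to the reference stays unmapped", {
  ref <- make_ref(2000, seed = 34)
  set.seed(35)
  hits <- vapply(1:50, function(i) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 58, TRUE), collapse = "")
    nrow(map_fragments(fragments_from_seqs("r", rnd), ref))
  }, numeric(1))
  expect_true(all(hits == 0))
})

test_that("duplicate collapsing keeps one representative per compatible group", {
  mk <- function(id, start, end, strand, q) {
    data.frame(id = id, start = start, end = end, strand = strand,
               score = 100, seq = strrep("A", end - start),
               qual = phred_str(rep(q, end - start)),
               stringsAsFactors = FALSE)
  }
  aln <- rbind(mk("a", 10, 68, "+", 30), mk("b", 10, 68, "+", 40),
               mk("c", 10, 70, "+", 20), mk("d", 10, 68, "-", 30),
               mk("e", 10, 80, "+", 30))
  attr(aln, "ref_length") <- 200
  class(aln) <- c("fragment_alignments", "data.frame")
  dd <- dedup(aln, end_tolerance = 2)
  ## a, b, c chain (ends 68, 68, 70) -> one representative, the highest
  ## summed quality (b); d has the other orientation; e's end is 10 away
  expect_setequal(dd$id, c("b", "d", "e"))
  ## idempotence
  dd2 <- dedup(dd, end_tolerance = 2)
  expect_identical(dd$id, dd2$id)
})

test_that("brute-force grouping agrees with dedup on random alignment sets", {
  set.seed(36)
  for (rep in 1:5) {
    n <- 40
    starts <- sample(1:5, n, TRUE)
    ends <- starts + 50 + sample(0:6, n, TRUE)
    strands <- sample(c("+", "-"), n, TRUE)
    aln <- data.frame(id = paste0("f", 1:n), start = starts, end = ends,
                      strand = strands, score = 100,
                      seq = strrep("A", 50),
                      qual = vapply(1:n, function(i)
                        phred_str(sample(10:40, 50, TRUE)), character(1)),
                      stringsAsFactors = FALSE)
    attr(aln, "ref_length") <- 300
    class(aln) <- c("fragment_alignments", "data.frame")
    dd <- dedup(aln, end_tolerance = 2)
    ## oracle: chain-cluster within (strand, start) by sorted ends
    expected <- 0L
    for (g in split(seq_len(n), paste(strands, starts))) {
      e <- sort(ends[g])
      expected <- expected + 1L + sum(diff(e) > 2)
    }
    expect_equal(nrow(dd), expected)
  }
})

test_that("consensus calling follows the 2-fold unique coverage rule", {
  counts <- matrix(0L, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 2L                     # {A,A} -> A
  counts["A", 2] <- 1L                     # {A} -> low coverage N
  counts["A", 3] <- 1L; counts["C", 3] <- 1L  # {A,C} -> ambiguous N
  counts["A", 4] <- 5L; counts["C", 4] <- 1L  # clear majority -> A
                                            # position 5: no data -> N
  pl <- structure(list(counts = counts, coverage = colSums(counts),
                       ref_length = 5L), class = "pileup")
  cons <- call_consensus(pl)
  expect_identical(cons$seq, "ANNAN")
  expect_identical(as.character(cons$status),
                   c("called", "low_coverage_N", "ambiguous_N", "called",
                     "low_coverage_N"))
})

test_that("every called consensus position has >= 2 unique supporting fragments", {
  ref <- make_ref(3000, seed = 37)
  cfg <- library_sim_config(ref, n_fragments = 400, per_base_error = 0.002,
                            seed = 38)
  sim <- simulate_library(cfg)
  mg <- merge_pairs(filter_read_pairs(
    demultiplex(sim$pairs, c(s = cfg$barcode))$samples$s)$kept)
  asm <- iterate_assembly(mg, ref)
  called <- asm$consensus$status == "called"
  expect_true(all(asm$pileup$coverage[called] >= 2))
  top <- apply(asm$pileup$counts[, called, drop = FALSE], 2, max)
  expect_true(all(top >= 2))
})

test_that("error-free fragments from the reference itself are a fixed point", {
  ref <- make_ref(1500, seed = 39)
  starts <- seq(1, 1400, by = 25)
  frs <- fragments_from_seqs(paste0("f", seq_along(starts)),
                             vapply(starts, function(s)
                               substr(ref, s, s + 57), character(1)))
  asm <- iterate_assembly(frs, ref)
  expect_equal(asm$n_iterations, 1L)       # immediate fixed point
  called <- asm$consensus$status == "called"
  cc <- strsplit(asm$consensus$seq, NULL)[[1]]
  rr <- strsplit(ref, NULL)[[1]]
  expect_true(all(cc[called] == rr[called]))
})

test_that("iterative assembly recovers a sample genome 20 substitutions away", {
  ref <- make_ref(2000, seed = 40)
  sample_genome <- ref
  set.seed(41)
  subs <- sample(2000, 20)
  sg <- strsplit(sample_genome, NULL)[[1]]
  for (p in subs) sg[p] <- sample(setdiff(c("A", "C", "G", "T"), sg[p]), 1)
  sample_genome <- paste(sg, collapse = "")
  cfg <- library_sim_config(sample_genome, n_fragments = 800,
                            per_base_error = 0, seed = 42)
  sim <- simulate_library(cfg)
  mg <- merge_pairs(filter_read_pairs(
    demultiplex(sim$pairs, c(s = cfg$barcode))$samples$s)$kept)
  asm <- iterate_assembly(mg, ref)      # mapping reference is the OLD genome
  called <- asm$consensus$status == "called"
  cc <- strsplit(asm$consensus$seq, NULL)[[1]]
  expect_true(all(cc[called] == sg[called]))
  expect_true(all(cc[intersect(which(called), subs)] == sg[intersect(which(called), subs)]))
})

test_that("zero fragments give an all-N consensus in one iteration", {
  ref <- make_ref(300, seed = 43)
  asm <- iterate_assembly(fragments_from_seqs(character(0), character(0)),
                          ref)
  expect_equal(asm$n_iterations, 1L)
  expect_identical(asm$consensus$seq, strrep("N", 300))
})

test_that("assembly converges to the same consensus from slightly different references", {
  truth <- make_ref(1500, seed = 44)
  cfg <- library_sim_config(truth, n_fragments = 600, per_base_error = 0,
                            seed = 45)
  sim <- simulate_library(cfg)
  mg <- merge_pairs(filter_read_pairs(
    demultiplex(sim$pairs, c(s = cfg$barcode))$samples$s)$kept)
  ref_b <- make_homolog(truth, 0.01, seed = 46)     # <= 1% substitutions
  asm_a <- iterate_assembly(mg, truth)
  asm_b <- iterate_assembly(mg, ref_b)
  expect_identical(asm_a$consensus$seq, asm_b$consensus$seq)
})

test_that("coverage statistics flag zero-variance coverage and recover exact linearity", {
  ref <- make_ref(1000, seed = 47)
  pl_flat <- structure(list(counts = matrix(0L, 4, 1000),
                            coverage = rep(5L, 1000), ref_length = 1000L),
                       class = "pileup")
  cs <- coverage_stats(pl_flat, ref)
  expect_true(cs$undefined)
  ## coverage proportional to window GC -> r = 1
  gc <- vapply(seq_len(10), function(w) {
    win <- substr(ref, (w - 1) * 100 + 1, w * 100)
    mean(strsplit(win, NULL)[[1]] %in% c("G", "C"))
  }, numeric(1))
  cov <- rep(round(gc * 1000), each = 100)
  pl_gc <- structure(list(counts = matrix(0L, 4, 1000),
                          coverage = as.integer(cov), ref_length = 1000L),
                     class = "pileup")
  cs2 <- coverage_stats(pl_gc, ref)
  expect_gt(cs2$gc_cov_pearson_r, 0.999)
})

test_that("GC-biased sampling yields a positive coverage-GC correlation", {
  set.seed(48)
  signs <- vapply(1:10, function(i) {
    ref <- make_ref(3000, seed = 480 + i)
    gc_at <- cumsum(strsplit(ref, NULL)[[1]] %in% c("G", "C"))
    win_gc <- function(s, e) (gc_at[min(e, 3000)] - gc_at[max(s, 1)]) /
      (e - s)
    ## accept fragments proportionally to local GC
    starts <- sample(2900, 3000, TRUE)
    keep <- stats::runif(3000) < vapply(seq_along(starts), function(j)
      win_gc(starts[j], starts[j] + 58), numeric(1)) * 1.8
    starts <- starts[keep][1:500]
    aln <- data.frame(id = paste0("f", seq_along(starts)),
                      start = starts - 1, end = starts + 57,
                      strand = "+", score = 290,
                      seq = substr(rep(ref, length(starts)), starts,
                                   starts + 57),
                      qual = q40(58), stringsAsFactors = FALSE)
    attr(aln, "ref_length") <- 3000L
    class(aln) <- c("fragment_alignments", "data.frame")
    pl <- build_pileup(aln, 3000)
    coverage_stats(pl, ref)$gc_cov_pearson_r > 0
  }, logical(1))
  expect_gte(mean(signs), 0.9)
})

test_that("mapped plus unmapped equals total fragments", {
  ref <- make_ref(2000, seed = 49)
  cfg <- library_sim_config(ref, n_fragments = 200, per_base_error = 0.01,
                            seed = 50)
  sim <- simulate_library(cfg)
  mg <- merge_pairs(filter_read_pairs(
    demultiplex(sim$pairs, c(s = cfg$barcode))$samples$s)$kept)
  aln <- map_fragments(mg, ref)
  expect_lte(nrow(aln), length(mg$id))
  expect_equal(attr(aln, "n_input"), length(mg$id))
})

test_that("SAM export writes well-formed ungapped records", {
  ref <- make_ref(500, seed = 51)
  aln <- map_fragments(fragments_from_seqs("f1", substr(ref, 51, 108)), ref)
  path <- tempfile(fileext = ".sam")
  write_sam(aln, "chrM", path)
  lines <- readLines(path)
  expect_match(lines[2], "SN:chrM\tLN:500")
  rec <- strsplit(lines[3], "\t")[[1]]
  expect_equal(rec[4], "51")
  expect_equal(rec[6], "58M")
})
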