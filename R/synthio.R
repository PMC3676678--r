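ADAPTER1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAG"   # fixed synthetic 30-mers used
ADAPTER2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAG"   # for read-through padding

#' Simulate a diverged homolog of a sequence
#'
#' Applies independent random substitutions at a given per-site rate;
#' useful for constructing contaminant or numt-like reference sequences
#' for library simulations.
#'
#' @param seq DNA sequence (character string).
#' @param divergence per-site substitution probability.
#' @param seed optional integer seed.
#' @return the mutated sequence.
#' @export
simulate_homolog <- function(seq, divergence, seed = NULL) {
  set_seed_if_given(seed)
  mutate_sequence(toupper(seq), divergence)
}

#' Configuration for the synthetic capture-library simulator
#'
#' Describes a degraded, barcoded, target-captured sequencing library: a
#' circular endogenous reference plus optional contaminant and numt-like
#' sources at configurable proportions, log-normal fragment lengths
#' parameterised by their median (default 58 nt, below the 76-nt read
#' length), per-cycle quality profiles and uniform substitution errors.
#'
#' @param endogenous_ref circular endogenous reference sequence (string).
#' @param contaminant_ref contaminant source sequence (string or `NULL`).
#' @param numt_refs list/vector of numt-like source sequences.
#' @param n_fragments number of fragments to simulate.
#' @param frac_contaminant,frac_numt source proportions (sum must be <= 1).
#' @param frac_duplicate proportion of fragments that are duplicates of an
#'   earlier fragment (same coordinates and strand, fresh errors).
#' @param fragment_length_median median fragment length, nt (default 58;
#'   must be >= 20).
#' @param fragment_length_shape log-normal sdlog (default 0.3).
#' @param read_length sequencing read length per mate (default 76).
#' @param per_base_error uniform substitution error probability per base.
#' @param quality_mean_start,quality_mean_end per-cycle Phred mean at the
#'   first and last cycle (linear profile).
#' @param quality_sd per-cycle Phred standard deviation.
#' @param barcode 7-mer sample barcode.
#' @param seed integer seed.
#' @return object of class `library_sim_config`.
#' @export
library_sim_config <- function(endogenous_ref, contaminant_ref = NULL,
                               numt_refs = list(), n_fragments = 1000L,
                               frac_contaminant = 0, frac_numt = 0,
                               frac_duplicate = 0,
                               fragment_length_median = 58,
                               fragment_length_shape = 0.3,
                               read_length = 76L, per_base_error = 0.002,
                               quality_mean_start = 38,
                               quality_mean_end = 28, quality_sd = 3,
                               barcode = "ACGTGCA", seed = NULL) {
  if (nchar(endogenous_ref) == 0L) stop("endogenous reference is empty")
  if (frac_contaminant < 0 || frac_numt < 0 ||
      frac_contaminant + frac_numt > 1)
    stop("source proportions must be non-negative and sum to <= 1")
  if (frac_contaminant > 0 && is.null(contaminant_ref))
    stop("frac_contaminant > 0 requires a contaminant reference")
  if (frac_numt > 0 && length(numt_refs) == 0L)
    stop("frac_numt > 0 requires numt reference sequences")
  if (fragment_length_median < 20)
    stop("fragment length law with median < 20 rejected")
  if (!grepl("^[ACGT]+$", barcode)) stop("barcode must be an ACGT string")
  structure(list(
    endogenous_ref = toupper(endogenous_ref),
    contaminant_ref = if (is.null(contaminant_ref)) NULL else
      toupper(contaminant_ref),
    numt_refs = lapply(numt_refs, toupper),
    n_fragments = as.integer(n_fragments),
    frac_contaminant = frac_contaminant, frac_numt = frac_numt,
    frac_duplicate = frac_duplicate,
    fragment_length_median = fragment_length_median,
    fragment_length_shape = fragment_length_shape,
    read_length = as.integer(read_length),
    per_base_error = per_base_error,
    quality_mean_start = quality_mean_start,
    quality_mean_end = quality_mean_end, quality_sd = quality_sd,
    barcode = toupper(barcode), seed = seed
  ), class = "library_sim_config")
}

#' Simulate a barcoded paired-end capture library with ground truth
#'
#' Draws fragments from the endogenous (circular), contaminant and
#' numt-like sources at the configured proportions, lays each out as a
#' barcoded paired-end construct (mate 1 = fragment + reverse-complemented
#' barcode + adapter read-through; mate 2 = barcode + reverse complement of
#' the fragment + adapter read-through, both truncated to the read length),
#' applies per-cycle qualities and uniform substitution errors, and records
#' every read in a truth table. Endogenous fragments may span the circular
#' origin (starts are sampled on the doubled reference).
#'
#' @param config a `library_sim_config`.
#' @return object of class `sim_library`: list with `pairs` (a
#'   `read_pairs`), `truth` (data.frame: id, source, start, end, strand,
#'   duplicate_of, insert_length), and `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "library_sim_config"))
  set_seed_if_given(config$seed)
  n <- config$n_fragments
  R <- config$read_length
  L_end <- nchar(config$endogenous_ref)
  doubled <- paste0(config$endogenous_ref, config$endogenous_ref)

  probs <- c(endogenous = 1 - config$frac_contaminant - config$frac_numt,
             contaminant = config$frac_contaminant,
             numt = config$frac_numt)
  source <- sample(names(probs), n, replace = TRUE, prob = probs)

  draw_len <- function(m) {
    len <- round(stats::rlnorm(m, log(config$fragment_length_median),
                               config$fragment_length_shape))
    while (any(len < 20)) {
      bad <- len < 20
      len[bad] <- round(stats::rlnorm(sum(bad),
                                      log(config$fragment_length_median),
                                      config$fragment_length_shape))
    }
    as.integer(len)
  }
  len <- draw_len(n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n)
  insert <- character(n)
  dup_of <- rep(NA_character_, n)
  ids <- sprintf("read%06d", seq_len(n))

  is_dup <- stats::runif(n) < config$frac_duplicate
  is_dup[1L] <- FALSE

  for (i in seq_len(n)) {
    if (is_dup[i]) {
      j <- sample.int(i - 1L, 1L)
      source[i] <- source[j]; len[i] <- len[j]; strand[i] <- strand[j]
      start[i] <- start[j]; insert[i] <- insert[j]
      dup_of[i] <- ids[j]
      next
    }
    if (source[i] == "endogenous") {
      len[i] <- min(len[i], L_end)
      start[i] <- sample.int(L_end, 1L) - 1L
      insert[i] <- substr(doubled, start[i] + 1L, start[i] + len[i])
    } else {
      src <- if (source[i] == "contaminant") config$contaminant_ref else
        config$numt_refs[[sample.int(length(config$numt_refs), 1L)]]
      len[i] <- min(len[i], nchar(src))
      start[i] <- sample.int(nchar(src) - len[i] + 1L, 1L) - 1L
      insert[i] <- substr(src, start[i] + 1L, start[i] + len[i])
    }
  }
  minus <- strand == "-" & !is_dup
  if (any(minus)) insert[minus] <- revcomp(insert[minus])
  ## duplicates copy the already-oriented insert of their original
  for (i in which(is_dup)) insert[i] <- insert[match(dup_of[i], ids)]

  bc <- config$barcode
  pad1 <- paste0(revcomp(bc), ADAPTER1, ADAPTER1, ADAPTER1)
  pad2 <- paste0(ADAPTER2, ADAPTER2, ADAPTER2)
  m1 <- substr(paste0(insert, pad1), 1L, R)
  m2 <- substr(paste0(bc, revcomp(insert), pad2), 1L, R)

  ## per-cycle quality profile (linear mean decay), then substitution errors
  qmeans <- seq(config$quality_mean_start, config$quality_mean_end,
                length.out = R)
  draw_quals <- function() {
    q <- matrix(round(stats::rnorm(n * R, mean = rep(qmeans, each = n),
                                   sd = config$quality_sd)), nrow = n)
    q[q < 2L] <- 2L; q[q > 41L] <- 41L
    apply(q, 1L, int_to_phred)
  }
  q1 <- draw_quals()
  q2 <- draw_quals()

  mutate_reads <- function(seqs) {
    if (config$per_base_error <= 0) return(seqs)
    mat <- matrix(unlist(strsplit(seqs, NULL)), nrow = R)
    mat <- mutate_base_matrix(mat, config$per_base_error)
    apply(mat, 2L, paste, collapse = "")
  }
  m1 <- mutate_reads(m1)
  m2 <- mutate_reads(m2)

  truth <- data.frame(id = ids, source = source, start = start,
                      end = start + len, strand = strand,
                      duplicate_of = dup_of, insert_length = len,
                      stringsAsFactors = FALSE)
  structure(list(pairs = read_pairs(read_set(ids, m1, q1),
                                    read_set(ids, m2, q2)),
                 truth = truth, config = config),
            class = "sim_library")
}

#' Write a truth table as TSV
#' @param truth the `truth` data.frame of a `sim_library`.
#' @param path output path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate an ultrametric tree under a Yule process with rate shifts
#'
#' Forward birth process starting from the root bifurcation: with k
#' lineages the next speciation waits an exponential time with hazard
#' k * r(t), where the per-lineage speciation rate r(t) is piecewise
#' constant, switching from `rates[i]` to `rates[i+1]` at time
#' `shift_times[i]` measured from the root. After the n-th lineage
#' appears, one further waiting time with n lineages is drawn and the
#' present is placed there (censored terminal interval). Because the total
#' tree depth is random, shifts are specified in forward time; the
#' realised shift ages are returned in the `"shift_ages"` attribute.
#'
#' @param rates per-lineage speciation rates (one more than shift times).
#' @param shift_times times of rate shifts measured from the root
#'   (increasing; default none).
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @return an ultrametric, binary `phylo` object with `n_tips` tips;
#'   attributes `shift_ages` (realised shift ages, time before present)
#'   and `root_age`.
#' @export
simulate_yule_shift_tree <- function(rates, shift_times = numeric(0),
                                     n_tips, seed = NULL) {
  if (length(rates) != length(shift_times) + 1L)
    stop("need exactly one more rate than shift times")
  if (any(rates <= 0)) stop("rates must be positive")
  if (is.unsorted(shift_times, strictly = TRUE) && length(shift_times) > 1L)
    stop("shift times must be strictly increasing")
  if (n_tips < 3L) stop("n_tips must be >= 3 (no informative branching times)")
  set_seed_if_given(seed)

  rate_at <- function(t) rates[findInterval(t, shift_times) + 1L]
  ## sample waiting time from t0 with piecewise-constant hazard k * r(t)
  draw_wait <- function(t0, k) {
    target <- stats::rexp(1L)
    t <- t0
    acc <- 0
    bps <- c(shift_times[shift_times > t0], Inf)
    for (b in bps) {
      r <- rate_at(t)
      seg <- b - t
      if (acc + k * r * seg >= target) return(t + (target - acc) / (k * r) - t0)
      acc <- acc + k * r * seg
      t <- b
    }
    stop("unreachable")
  }

  ## grow the tree: internal nodes numbered 1.. in creation order (1 = root)
  n <- as.integer(n_tips)
  n_int <- 0L
  int_edges <- list()                 # each: c(parent_internal, child_internal, length)
  root <- 1L; n_int <- 1L
  active_parent <- c(root, root)      # internal node each open lineage hangs from
  active_birth <- c(0, 0)
  t <- 0
  for (k in 2:(n - 1L)) {
    t <- t + draw_wait(t, k)
    i <- sample.int(length(active_parent), 1L)
    n_int <- n_int + 1L
    nd <- n_int
    int_edges[[length(int_edges) + 1L]] <-
      c(active_parent[i], nd, t - active_birth[i])
    active_parent <- c(active_parent[-i], nd, nd)
    active_birth <- c(active_birth[-i], t, t)
  }
  t_present <- t + draw_wait(t, n)

  ## ape numbering: tips 1..n, root n+1, internals follow creation order
  edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  elen <- numeric(2L * n - 2L)
  r <- 0L
  for (e in int_edges) {
    r <- r + 1L
    edge[r, ] <- c(n + e[1L], n + e[2L])
    elen[r] <- e[3L]
  }
  for (i in seq_along(active_parent)) {
    r <- r + 1L
    edge[r, ] <- c(n + active_parent[i], i)
    elen[r] <- t_present - active_birth[i]
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = sprintf("t%d", seq_len(n)),
                       Nnode = n_int), class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "root_age") <- t_present
  attr(tr, "shift_ages") <- rev(t_present - shift_times[shift_times < t_present])
  tr
}

#' Simulate clade range grids under allopatric or sympatric speciation
#'
#' Walks a dated tree from the root to the tips carrying an occupied-cell
#' set on an equal-area grid. Along each branch the range drifts by random
#' cell swaps: occupied cells are vacated and unoccupied neighbour cells of
#' the range are colonised, keeping range size constant; the expected
#' number of swaps is `drift * range size * branch length` (Poisson), and
#' swaps are applied in batches of at most a tenth of the range size so
#' large ranges drift efficiently. At each cladogenesis the parent range
#' is either split into two disjoint halves along its longer axis
#' (allopatric mode) or copied to both daughters (sympatric mode); a
#' single-cell parent places one daughter on an adjacent cell so the
#' daughters remain disjoint.
#'
#' @param tree a `phylo` with branch lengths and unique tip labels.
#' @param mode `"allopatric"` or `"sympatric"`.
#' @param grid_dim grid dimensions `c(nx, ny)` (default 64 x 64).
#' @param root_range optional integer matrix of occupied `(x, y)` cells for
#'   the root; default: a centred block covering ~75% of each axis.
#' @param drift expected swaps per occupied cell per unit time (default 0.25).
#' @param seed integer seed.
#' @return named list (one element per tip) of two-column integer matrices
#'   of occupied cells; class `range_grid_set`, attribute `grid_dim`.
#' @export
simulate_clade_ranges <- function(tree, mode = c("allopatric", "sympatric"),
                                  grid_dim = c(64L, 64L), root_range = NULL,
                                  drift = 0.25, seed = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  set_seed_if_given(seed)
  nx <- as.integer(grid_dim[1L]); ny <- as.integer(grid_dim[2L])
  if (is.null(root_range)) {
    wx <- max(2L, round(0.75 * nx)); wy <- max(2L, round(0.75 * ny))
    x0 <- (nx - wx) %/% 2L; y0 <- (ny - wy) %/% 2L
    root_range <- as.matrix(expand.grid(x = x0 + seq_len(wx),
                                        y = y0 + seq_len(wy)))
  }
  cell_id <- function(m) (m[, 2L] - 1L) * nx + m[, 1L]
  id_to_cell <- function(id) cbind(x = (id - 1L) %% nx + 1L,
                                   y = (id - 1L) %/% nx + 1L)
  neighbours_of <- function(ids) {
    cur <- id_to_cell(ids)
    nb <- rbind(cbind(cur[, 1L] + 1L, cur[, 2L]),
                cbind(cur[, 1L] - 1L, cur[, 2L]),
                cbind(cur[, 1L], cur[, 2L] + 1L),
                cbind(cur[, 1L], cur[, 2L] - 1L))
    nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= nx &
             nb[, 2L] >= 1L & nb[, 2L] <= ny, , drop = FALSE]
    unique((nb[, 2L] - 1L) * nx + nb[, 1L])
  }

  drift_range <- function(cells, time) {
    if (drift <= 0 || time <= 0) return(cells)
    ids <- cell_id(cells)
    n_moves <- stats::rpois(1L, drift * nrow(cells) * time)
    while (n_moves > 0L && length(ids) >= 2L) {
      free_nb <- setdiff(neighbours_of(ids), ids)
      if (length(free_nb) == 0L) break
      batch <- min(n_moves, max(1L, length(ids) %/% 10L), length(free_nb))
      gain <- free_nb[sample.int(length(free_nb), batch)]
      lose <- ids[sample.int(length(ids), batch)]
      ids <- c(setdiff(ids, lose), gain)
      n_moves <- n_moves - batch
    }
    id_to_cell(ids)
  }

  split_range <- function(cells) {
    if (nrow(cells) >= 2L) {
      spread_x <- diff(range(cells[, 1L])); spread_y <- diff(range(cells[, 2L]))
      axis <- if (spread_x >= spread_y) 1L else 2L
      o <- order(cells[, axis], cells[, 3L - axis])
      half <- nrow(cells) %/% 2L
      return(list(cells[o[seq_len(half)], , drop = FALSE],
                  cells[o[(half + 1L):nrow(cells)], , drop = FALSE]))
    }
    ## single-cell parent: second daughter on an adjacent cell (disjoint)
    ids <- cell_id(cells)
    nb <- neighbours_of(ids)
    nb <- setdiff(nb, ids)
    if (length(nb) == 0L) stop("grid range too small to split")
    list(cells, id_to_cell(nb[sample.int(length(nb), 1L)]))
  }

  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  out <- vector("list", ntip)
  names(out) <- tree$tip.label

  if (nrow(root_range) < 2L && mode == "allopatric" && (nx * ny) < 2L)
    stop("grid range too small to split")
  recurse <- function(node, cells) {
    if (node <= ntip) { out[[node]] <<- cells; return(invisible(NULL)) }
    kids <- children[[as.character(node)]]
    halves <- if (mode == "allopatric") split_range(cells) else
      list(cells, cells)
    for (j in seq_along(kids)) {
      kid <- kids[j]
      moved <- drift_range(halves[[j]], edge_len[[as.character(kid)]])
      recurse(kid, moved)
    }
  }
  recurse(root_node, root_range)
  structure(out, class = "range_grid_set", grid_dim = c(nx, ny))
}

#' Write/read range grids as CSV (taxon, cell_x, cell_y)
#' @param ranges a `range_grid_set` (named list of cell matrices).
#' @param path CSV path.
#' @export
write_ranges_csv <- function(ranges, path) {
  df <- do.call(rbind, lapply(names(ranges), function(tx)
    data.frame(taxon = tx, cell_x = ranges[[tx]][, 1L],
               cell_y = ranges[[tx]][, 2L])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ranges_csv
#' @return `read_ranges_csv`: a `range_grid_set` (duplicate taxon rows are
#'   collapsed by first occurrence of each cell).
#' @export
read_ranges_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp <- split(df[, c("cell_x", "cell_y")], df$taxon)
  out <- lapply(sp, function(d) unique(as.matrix(d)))
  structure(out, class = "range_grid_set",
            grid_dim = c(max(df$cell_x), max(df$cell_y)))
}
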