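range_cell_keys <- function(cells) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2L)
  unique(paste(cells[, 1L], cells[, 2L], sep = ","))
}

## tip indices descending from a node (node in ape numbering)
node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, node_tips, tree = tree))
}

#' Range of a clade: union of its tip ranges
#'
#' @param tree a `phylo`.
#' @param node node number (ape numbering; tips are 1..Ntip).
#' @param grids a `range_grid_set` (named list of cell matrices keyed by
#'   tip label).
#' @return two-column matrix of occupied cells (the union), or `NULL` with
#'   a warning when a descendant tip has no range.
#' @export
clade_range <- function(tree, node, grids) {
  tips <- tree$tip.label[node_tips(tree, node)]
  missing <- setdiff(tips, names(grids))
  if (length(missing)) {
    warning("missing tip ranges: ", paste(missing, collapse = ", "),
            "; node skipped")
    return(NULL)
  }
  cells <- unique(do.call(rbind, lapply(grids[tips], function(m)
    matrix(as.integer(m), ncol = 2L))))
  colnames(cells) <- c("x", "y")
  cells
}

#' Degree of range overlap between two cell sets
#'
#' The shared occupied area divided by the smaller range's area:
#' `|A intersect B| / min(|A|, |B|)`. Symmetric and translation-invariant;
#' 1 when one range contains the other, 0 when disjoint.
#'
#' @param a,b two-column matrices of occupied cells (non-empty).
#' @return overlap degree in `[0, 1]`.
#' @export
overlap_degree <- function(a, b) {
  ka <- range_cell_keys(a); kb <- range_cell_keys(b)
  if (length(ka) == 0L || length(kb) == 0L) stop("empty range")
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Range-overlap points for the nodes of a dated tree
#'
#' For every internal node (or every sister-tip pair in `"sisters"` mode)
#' computes the overlap degree between the two daughter-clade ranges and
#' pairs it with the node age, producing the points of an
#' age--range-overlap plot.
#'
#' @param tree ultrametric `phylo` with branch lengths.
#' @param grids a `range_grid_set` keyed by tip label.
#' @param mode `"nodes"` (all internal nodes, daughter-clade range unions)
#'   or `"sisters"` (cherries only).
#' @return data.frame with columns `node`, `age`, `overlap`.
#' @export
range_overlap_points <- function(tree, grids, mode = c("nodes", "sisters")) {
  mode <- match.arg(mode)
  ntip <- length(tree$tip.label)
  ages <- ape::branching.times(tree)
  out <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    if (length(kids) != 2L) next
    if (mode == "sisters" && !all(kids <= ntip)) next
    ra <- clade_range(tree, kids[1L], grids)
    rb <- clade_range(tree, kids[2L], grids)
    if (is.null(ra) || is.null(rb)) next
    out[[length(out) + 1L]] <-
      data.frame(node = node, age = unname(ages[as.character(node)]),
                 overlap = overlap_degree(ra, rb))
  }
  do.call(rbind, out)
}

#' Age--range-overlap regression (allopatry test)
#'
#' Ordinary least squares of overlap degree on node age. Under allopatric
#' speciation with post-speciation range drift, recently diverged pairs
#' have near-zero overlap (intercept indistinguishable from 0) and overlap
#' increases with divergence time (positive slope); under sympatric
#' speciation the intercept is positive.
#'
#' @param points data.frame with columns `age` and `overlap` (>= 3 rows,
#'   ages not all equal).
#' @return list with `intercept`, `slope`, `adj_R2`, `p_intercept`,
#'   `p_slope`, `n`, and the fitted `lm` object.
#' @export
arc_regression <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (stats::var(points$age) == 0) stop("degenerate design: all ages equal")
  fit <- stats::lm(overlap ~ age, data = points)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn
  co <- sm$coefficients
  p_int <- co["(Intercept)", "Pr(>|t|)"]
  p_slp <- co["age", "Pr(>|t|)"]
  if (sm$sigma < 1e-10) {
    ## exact fit: a zero coefficient carries no evidence, a non-zero one is
    ## exact (the t statistics are 0/0 and +-Inf/0)
    p_int <- if (abs(co["(Intercept)", "Estimate"]) < 1e-12) 1 else 0
    p_slp <- if (abs(co["age", "Estimate"]) < 1e-12) 1 else 0
  }
  list(intercept = co["(Intercept)", "Estimate"],
       slope = co["age", "Estimate"],
       adj_R2 = sm$adj.r.squared,
       p_intercept = p_int,
       p_slope = p_slp,
       n = nrow(points), fit = fit)
}
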