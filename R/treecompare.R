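#' Nucleotide substitution model
#'
#' Time-reversible rate matrix builder for JC69, HKY85 and GTR, scaled to
#' one expected substitution per unit branch length, with optional
#' discrete-gamma rate heterogeneity (median method).
#'
#' @param type `"JC69"`, `"HKY85"` or `"GTR"`.
#' @param base_freq equilibrium base frequencies (A, C, G, T); must sum
#'   to 1. Ignored for JC69 (equal).
#' @param kappa transition/transversion rate ratio (HKY85).
#' @param rates six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param gamma_shape gamma shape for among-site rate variation, or `NULL`
#'   for equal rates.
#' @param n_cat number of discrete gamma categories (default 4).
#' @return object of class `subst_model`: list with `Q` (scaled rate
#'   matrix), `freq`, `site_rates`, `type`.
#' @export
substitution_model <- function(type = c("JC69", "HKY85", "GTR"),
                               base_freq = rep(0.25, 4), kappa = 2,
                               rates = rep(1, 6), gamma_shape = NULL,
                               n_cat = 4L) {
  type <- match.arg(type)
  if (type == "JC69") base_freq <- rep(0.25, 4)
  if (abs(sum(base_freq) - 1) > 1e-8) stop("base frequencies must sum to 1")
  if (any(base_freq <= 0)) stop("base frequencies must be positive")
  ex <- switch(type,
    JC69 = rep(1, 6),
    HKY85 = c(1, kappa, 1, 1, kappa, 1),
    GTR = rates)
  if (length(ex) != 6L || any(ex <= 0)) stop("need 6 positive exchangeabilities")
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (i in seq_len(6)) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    Q[a, b] <- ex[i] * base_freq[b]
    Q[b, a] <- ex[i] * base_freq[a]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freq * diag(Q))        # mean rate; scale to 1
  Q <- Q / mu
  site_rates <- if (is.null(gamma_shape)) 1 else {
    r <- stats::qgamma((seq_len(n_cat) - 0.5) / n_cat,
                       shape = gamma_shape, rate = gamma_shape)
    r * n_cat / sum(r)                   # median method, renormalised
  }
  structure(list(Q = Q, freq = base_freq, site_rates = site_rates,
                 type = type, gamma_shape = gamma_shape),
            class = "subst_model")
}

## eigen machinery for P(t) = exp(Qt), computed in the symmetrised basis
model_eigen <- function(model) {
  pr <- sqrt(model$freq)
  B <- diag(pr) %*% model$Q %*% diag(1 / pr)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(vals = eig$values,
       right = diag(1 / pr) %*% eig$vectors,
       left = t(eig$vectors) %*% diag(pr))
}

prob_matrix <- function(me, t) {
  P <- me$right %*% (exp(me$vals * t) * me$left)
  P[P < 0] <- 0
  P
}

encode_alignment <- function(alignment) {
  if (inherits(alignment, "DNAbin"))
    alignment <- toupper(as.character(alignment))
  if (is.list(alignment))
    alignment <- do.call(rbind, lapply(alignment, function(x)
      strsplit(toupper(paste(x, collapse = "")), NULL)[[1]]))
  stopifnot(is.matrix(alignment))
  mode(alignment) <- "character"
  toupper(alignment)
}

#' Per-site log-likelihoods of a fixed tree
#'
#' Felsenstein pruning over alignment columns for a tree with fixed branch
#' lengths. Gaps, Ns and other ambiguity codes are treated as missing data
#' (all-ones partial likelihood). With gamma rate heterogeneity the site
#' likelihood averages over the discrete categories.
#'
#' @param tree a `phylo` with branch lengths; tip labels must match
#'   alignment row names.
#' @param alignment character matrix (taxa x sites; rownames = taxa), a
#'   `DNAbin` matrix, or a named list of character vectors.
#' @param model a `subst_model`.
#' @return numeric vector of per-site log-likelihoods (length = number of
#'   sites); attribute `logL` holds the sum.
#' @export
site_loglik <- function(tree, alignment, model = substitution_model("JC69")) {
  aln <- encode_alignment(alignment)
  if (is.null(rownames(aln))) stop("alignment must have taxon names")
  missing_taxa <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing_taxa))
    stop("tips missing from alignment: ", paste(missing_taxa, collapse = ", "))
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  aln <- aln[tree$tip.label, , drop = FALSE]
  nsites <- ncol(aln)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  me <- model_eigen(model)

  ## tip partial likelihoods (4 x nsites), shared across categories
  tip_partials <- lapply(seq_len(ntip), function(i) {
    codes <- .base_code_table[utf8ToInt(paste(aln[i, ], collapse = ""))]
    M <- matrix(0, 4L, nsites)
    known <- codes > 0L
    M[cbind(codes[known], which(known))] <- 1
    M[, !known] <- 1                   # missing data
    M
  })

  po <- ape::reorder.phylo(tree, "postorder")
  lik_site <- rep(0, nsites)
  for (rate in model$site_rates) {
    partials <- vector("list", nnode)
    partials[seq_len(ntip)] <- tip_partials
    for (e in seq_len(nrow(po$edge))) {
      child <- po$edge[e, 2L]; parent <- po$edge[e, 1L]
      P <- prob_matrix(me, po$edge.length[e] * rate)
      contrib <- P %*% partials[[child]]
      partials[[parent]] <- if (is.null(partials[[parent]])) contrib else
        partials[[parent]] * contrib
    }
    root <- po$edge[nrow(po$edge), 1L]
    lik_site <- lik_site +
      as.numeric(model$freq %*% partials[[root]]) / length(model$site_rates)
  }
  out <- log(lik_site)
  attr(out, "logL") <- sum(out)
  out
}

#' Shimodaira-Hasegawa test via RELL resampling
#'
#' Compares the summed log-likelihoods of competing fixed trees on the
#' same alignment columns. For each tree `m`, the test statistic is
#' `delta_m = L_best - L_m`. The null distribution is obtained by
#' resampling site log-likelihoods (RELL bootstrap), centering each tree's
#' resampled totals on its own bootstrap mean, and recording for each
#' replicate the centered maximum advantage over tree `m`; `p_m` is the
#' fraction of replicates at or above `delta_m`. The best tree always
#' receives p = 1 under this convention.
#'
#' @param site_ll matrix of per-site log-likelihoods (trees x sites) with
#'   row names, or a list of vectors from [site_loglik()].
#' @param n_boot number of RELL replicates (default 10000).
#' @param seed integer seed.
#' @return data.frame with columns `tree`, `logL`, `delta`, `p_value`.
#' @export
sh_test <- function(site_ll, n_boot = 10000L, seed = NULL) {
  if (is.list(site_ll)) site_ll <- do.call(rbind, site_ll)
  stopifnot(is.matrix(site_ll))
  m <- nrow(site_ll); nsites <- ncol(site_ll)
  if (m < 2L) stop("need at least two trees")
  if (nsites < 10L) stop("need at least 10 sites")
  if (any(!is.finite(site_ll))) stop("non-finite site log-likelihoods")
  if (is.null(rownames(site_ll)))
    rownames(site_ll) <- paste0("tree", seq_len(m))
  set_seed_if_given(seed)
  L <- rowSums(site_ll)
  delta <- max(L) - L
  ## RELL: multinomial site weights
  W <- stats::rmultinom(n_boot, nsites, rep(1 / nsites, nsites))
  Lb <- site_ll %*% W                         # m x n_boot
  R <- Lb - rowMeans(Lb)                      # center per tree
  colmax <- do.call(pmax, lapply(seq_len(m), function(i) R[i, ]))
  p <- vapply(seq_len(m), function(i) mean(colmax - R[i, ] >= delta[i]),
              numeric(1))
  data.frame(tree = rownames(site_ll), logL = L, delta = delta,
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate an alignment under a substitution model on a tree
#'
#' Forward simulation used for calibration experiments: draws root states
#' from the equilibrium frequencies and evolves them along the tree with
#' the model's transition probabilities.
#'
#' @param tree a `phylo` with branch lengths.
#' @param nsites number of alignment columns.
#' @param model a `subst_model`.
#' @param seed integer seed.
#' @return character matrix (taxa x sites) with tip labels as row names.
#' @export
simulate_alignment <- function(tree, nsites, model = substitution_model("JC69"),
                               seed = NULL) {
  set_seed_if_given(seed)
  me <- model_eigen(model)
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1L]
  states <- matrix(0L, nrow = ntip + tree$Nnode, ncol = nsites)
  states[root, ] <- sample.int(4L, nsites, replace = TRUE, prob = model$freq)
  ## preorder = reversed postorder edges
  for (e in rev(seq_len(nrow(po$edge)))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    P <- prob_matrix(me, po$edge.length[e])
    ## vectorised multinomial draw per parent state
    for (s in 1:4) {
      cols <- which(states[parent, ] == s)
      if (length(cols))
        states[child, cols] <- sample.int(4L, length(cols), replace = TRUE,
                                          prob = P[s, ])
    }
  }
  out <- matrix(DNA_BASES[states[seq_len(ntip), ]], nrow = ntip)
  rownames(out) <- tree$tip.label
  out
}
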