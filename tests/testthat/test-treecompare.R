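test_that("rate matrices are properly scaled and frequencies validated", {
  m <- substitution_model("GTR", base_freq = c(0.4, 0.1, 0.3, 0.2),
                          rates = c(1, 4, 0.7, 1.2, 5, 1))
  expect_equal(unname(rowSums(m$Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(m$freq * diag(m$Q)), 1, tolerance = 1e-12)
  expect_error(substitution_model("GTR", base_freq = c(0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("two identical 1-nt sequences match the closed-form JC probability", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.3);")
  aln <- matrix(c("A", "A"), nrow = 2, dimnames = list(c("A", "B"), NULL))
  ll <- site_loglik(tr, aln, substitution_model("JC69"))
  ## closed form: sum_x pi_x P_xA(t1) P_xA(t2) with JC transition probs
  pjc <- function(t, same) if (same) 0.25 + 0.75 * exp(-4 * t / 3) else
    0.25 - 0.25 * exp(-4 * t / 3)
  expected <- log(sum(vapply(1:4, function(x)
    0.25 * pjc(0.2, x == 1) * pjc(0.3, x == 1), numeric(1))))
  expect_equal(as.numeric(ll), expected, tolerance = 1e-10)
})

test_that("zero branch lengths with identical sequences give ln(pi)", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  aln <- matrix(c("G", "G"), nrow = 2, dimnames = list(c("A", "B"), NULL))
  m <- substitution_model("HKY85", base_freq = c(0.1, 0.2, 0.3, 0.4))
  ll <- site_loglik(tr, aln, m)
  expect_equal(as.numeric(ll), log(0.3), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration over ancestral states (5 taxa)", {
  tr <- ape::read.tree(
    text = "(((A:0.1,B:0.15):0.05,C:0.2):0.08,(D:0.12,E:0.07):0.1);")
  m <- substitution_model("HKY85", base_freq = c(0.35, 0.15, 0.25, 0.25),
                          kappa = 4)
  aln <- simulate_alignment(tr, 40, m, seed = 121)
  ll <- site_loglik(tr, aln, m)

  ## brute force: sum over all 4^Nnode ancestral assignments per column
  me <- museomics:::model_eigen(m)
  ntip <- 5L
  nnode <- tr$Nnode
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    museomics:::prob_matrix(me, tr$edge.length[e]))
  root <- ntip + 1L
  states <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  codes <- apply(aln, c(1, 2), function(ch) match(ch, c("A", "C", "G", "T")))
  brute <- vapply(seq_len(ncol(aln)), function(site) {
    total <- 0
    for (r in seq_len(nrow(states))) {
      anc <- states[r, ]
      state_of <- function(node) if (node <= ntip) codes[node, site] else
        anc[node - ntip]
      p <- m$freq[anc[1]]
      for (e in seq_len(nrow(tr$edge)))
        p <- p * P[[e]][state_of(tr$edge[e, 1]), state_of(tr$edge[e, 2])]
      total <- total + p
    }
    log(total)
  }, numeric(1))
  expect_equal(as.numeric(ll), brute, tolerance = 1e-8)
})

test_that("per-site likelihoods agree with phangorn", {
  skip_if_not_installed("phangorn")
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.08);")
  m <- substitution_model("GTR", base_freq = c(0.3, 0.2, 0.3, 0.2),
                          rates = c(1, 3, 0.8, 1.1, 4, 1))
  aln <- simulate_alignment(tr, 150, m, seed = 122)
  ours <- attr(site_loglik(tr, aln, m), "logL")
  fit <- phangorn::pml(tr, phangorn::phyDat(aln),
                       bf = c(0.3, 0.2, 0.3, 0.2),
                       Q = c(1, 3, 0.8, 1.1, 4, 1))
  expect_equal(ours, fit$logLik, tolerance = 1e-6)
})

test_that("JC69 is GTR with equal frequencies and exchangeabilities", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.08);")
  aln <- simulate_alignment(tr, 80, substitution_model("JC69"), seed = 123)
  ll_jc <- site_loglik(tr, aln, substitution_model("JC69"))
  ll_gtr <- site_loglik(tr, aln, substitution_model("GTR"))
  expect_lt(max(abs(ll_jc - ll_gtr)), 1e-9)
})

test_that("gaps and Ns are treated as missing data", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- matrix(c("A", "N"), nrow = 2, dimnames = list(c("A", "B"), NULL))
  ll <- site_loglik(tr, aln)
  ## with B missing the site likelihood is just pi_A summed over paths = 0.25
  expect_equal(as.numeric(ll), log(0.25), tolerance = 1e-10)
})

test_that("total log-likelihood is invariant to site order", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.08);")
  aln <- simulate_alignment(tr, 60, seed = 124)
  ll1 <- attr(site_loglik(tr, aln), "logL")
  perm <- sample(ncol(aln))
  ll2 <- attr(site_loglik(tr, aln[, perm]), "logL")
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("mismatched tip names raise an informative error", {
  tr <- ape::read.tree(text = "(A:0.1,Z:0.1);")
  aln <- matrix(c("A", "C"), nrow = 2, dimnames = list(c("A", "B"), NULL))
  expect_error(site_loglik(tr, aln), "Z")
})

test_that("a tree compared with itself yields zero deltas and p = 1", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.08);")
  aln <- simulate_alignment(tr, 100, seed = 125)
  ll <- site_loglik(tr, aln)
  res <- sh_test(rbind(a = ll, b = ll), n_boot = 2000, seed = 126)
  expect_equal(res$delta, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
})

test_that("a tree worse by many log-units per site is firmly rejected", {
  set.seed(127)
  good <- matrix(stats::rnorm(100, 0, 0.1), nrow = 1)
  bad <- good - 5
  res <- sh_test(rbind(good = good[1, ], bad = bad[1, ]), n_boot = 3000,
                 seed = 128)
  expect_lt(res$p_value[res$tree == "bad"], 0.001)
  expect_equal(res$p_value[res$tree == "good"], 1)
})

test_that("p-values are monotone in total log-likelihood on shared resamples", {
  set.seed(129)
  S <- matrix(stats::rnorm(5 * 200, 0, 1), nrow = 5)
  S <- S - (1:5) * 0.02        # strictly ordered totals
  res <- sh_test(S, n_boot = 2000, seed = 130)
  o <- order(res$logL, decreasing = TRUE)
  expect_true(all(diff(res$p_value[o]) <= 1e-12))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("SH p-values for equally good trees are calibrated (KS uniformity)", {
  gen <- ape::read.tree(text = "((A:0.15,B:0.15):0.0,(C:0.15,D:0.15):0.0);")
  t1 <- ape::read.tree(text = "((A:0.15,B:0.15):0.03,(C:0.15,D:0.15):0.03);")
  t2 <- ape::read.tree(text = "((A:0.15,C:0.15):0.03,(B:0.15,D:0.15):0.03);")
  m <- substitution_model("JC69")
  set.seed(131)
  pw <- vapply(1:120, function(i) {
    aln <- simulate_alignment(gen, 200, m)
    S <- rbind(T1 = site_loglik(t1, aln, m), T2 = site_loglik(t2, aln, m))
    min(sh_test(S, n_boot = 600)$p_value)
  }, numeric(1))
  ## the worse of two exchangeable trees has p ~ U(0, 0.5)
  ks <- suppressWarnings(stats::ks.test(2 * pw, "punif"))
  expect_gt(ks$p.value, 0.01)
})
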