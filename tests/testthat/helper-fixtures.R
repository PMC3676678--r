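# Shared fixture builders (everything generated in code; no binary files).

make_ref <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# diverged homolog: per-site substitution at rate p
make_homolog <- function(ref, p, seed = 2) {
  set.seed(seed)
  museomics:::mutate_sequence(ref, p)
}

q40 <- function(n) intToUtf8(rep(40L + 33L, n))

phred_str <- function(q) intToUtf8(as.integer(q) + 33L)

# one read pair laid out exactly as the simulator does (no errors):
# mate1 = insert + rc(barcode) + adapter; mate2 = barcode + rc(insert) + adapter
make_pair <- function(insert, barcode = "ACGTGCA", read_length = 76L,
                      id = "p1") {
  a1 <- paste0(museomics::revcomp(barcode),
               strrep(museomics:::ADAPTER1, 3L))
  a2 <- strrep(museomics:::ADAPTER2, 3L)
  m1 <- substr(paste0(insert, a1), 1L, read_length)
  m2 <- substr(paste0(barcode, museomics::revcomp(insert), a2), 1L,
               read_length)
  read_pairs(read_set(id, m1, q40(nchar(m1))),
             read_set(id, m2, q40(nchar(m2))))
}

# independent node-age oracle: recursive depth traversal (no ape calls)
node_ages_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- rep(NA_real_, nn)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  depth[root] <- 0
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + tree$edge.length[e]
        done <- FALSE
      }
    }
    if (done) break
  }
  total <- max(depth[seq_len(ntip)])
  sort(total - depth[(ntip + 1L):nn], decreasing = TRUE)
}
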