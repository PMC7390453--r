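# small builders shared across test files

# genotype matrix from a plain matrix, with optional per-call depth
make_gm <- function(calls, depth = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  if (!is.null(samples)) rownames(calls) <- samples
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    dimnames(depth) <- dimnames(calls)
  }
  genotype_matrix(calls, depth = depth)
}

# random multi-population genotype matrix with independent per-pop freqs
rand_gm <- function(n_per_pop, n_loci, seed, miss = 0.1, depth = FALSE) {
  withr::with_seed(seed, {
    pops <- names(n_per_pop)
    rows <- list(); labels <- character(0)
    for (p in pops) {
      f <- runif(n_loci, 0.05, 0.95)
      g <- matrix(rbinom(n_per_pop[[p]] * n_loci, 2, rep(f, each = n_per_pop[[p]])),
                  n_per_pop[[p]])
      rows[[p]] <- g
      labels <- c(labels, rep(p, n_per_pop[[p]]))
    }
    calls <- do.call(rbind, rows)
    calls[runif(length(calls)) < miss] <- NA
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
    dp <- if (depth) matrix(rpois(length(calls), 20), nrow(calls)) else NULL
    list(gm = make_gm(calls, depth = dp),
         pm = stats::setNames(labels, rownames(calls)))
  })
}

# align a pairwise matrix to a label order (keeps semantics)
align_pm <- function(m, labs) {
  pairwise_matrix(unclass(m)[labs, labs], semantics = attr(m, "semantics"))
}

# adjusted Rand index between two partitions (Hubert & Arabie)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
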