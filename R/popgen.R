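#' Labelled symmetric pairwise matrix
#'
#' A small container for the square matrices the landscape stage consumes:
#' pairwise F'ST, great-circle distances in km, or averaged connectivity
#' scores. The semantics tag travels with the matrix so downstream code can
#' refuse mixed-up inputs.
#'
#' @param values square numeric matrix (or object coercible to one).
#' @param labels population labels; default taken from dimnames.
#' @param semantics one of `"fst_prime"`, `"geo_km"`, `"connectivity_marine"`,
#'   `"connectivity_aerial"`.
#' @return matrix of class `pairwise_matrix` with attribute `semantics`.
#' @export
pairwise_matrix <- function(values, labels = NULL,
                            semantics = c("fst_prime", "geo_km",
                                          "connectivity_marine",
                                          "connectivity_aerial")) {
  semantics <- match.arg(semantics)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pairwise matrix must be square")
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE,
                        tolerance = 1e-8)))
    stop("pairwise matrix must be symmetric")
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  if (is.null(rownames(values))) stop("pairwise matrix needs labels")
  structure(values, class = c("pairwise_matrix", "matrix"),
            semantics = semantics)
}

#' Read / write pairwise matrices as labelled square CSV
#' @param path CSV path (first column = row labels).
#' @param semantics semantics tag for the matrix read, see
#'   [pairwise_matrix()].
#' @return [pairwise_matrix()] (read) or `path` invisibly (write).
#' @export
read_pairwise_csv <- function(path, semantics = "fst_prime") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  pairwise_matrix(as.matrix(df), semantics = semantics)
}

#' @rdname read_pairwise_csv
#' @param m a [pairwise_matrix()]
#' @export
write_pairwise_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path)
  invisible(path)
}

# internal: per-population alt-allele frequencies and called counts
# returns list(freq = pops x loci, n_called = pops x loci diploid counts)
pop_allele_freqs <- function(gm, pm) {
  pm <- check_popmap(gm, pm)
  pops <- sort(unique(pm))
  idx <- split(seq_along(gm$samples), pm)[pops]
  freq <- matrix(NA_real_, length(pops), ncol(gm$calls),
                 dimnames = list(pops, colnames(gm$calls)))
  n_called <- matrix(0L, length(pops), ncol(gm$calls),
                     dimnames = dimnames(freq))
  for (p in seq_along(pops)) {
    sub <- gm$calls[idx[[p]], , drop = FALSE]
    n <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    freq[p, ] <- ifelse(n > 0, alt / (2 * n), NA_real_)
    n_called[p, ] <- n
  }
  list(freq = freq, n_called = n_called)
}

# internal: F'ST from two allele-frequency vectors (NA = not called)
fst_prime_from_freqs <- function(pA, pB) {
  use <- !is.na(pA) & !is.na(pB)
  pA <- pA[use]; pB <- pB[use]
  if (!length(pA)) stop("no loci called in both populations")
  hS <- (2 * pA * (1 - pA) + 2 * pB * (1 - pB)) / 2
  pbar <- (pA + pB) / 2
  hT <- 2 * pbar * (1 - pbar)
  sum_hT <- sum(hT)
  if (sum_hT == 0) return(NA_real_)  # both populations monomorphic throughout
  gst <- (sum_hT - sum(hS)) / sum_hT
  hS_bar <- mean(hS)
  if (hS_bar >= 1) return(NA_real_)
  gst * (1 + hS_bar) / (1 - hS_bar)   # Hedrick standardisation, k = 2 demes
}

#' Hedrick standardised pairwise F'ST
#'
#' Multi-locus G_ST between two populations from plug-in allele frequencies,
#' rescaled by its maximum attainable value given the within-population
#' heterozygosity (Hedrick's F'ST for k = 2 demes). Per locus, with alt
#' frequencies \eqn{p_A, p_B} over non-missing calls:
#' \eqn{H_S = (2p_A(1-p_A) + 2p_B(1-p_B))/2}, \eqn{H_T = 2\bar p(1-\bar p)}
#' with \eqn{\bar p = (p_A+p_B)/2}. Loci are combined as a ratio of sums,
#' \eqn{G_{ST} = (\Sigma H_T - \Sigma H_S)/\Sigma H_T}, and standardised as
#' \eqn{F'_{ST} = G_{ST}(1 + \bar H_S)/(1 - \bar H_S)} where
#' \eqn{\bar H_S} is the mean of \eqn{H_S} over loci. Loci not called in
#' either population are skipped. Negative multi-locus values (sampling
#' noise) are reported as computed unless `clamp`.
#'
#' @param gm a [genotype_matrix()]
#' @param pm population map
#' @param popA,popB population labels.
#' @param clamp clamp negative estimates at 0. Default FALSE.
#' @return F'ST (scalar; NA with a warning when both populations are
#'   monomorphic at every shared locus).
#' @export
fst_prime <- function(gm, pm, popA, popB, clamp = FALSE) {
  af <- pop_allele_freqs(gm, pm)
  if (!all(c(popA, popB) %in% rownames(af$freq)))
    stop("unknown population label")
  f <- fst_prime_from_freqs(af$freq[popA, ], af$freq[popB, ])
  if (is.na(f)) warning("F'ST undefined: both populations monomorphic at all shared loci")
  if (clamp && !is.na(f)) f <- max(f, 0)
  f
}

#' All pairwise F'ST values
#' @inheritParams fst_prime
#' @return a [pairwise_matrix()] with semantics `fst_prime` (diagonal 0).
#' @export
fst_prime_matrix <- function(gm, pm, clamp = FALSE) {
  af <- pop_allele_freqs(gm, pm)
  pops <- rownames(af$freq)
  out <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    f <- fst_prime_from_freqs(af$freq[i, ], af$freq[j, ])
    if (clamp && !is.na(f)) f <- max(f, 0)
    out[i, j] <- out[j, i] <- f
  }
  pairwise_matrix(out, semantics = "fst_prime")
}

#' Balanced subsamples of genotypes per population
#'
#' Draws `n_reps` replicate datasets; in each, every population contributes
#' exactly `k` genotypes sampled (by default with replacement) from that
#' population. `k` defaults to the minimum population size, the scheme that
#' keeps uneven sample sizes from biasing comparative statistics.
#'
#' @param gm a [genotype_matrix()]
#' @param pm population map
#' @param n_reps number of replicates, default 10.
#' @param k genotypes per population per replicate; default (`NULL`) the
#'   minimum population size.
#' @param replace sample with replacement (default TRUE).
#' @param seed integer seed; replicates are fully reproducible.
#' @return list of length `n_reps`; each element a list with the replicate
#'   `gm` (samples renamed to be unique) and matching `pm`.
#' @export
balanced_subsample <- function(gm, pm, n_reps = 10, k = NULL, replace = TRUE,
                               seed = NULL) {
  pm <- check_popmap(gm, pm)
  idx <- split(seq_along(gm$samples), pm)
  if (is.null(k)) k <- min(lengths(idx))
  if (k <= 0) stop("k must be positive")
  if (!replace && any(lengths(idx) < k))
    stop("k exceeds a population size and replace = FALSE")
  with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      take <- unlist(lapply(idx, function(i)
        i[sample.int(length(i), k, replace = replace)]), use.names = FALSE)
      sub <- gm$calls[take, , drop = FALSE]
      rownames(sub) <- paste0(gm$samples[take], "_r", seq_along(take))
      rep_pm <- stats::setNames(pm[take], rownames(sub))
      list(gm = genotype_matrix(sub, gm$loci,
                                if (!is.null(gm$depth))
                                  gm$depth[take, , drop = FALSE]),
           pm = rep_pm)
    })
  })
}

#' Per-population diversity statistics
#'
#' For each population: mean observed heterozygosity H_O (heterozygote
#' count over called count, averaged across loci), nucleotide diversity pi
#' (per locus \eqn{\frac{2n}{2n-1} 2p(1-p)} with n called diploids, averaged
#' over the loci of the matrix — a relative measure, since invariant sites
#' are absent from SNP panels), the number of private alleles (alleles seen
#' in exactly one population), and the missing-call fraction.
#'
#' @param gm a [genotype_matrix()]
#' @param pm population map
#' @return data.frame with one row per population and columns `population`,
#'   `H_O`, `pi`, `private_alleles`, `missing_fraction`.
#' @export
diversity_stats <- function(gm, pm) {
  pm <- check_popmap(gm, pm)
  pops <- sort(unique(pm))
  idx <- split(seq_along(gm$samples), pm)[pops]
  af <- pop_allele_freqs(gm, pm)
  # allele presence per population: ref (p < 1) and alt (p > 0)
  has_ref <- !is.na(af$freq) & af$freq < 1
  has_alt <- !is.na(af$freq) & af$freq > 0
  ref_npops <- colSums(has_ref)
  alt_npops <- colSums(has_alt)
  out <- lapply(seq_along(pops), function(p) {
    sub <- gm$calls[idx[[p]], , drop = FALSE]
    called <- colSums(!is.na(sub))
    if (all(called == 0)) stop("population ", pops[p], " has no called genotypes")
    het <- colSums(!is.na(sub) & sub == 1L)
    ho <- mean((het / called)[called > 0])
    n <- af$n_called[p, ]
    pr <- af$freq[p, ]
    pi_l <- ifelse(n > 0, (2 * n / (2 * n - 1)) * 2 * pr * (1 - pr), NA_real_)
    data.frame(
      population = pops[p],
      H_O = ho,
      pi = mean(pi_l, na.rm = TRUE),
      private_alleles = sum(has_ref[p, ] & ref_npops == 1L) +
        sum(has_alt[p, ] & alt_npops == 1L),
      missing_fraction = mean(is.na(sub)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Folded allele frequency spectrum of one population
#'
#' Bins each locus by its minor-allele frequency min(p, 1-p). With a fixed
#' number of called diploids k per locus the frequencies land on the exact
#' grid \{0, 1/2k, ..., 0.5\} (for k = 5: 0, 0.1, ..., 0.5); bin 0 is the
#' monomorphic proportion.
#'
#' @param gm a [genotype_matrix()]
#' @param pm population map
#' @param pop population label.
#' @return named numeric vector of class `folded_afs`: proportion of loci
#'   per minor-allele-frequency bin; sums to 1. Attribute `k` records the
#'   diploid sample size.
#' @export
folded_afs <- function(gm, pm, pop) {
  pm <- check_popmap(gm, pm)
  sub <- gm$calls[pm == pop, , drop = FALSE]
  if (!nrow(sub)) stop("unknown or empty population: ", pop)
  n <- colSums(!is.na(sub))
  k <- unique(n)
  if (length(k) != 1L || k == 0)
    stop("exact AFS binning needs the same called count at every locus; ",
         "impute missing calls or restrict to complete-case loci")
  alt <- colSums(sub, na.rm = TRUE)
  maf_count <- pmin(alt, 2L * k - alt)
  bins <- 0:k
  counts <- tabulate(maf_count + 1L, nbins = k + 1L)
  props <- counts / length(maf_count)
  names(props) <- as.character(round(bins / (2 * k), 10))
  structure(props, class = "folded_afs", k = k)
}

#' Mean and confidence interval over balanced-subsample replicates
#'
#' @param values numeric vector (one statistic, one value per replicate) or
#'   matrix with replicates in rows (one column per population/pair).
#' @param conf confidence level, default 0.95.
#' @param method `"t"` (mean +/- t-quantile * sd / sqrt(r), the standard
#'   confidence interval of the mean; default) or `"percentile"`.
#' @return data.frame with columns `mean`, `ci_low`, `ci_high`,
#'   `n_replicates` (one row per column of `values`).
#' @export
summarize_subsamples <- function(values, conf = 0.95,
                                 method = c("t", "percentile")) {
  method <- match.arg(method)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  r <- nrow(values)
  if (r < 2) stop("need at least 2 replicates")
  m <- colMeans(values)
  if (method == "t") {
    s <- apply(values, 2, stats::sd)
    half <- stats::qt(1 - (1 - conf) / 2, df = r - 1) * s / sqrt(r)
    lo <- m - half; hi <- m + half
  } else {
    a <- (1 - conf) / 2
    qs <- apply(values, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  data.frame(mean = m, ci_low = lo, ci_high = hi, n_replicates = r,
             row.names = colnames(values))
}

#' Mean and SD of one population's pairwise values against all others
#'
#' @param m a [pairwise_matrix()]
#' @param pop population label.
#' @return list with `mean` and `sd` ((n-1) denominator) of the
#'   off-diagonal row for `pop`.
#' @export
mean_fst_to_others <- function(m, pop) {
  if (!pop %in% rownames(m)) stop("unknown population: ", pop)
  if (nrow(m) < 2) stop("matrix has a single population")
  v <- m[pop, setdiff(colnames(m), pop)]
  list(mean = mean(v), sd = stats::sd(v))
}
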