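#' Filter SNPs on depth, missingness and allele count
#'
#' Applies the per-call and per-locus filters in the order that makes the
#' depth bounds meaningful: first, any call whose read depth falls outside
#' `[min_depth, max_depth]` is set missing; then loci are dropped if their
#' missing-data fraction is `>= max_missing` (the retention rule is a strict
#' "less than") or, when `biallelic_only`, if they carry more than one
#' alternate allele.
#'
#' @param gm a [genotype_matrix()]; must carry depth when depth bounds are
#'   active.
#' @param max_missing maximum tolerated missing fraction per locus,
#'   exclusive; loci at or above it are dropped. Default 0.20.
#' @param min_depth,max_depth inclusive per-call depth bounds; calls outside
#'   are masked. Pass `NULL` for both to skip depth masking.
#' @param biallelic_only drop loci flagged as multi-allelic. Default TRUE.
#' @return the filtered [genotype_matrix()], with an attribute `removed`
#'   giving per-rule removal counts (`masked_calls`, `multiallelic_loci`,
#'   `high_missing_loci`).
#' @export
filter_snps <- function(gm, max_missing = 0.20, min_depth = 3, max_depth = 45,
                        biallelic_only = TRUE) {
  if (!is.numeric(max_missing) || max_missing <= 0 || max_missing > 1)
    stop("max_missing must be in (0, 1]")
  depth_active <- !is.null(min_depth) || !is.null(max_depth)
  masked <- 0L
  if (depth_active) {
    if (is.null(gm$depth))
      stop("depth bounds requested but genotype matrix has no depth")
    if (is.null(min_depth)) min_depth <- 0L
    if (is.null(max_depth)) max_depth <- .Machine$integer.max
    if (min_depth > max_depth) stop("min_depth > max_depth")
    bad <- !is.na(gm$calls) & (gm$depth < min_depth | gm$depth > max_depth)
    masked <- sum(bad)
    gm$calls[bad] <- NA_integer_
  }
  multi <- if (biallelic_only && "multiallelic" %in% names(gm$loci))
    which(gm$loci$multiallelic) else integer(0)
  miss_frac <- colMeans(is.na(gm$calls))
  high_miss <- which(miss_frac >= max_missing)
  drop <- union(multi, high_miss)
  keep <- setdiff(seq_len(ncol(gm$calls)), drop)
  out <- gm_subset(gm, loci = keep)
  attr(out, "removed") <- c(
    masked_calls = masked,
    multiallelic_loci = length(multi),
    high_missing_loci = length(setdiff(high_miss, multi))
  )
  out
}

#' Keep loci scored in a minimum fraction of every population
#'
#' A locus survives only if it is called in at least `min_called` of the
#' genotypes within each population ("at least" is inclusive, so a locus
#' called in exactly 75% of every population is kept at the default).
#'
#' @param gm a [genotype_matrix()]
#' @param pm population map (named character vector, see [read_popmap()])
#' @param min_called minimum called fraction per population, inclusive.
#' @return filtered [genotype_matrix()] with attribute `removed_loci`.
#' @export
population_coverage_filter <- function(gm, pm, min_called = 0.75) {
  pm <- check_popmap(gm, pm)
  pops <- split(seq_along(gm$samples), pm)
  if (any(lengths(pops) == 0)) stop("population with zero samples")
  called <- !is.na(gm$calls)
  ok <- rep(TRUE, ncol(gm$calls))
  for (idx in pops) {
    frac <- colMeans(called[idx, , drop = FALSE])
    ok <- ok & (frac >= min_called)
  }
  out <- gm_subset(gm, loci = which(ok))
  attr(out, "removed_loci") <- sum(!ok)
  out
}

#' Impute missing calls with the per-locus modal dosage
#'
#' Every missing call is replaced by the most frequent dosage at its locus;
#' ties go to the lower dosage. Deterministic. This is a deliberately simple
#' completion step so that PCA/DAPC have complete input; it is not a
#' phasing-based imputation and is logged as such by the pipeline.
#'
#' @param gm a [genotype_matrix()]
#' @return a [genotype_matrix()] with no missing calls.
#' @export
impute_missing <- function(gm) {
  all_missing <- which(colSums(!is.na(gm$calls)) == 0)
  if (length(all_missing))
    stop("loci with all calls missing: ",
         paste(colnames(gm$calls)[utils::head(all_missing, 5)], collapse = ", "))
  calls <- gm$calls
  for (j in which(colSums(is.na(calls)) > 0)) {
    tab <- tabulate(calls[, j] + 1L, nbins = 3L)
    mode <- which.max(tab) - 1L  # which.max takes the first max: lower dosage
    calls[is.na(calls[, j]), j] <- mode
  }
  genotype_matrix(calls, gm$loci, gm$depth)
}
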