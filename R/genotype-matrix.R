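#' Diploid SNP genotype matrix
#'
#' The central container of the package: an individuals x loci matrix of
#' diploid alt-allele dosages (0, 1, 2 or `NA` for missing), an optional
#' matrix of per-call read depths with identical dimensions, and a locus
#' table recording chromosome, position and the two alleles.
#'
#' @param calls integer matrix, samples in rows, loci in columns; entries in
#'   \{0, 1, 2, NA\}. Row names are sample identifiers, column names locus
#'   identifiers.
#' @param loci data.frame with one row per locus and columns `chrom`, `pos`,
#'   `ref`, `alt`. An optional logical column `multiallelic` flags records
#'   that carried more than one alternate allele in the source VCF.
#' @param depth optional non-negative integer matrix of per-call read depths,
#'   same dimensions and dimnames as `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `loci`, `depth` (possibly `NULL`), `samples`.
#' @export
genotype_matrix <- function(calls, loci = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("sample_", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("locus_", seq_len(ncol(calls)))
  if (is.null(loci)) {
    loci <- data.frame(
      chrom = "1", pos = seq_len(ncol(calls)),
      ref = "A", alt = "T", stringsAsFactors = FALSE
    )
  }
  loci <- as.data.frame(loci)
  rownames(loci) <- colnames(calls)
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (nrow(loci) != ncol(calls))
    stop("loci table has ", nrow(loci), " rows but calls has ",
         ncol(calls), " columns")
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("duplicate loci by (chrom, pos)")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(calls)))
      stop("depth dimensions must equal calls dimensions")
    dimnames(depth) <- dimnames(calls)
    if (any(depth < 0, na.rm = TRUE)) stop("depths must be non-negative")
  }
  structure(
    list(calls = calls, loci = loci, depth = depth,
         samples = rownames(calls)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing%s)\n",
              nrow(x$calls), ncol(x$calls), 100 * miss,
              if (is.null(x$depth)) ", no depth" else ", with depth"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of samples / loci
#' @param gm a [genotype_matrix()]
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a [genotype_matrix()]
#' @param samples character or integer index of samples to keep
#' @param loci character or integer index of loci to keep
#' @return a new `genotype_matrix`
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$calls))
  if (is.null(loci)) loci <- seq_len(ncol(gm$calls))
  genotype_matrix(
    gm$calls[samples, loci, drop = FALSE],
    gm$loci[loci, , drop = FALSE],
    if (!is.null(gm$depth)) gm$depth[samples, loci, drop = FALSE]
  )
}

#' Per-sample missing-data proportion
#' @param gm a [genotype_matrix()]
#' @return named numeric vector, one entry per sample.
#' @export
sample_missingness <- function(gm) rowMeans(is.na(gm$calls))

# internal: run code with a temporary RNG seed; NULL seed leaves RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
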