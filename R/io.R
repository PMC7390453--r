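#' Read diploid genotypes from a VCF file
#'
#' Parses the GT field (and DP, when present) of a VCF 4.x file into a
#' [genotype_matrix()]. Sample and locus order are preserved. Unphased and
#' phased separators are both accepted; half-calls (`0/.`) and `./.` map to
#' missing. Records with more than one alternate allele are retained but
#' flagged in the locus table (`multiallelic = TRUE`); their dosage counts
#' non-reference allele copies and is only meaningful after biallelic
#' filtering.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return a [genotype_matrix()] with depth when the VCF carries DP.
#' @seealso [write_vcf()], [filter_snps()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (ncol(v@gt) < 2) stop("VCF has no sample columns: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  dosage <- vapply(alleles, function(a) {
    if (length(a) != 2 || anyNA(a) || any(a == ".")) return(NA_integer_)
    sum(as.integer(a) > 0L)
  }, integer(1))
  calls <- matrix(dosage, nrow = nrow(gt), dimnames = dimnames(gt))
  calls <- t(calls)  # samples x loci
  depth <- NULL
  fmt <- strsplit(v@gt[, 1], ":", fixed = TRUE)
  if (all(vapply(fmt, function(f) "DP" %in% f, logical(1)))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    dp[is.na(dp)] <- 0
    depth <- t(dp)
  }
  alt <- fix[, "ALT"]
  loci <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    multiallelic = grepl(",", alt, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  ids <- fix[, "ID"]
  locus_names <- ifelse(is.na(ids) | ids == ".",
                        paste0(loci$chrom, "_", loci$pos), ids)
  colnames(calls) <- locus_names
  if (!is.null(depth)) colnames(depth) <- locus_names
  genotype_matrix(calls, loci, depth)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT (and DP when the matrix carries depth) so that
#' `read_vcf(write_vcf(gm, path))` is the identity on calls, depth, sample
#' order and locus order.
#'
#' @param gm a [genotype_matrix()]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=landgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  has_dp <- !is.null(gm$depth)
  fmt <- if (has_dp) "GT:DP" else "GT"
  for (j in seq_len(ncol(gm$calls))) {
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    if (has_dp) gt <- paste0(gt, ":", gm$depth[, j])
    rec <- gm$loci[j, ]
    writeLines(paste(c(as.character(rec$chrom), rec$pos, colnames(gm$calls)[j],
                       rec$ref, rec$alt, ".", "PASS", ".", fmt, gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a TSV with header `sample<TAB>population`.
#'
#' @param path path to the TSV.
#' @return named character vector: names are sample ids, values population
#'   labels.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("sample", "population") %in% names(df)))
    stop("popmap must have columns 'sample' and 'population'")
  if (anyDuplicated(df$sample))
    stop("duplicate sample(s) in popmap: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (any(!nzchar(df$population))) stop("empty population label in popmap")
  stats::setNames(as.character(df$population), df$sample)
}

#' Read a per-population site table
#'
#' Expects a TSV with header
#' `population<TAB>lat<TAB>lon<TAB>marine<TAB>aerial`: decimal-degree
#' coordinates of each population plus its marine connectivity score
#' (mean density of commercial shipping tracks within 200 km of the
#' sampling point) and aerial connectivity score (number of active airline
#' routes at the main airport). Scores may be NA for populations excluded
#' from landscape analyses.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `population`, `lat`, `lon`, `marine`,
#'   `aerial`.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", "*"))
  need <- c("population", "lat", "lon", "marine", "aerial")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  for (col in c("lat", "lon", "marine", "aerial"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in site table column '", col, "'")
  if (anyDuplicated(df$population)) stop("duplicate population in site table")
  if (any(abs(df$lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(df$lon) > 180)) stop("longitude outside [-180, 180]")
  if (any(df$marine < 0, na.rm = TRUE) || any(df$aerial < 0, na.rm = TRUE))
    stop("connectivity scores must be >= 0")
  df[need]
}

#' Bundled Aedes site tables
#'
#' Returns the per-population site table bundled with the package for one of
#' the two study species: population labels, collection-city coordinates,
#' and marine/aerial connectivity scores. The Colombo-1 Ae. albopictus
#' subpopulation carries NA connectivity scores and is conventionally
#' omitted from landscape analyses.
#'
#' @param species `"aegypti"` or `"albopictus"`.
#' @return data.frame as returned by [read_sites()].
#' @export
aedes_sites <- function(species = c("aegypti", "albopictus")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0(species, "_sites.tsv"),
                      package = "landgen", mustWork = TRUE)
  read_sites(path)
}

# internal: check that every sample of gm is labelled exactly once
check_popmap <- function(gm, pm) {
  missing <- setdiff(gm$samples, names(pm))
  if (length(missing))
    stop("samples without population label: ",
         paste(utils::head(missing, 5), collapse = ", "))
  pm[gm$samples]
}
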